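#' Expected fraction abundances under the steady-state labeling model
#'
#' For a transcript synthesized at constant rate `s` (transcripts/h) and
#' decaying with first-order rate `k` (1/h), steady-state total abundance is
#' `s/k`. After a metabolic-labeling pulse of `t` hours, the labeled (newly
#' made) pool is `(s/k) * (1 - exp(-k t))` and the unlabeled (pre-existing,
#' flow-through) pool is `(s/k) * exp(-k t)`; total = labeled + unlabeled
#' exactly.
#'
#' @param s synthesis rate(s), > 0.
#' @param k decay rate(s) in 1/h, > 0.
#' @param t labeling time in hours, > 0.
#' @return data.frame with columns `total`, `labeled`, `unlabeled`, recycled
#'   over the longest input.
#' @examples
#' expected_fractions(log(2), log(2), 1)  # half-life 1 h: 50/50 split
#' @export
expected_fractions <- function(s, k, t = 1) {
  if (any(k <= 0)) stop("decay rate k must be > 0")
  if (any(t <= 0)) stop("labeling time t must be > 0")
  if (any(s <= 0)) stop("synthesis rate s must be > 0")
  total <- s / k
  unlabeled <- total * exp(-k * t)
  data.frame(total = total, labeled = total - unlabeled, unlabeled = unlabeled)
}

#' Stability Score implied by decay kinetics
#'
#' The noiseless Stability Score of a transcript with decay rate `k` after a
#' pulse of `t` hours: `log2(exp(-kt) / (1 - exp(-kt)))`, i.e. the log2 ratio
#' of the pre-existing (FT) to newly made (4sU) pools. Strictly decreasing in
#' `k` for fixed `t`.
#'
#' @param k decay rate (1/h), > 0.
#' @param t labeling time (h), > 0.
#' @return numeric Stability Score(s).
#' @export
implied_ss <- function(k, t = 1) {
  if (any(k <= 0) || any(t <= 0)) stop("k and t must be > 0")
  e <- exp(-k * t)
  log2(e / (1 - e))
}

#' Simulate ground-truth kinetics for an annotated genome
#'
#' Draws per-gene half-lives (log-normal) and synthesis rates, then derives
#' per-isoform decay rates: distal 3'UTR isoforms of affected multi-PAS genes
#' are destabilized by `dpas_k_factor` per distal rank step; intronic-PAS
#' isoforms by `ipa_k_factor`, optionally coupled to host-intron size.
#' Condition specifications then scale decay rates per condition (cell-line
#' specific stability).
#'
#' @param config a [sim_config()] object.
#' @param annotation the `genome_annotation` from [simulate_annotation()].
#' @return data.frame (one row per isoform/PAS) with synthesis rate `s`,
#'   baseline decay `k_base`, half-life `halflife`, one `k_<condition>` column
#'   per condition, and one `perturbed_<condition>` flag per condition marking
#'   genes whose decay that condition rescales.
#' @export
simulate_kinetics <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "genome_annotation"))
  set.seed(config$seed + 1L)
  g <- annotation$genes
  n <- nrow(g)
  hl <- rlnorm(n, config$halflife_meanlog, config$halflife_sdlog)
  hl <- hl * ifelse(g$gene_type == "lncRNA", config$lncrna_halflife_scale, 1)
  k_gene <- setNames(log(2) / hl, g$gene_id)
  s_gene <- setNames(rlnorm(n, config$synthesis_meanlog, config$synthesis_sdlog),
                     g$gene_id)

  p <- annotation$pas
  multi <- names(which(table(p$gene_id[p$region_class == "TPA"]) > 1))
  dpas_affected <- multi[runif(length(multi)) < config$dpas_affected_frac]

  k_base <- k_gene[p$gene_id]
  is_tpa <- p$region_class == "TPA"
  aff <- is_tpa & p$gene_id %in% dpas_affected
  k_base[aff] <- k_base[aff] * config$dpas_k_factor^(p$tpa_rank[aff] - 1)

  is_ipa <- p$region_class == "IPA"
  if (any(is_ipa)) {
    key <- paste(p$gene_id, p$host_intron)
    ikey <- paste(annotation$introns$gene_id, annotation$introns$rank)
    isz <- annotation$introns$size[match(key[is_ipa], ikey)]
    mult <- config$ipa_k_factor * (isz / median(isz))^config$ipa_intron_coupling
    k_base[is_ipa] <- k_base[is_ipa] * mult
  }

  w <- runif(nrow(p), 0.3, 1)
  s_iso <- s_gene[p$gene_id] * w

  out <- data.frame(isoform_id = p$pas_id, gene_id = p$gene_id,
                    region_class = p$region_class, tpa_rank = p$tpa_rank,
                    host_intron = p$host_intron,
                    gene_type = g$gene_type[match(p$gene_id, g$gene_id)],
                    s = unname(s_iso), k_base = unname(k_base),
                    halflife = log(2) / unname(k_base),
                    stringsAsFactors = FALSE)
  for (cond in names(config$conditions)) {
    spec <- config$conditions[[cond]]
    kc <- out$k_base
    perturbed <- rep(FALSE, n)
    frac <- spec$frac_genes %||% 0
    if (frac > 0 && !is.null(spec$k_scale)) {
      sel <- sample(g$gene_id, round(frac * n))
      perturbed <- g$gene_id %in% sel
      hit <- out$gene_id %in% sel
      kc[hit] <- kc[hit] * spec$k_scale
    }
    if (!is.null(spec$dpas_k_scale)) {
      hit <- out$region_class == "TPA" & !is.na(out$tpa_rank) & out$tpa_rank > 1
      kc[hit] <- kc[hit] * spec$dpas_k_scale
    }
    out[[paste0("k_", cond)]] <- kc
    out[[paste0("perturbed_", cond)]] <-
      perturbed[match(out$gene_id, g$gene_id)]
  }
  rownames(out) <- out$isoform_id
  out
}

#' Expected per-sample abundances for every simulated isoform
#'
#' Applies the labeling model condition by condition (using that condition's
#' decay rates) and distributes the three pools over the `total`, `4sU` and
#' `FT` fractions, with optional fractionation cross-contamination mixing the
#' labeled and unlabeled pools.
#'
#' @param truth output of [simulate_kinetics()].
#' @param config the [sim_config()] used to generate it.
#' @param samples optional sample sheet; defaults to [sample_sheet()] of
#'   `config`.
#' @return numeric matrix, isoforms x samples.
#' @export
expected_abundance_matrix <- function(truth, config, samples = sample_sheet(config)) {
  t <- config$labeling_time
  rho <- config$contamination
  m <- matrix(0, nrow(truth), nrow(samples),
              dimnames = list(truth$isoform_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    k <- truth[[paste0("k_", samples$condition[j])]]
    total <- truth$s / k
    unl <- total * exp(-k * t)
    lab <- total - unl
    m[, j] <- switch(samples$fraction[j],
                     total = total,
                     "4sU" = (1 - rho) * lab + rho * unl,
                     FT = (1 - rho) * unl + rho * lab,
                     stop("unknown fraction: ", samples$fraction[j]))
  }
  m
}

#' Sample sequencing counts from expected abundances
#'
#' Each sample's library size is drawn Poisson around `depth`, then reads are
#' distributed multinomially over isoforms with probabilities proportional to
#' that sample's expected abundances.
#'
#' @param expected isoforms x samples matrix of non-negative expected
#'   abundances (see [expected_abundance_matrix()]).
#' @param depth expected total reads per sample; 0 yields an all-zero matrix.
#' @param seed optional integer seed.
#' @return integer matrix of counts, same dimensions as `expected`.
#' @export
simulate_counts <- function(expected, depth, seed = NULL) {
  if (any(expected < 0)) stop("expected abundances must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(0L, nrow(expected), ncol(expected), dimnames = dimnames(expected))
  if (depth == 0) return(counts)
  tot <- colSums(expected)
  if (any(tot == 0)) stop("zero total abundance in sample(s): ",
                          paste(colnames(expected)[tot == 0], collapse = ", "))
  lib <- rpois(ncol(expected), depth)
  for (j in seq_len(ncol(expected)))
    counts[, j] <- rmultinom(1, lib[j], expected[, j])[, 1]
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a complete labeled 3'-end sequencing dataset
#'
#' Convenience wrapper chaining [simulate_annotation()], [simulate_kinetics()],
#' [expected_abundance_matrix()] and [simulate_counts()].
#'
#' @param config a [sim_config()] object.
#' @return list of class `"sim_dataset"`: `annotation`, `reference`, `truth`,
#'   `samples`, `expected`, `counts`, `config`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_annotation(config)
  truth <- simulate_kinetics(config, sim$annotation)
  samples <- sample_sheet(config)
  expected <- expected_abundance_matrix(truth, config, samples)
  counts <- simulate_counts(expected, config$depth, seed = config$seed + 2L)
  structure(list(annotation = sim$annotation, reference = sim$reference,
                 truth = truth, samples = samples, expected = expected,
                 counts = counts, config = config),
            class = "sim_dataset")
}

#' Assigned-cluster table from simulated ground truth
#'
#' Builds the same table that PAS calling + clustering + gene assignment
#' would produce on noise-free alignments, directly from the simulated PAS
#' records and a count matrix. Useful for exercising the downstream analysis
#' stages without emitting and re-parsing alignments.
#'
#' @param sim a `sim_dataset`.
#' @param counts isoforms x samples matrix (rownames = PAS ids); defaults to
#'   `sim$counts`.
#' @return data.frame in the layout of [assign_clusters()] output.
#' @export
truth_clusters <- function(sim, counts = sim$counts) {
  p <- sim$annotation$pas[rownames(counts), , drop = FALSE]
  out <- data.frame(cluster_id = p$pas_id, chrom = p$chrom, strand = p$strand,
                    summit = p$position, n_sites = 1L,
                    as.data.frame(counts), total = rowSums(counts),
                    gene_id = p$gene_id, region_class = p$region_class,
                    host_intron = p$host_intron,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- out$cluster_id
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d isoforms x %d samples (%d genes)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$annotation$genes)))
  cat(sprintf("  total reads: %d | conditions: %s\n", sum(x$counts),
              paste(names(x$config$conditions), collapse = ", ")))
  invisible(x)
}

#' @importFrom stats rmultinom
NULL
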