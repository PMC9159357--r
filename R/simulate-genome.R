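#' @importFrom stats rnorm runif rlnorm rpois median setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulate a genome annotation and reference sequence
#'
#' Lays out non-overlapping genes on a single synthetic chromosome. Every gene
#' has a 3'-most exon carrying 1-3 PAS positions (spacing drawn from
#' `autr_size_range`); genes flagged as IPA-bearing additionally carry one
#' intronic PAS in their first intron, and every intron is annotated with
#' MaxEnt-style 5'/3' splice-site scores (drawn, since splice-site scoring is a
#' consumed input, not computed here). Per-gene GC content of the transcribed
#' region is drawn from `utr_gc_range` so that sequence-feature recovery is
#' testable. Coordinates are 0-based half-open; PAS positions are the 0-based
#' coordinate of the last transcribed nucleotide.
#'
#' The two to `max(tail_range)` bases immediately downstream of every PAS (in
#' the direction the poly(A)-tail soft-clip lays back onto the genome) are
#' forced to be non-A on the sense strand, so that simulated tail Ts are
#' genuinely non-genomic and the PAS-read calling rule recovers every clean
#' read. This is a property of the generator, documented rather than hidden.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `annotation` (a `genome_annotation`: data frames
#'   `genes`, `exons`, `introns`, `pas`, plus `seqlengths`) and `reference`
#'   (a [Biostrings::DNAStringSet]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  chrom <- "chrS"
  gap <- 400L
  utr_lead <- 150L
  tail_margin <- 60L
  up_exon_len <- 150L

  n_pas <- as.integer(sample(names(config$pas_per_gene), n, replace = TRUE,
                             prob = config$pas_per_gene))
  gene_type <- sample(names(config$gene_type_probs), n, replace = TRUE,
                      prob = config$gene_type_probs)
  has_ipa <- runif(n) < config$ipa_probability
  gc <- runif(n, config$utr_gc_range[1], config$utr_gc_range[2])
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- vector("list", n)
  exons <- vector("list", n)
  introns <- vector("list", n)
  pas <- vector("list", n)
  sense_seqs <- vector("list", n)
  cursor <- 300L

  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    n_ex <- if (has_ipa[i]) sample(2:4, 1, prob = c(0.5, 0.3, 0.2))
            else sample(1:4, 1, prob = c(0.3, 0.3, 0.25, 0.15))
    intron_len <- if (n_ex > 1)
      as.integer(round(runif(n_ex - 1, config$intron_size_range[1],
                             config$intron_size_range[2]))) else integer(0)
    spacing <- if (n_pas[i] > 1)
      as.integer(round(runif(n_pas[i] - 1, config$autr_size_range[1],
                             config$autr_size_range[2]))) else integer(0)
    last_len <- utr_lead + sum(spacing) + tail_margin
    ex_len <- c(rep(up_exon_len, n_ex - 1), last_len)

    # sense-strand offsets (0-based) of exon/intron boundaries
    starts <- integer(n_ex); ends <- integer(n_ex)
    istarts <- integer(n_ex - 1); iends <- integer(n_ex - 1)
    off <- 0L
    for (e in seq_len(n_ex)) {
      starts[e] <- off; ends[e] <- off + ex_len[e]; off <- ends[e]
      if (e < n_ex) { istarts[e] <- off; iends[e] <- off + intron_len[e]; off <- iends[e] }
    }
    glen <- off
    p1 <- starts[n_ex] + utr_lead
    pas_off <- p1 + c(0L, cumsum(spacing))
    ipa_off <- if (has_ipa[i])
      istarts[1] + as.integer(round(runif(1, 0.2, 0.8) * intron_len[1])) else NA_integer_

    gstart <- cursor; gend <- cursor + glen; cursor <- gend + gap
    to_genomic_pos <- function(x)
      if (strand[i] == "+") gstart + x else gend - 1L - x
    to_genomic_iv <- function(a, b)  # sense [a,b) -> genomic [start,end)
      if (strand[i] == "+") cbind(gstart + a, gstart + b) else cbind(gend - b, gend - a)

    ex_iv <- to_genomic_iv(starts, ends)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand[i],
                             start = gstart, end = gend, gene_type = gene_type[i],
                             n_exons = n_ex, gc_target = gc[i],
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, rank = seq_len(n_ex), chrom = chrom,
                             strand = strand[i], start = ex_iv[, 1], end = ex_iv[, 2],
                             is_last = seq_len(n_ex) == n_ex,
                             stringsAsFactors = FALSE)
    if (n_ex > 1) {
      in_iv <- to_genomic_iv(istarts, iends)
      introns[[i]] <- data.frame(gene_id = gid, rank = seq_len(n_ex - 1),
                                 chrom = chrom, strand = strand[i],
                                 start = in_iv[, 1], end = in_iv[, 2],
                                 size = intron_len,
                                 ss5_score = round(rnorm(n_ex - 1, 8, 2), 2),
                                 ss3_score = round(rnorm(n_ex - 1, 8, 2), 2),
                                 stringsAsFactors = FALSE)
    }
    p_df <- data.frame(pas_id = sprintf("%s_TPA%d", gid, seq_len(n_pas[i])),
                       gene_id = gid, chrom = chrom, strand = strand[i],
                       position = vapply(pas_off, to_genomic_pos, integer(1)),
                       region_class = "TPA", tpa_rank = seq_len(n_pas[i]),
                       host_intron = NA_integer_, stringsAsFactors = FALSE)
    if (has_ipa[i]) {
      p_df <- rbind(p_df, data.frame(
        pas_id = sprintf("%s_IPA1", gid), gene_id = gid, chrom = chrom,
        strand = strand[i], position = to_genomic_pos(ipa_off),
        region_class = "IPA", tpa_rank = NA_integer_, host_intron = 1L,
        stringsAsFactors = FALSE))
    }
    pas[[i]] <- p_df
    probs <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    sense_seqs[[i]] <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                              prob = probs)
  }

  seqlen <- cursor + 300L
  ref <- sample(c("A", "C", "G", "T"), seqlen, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
  genes <- do.call(rbind, genes)
  for (i in seq_len(n)) {
    s <- sense_seqs[[i]]
    if (genes$strand[i] == "-") s <- rev(unname(.comp_map[s]))
    ref[(genes$start[i] + 1):genes$end[i]] <- s
  }

  pas <- do.call(rbind, pas)
  rownames(pas) <- pas$pas_id
  # guarantee non-genomic poly(A) evidence: bases the tail Ts lay back onto
  # must not read as A on the sense strand
  tmax <- max(config$tail_range)
  for (j in seq_len(nrow(pas))) {
    u <- seq_len(tmax)
    if (pas$strand[j] == "+") {
      idx <- pas$position[j] + 1L + u   # 1-based indices of positions p+1..p+tmax
      bad <- ref[idx] == "A"
      if (any(bad)) ref[idx[bad]] <- sample(c("C", "G", "T"), sum(bad), replace = TRUE)
    } else {
      idx <- pas$position[j] + 1L - u   # forward coords p-1..p-tmax (1-based)
      bad <- ref[idx] == "T"
      if (any(bad)) ref[idx[bad]] <- sample(c("A", "C", "G"), sum(bad), replace = TRUE)
    }
  }

  ann <- structure(
    list(genes = genes,
         exons = do.call(rbind, exons),
         introns = if (length(introns) && any(!vapply(introns, is.null, logical(1))))
           do.call(rbind, introns[!vapply(introns, is.null, logical(1))])
           else data.frame(gene_id = character(), rank = integer(),
                           chrom = character(), strand = character(),
                           start = integer(), end = integer(), size = integer(),
                           ss5_score = numeric(), ss3_score = numeric()),
         pas = pas,
         seqlengths = setNames(seqlen, chrom)),
    class = "genome_annotation")
  .check_no_same_strand_overlap(ann)
  reference <- Biostrings::DNAStringSet(setNames(paste(ref, collapse = ""), chrom))
  list(annotation = ann, reference = reference)
}

.check_no_same_strand_overlap <- function(ann) {
  g <- ann$genes
  for (s in unique(g$strand)) {
    gs <- g[g$strand == s, ]
    gs <- gs[order(gs$chrom, gs$start), ]
    same <- c(FALSE, gs$chrom[-1] == gs$chrom[-nrow(gs)])
    if (any(same & c(FALSE, gs$start[-1] < gs$end[-nrow(gs)])))
      stop("overlapping same-strand genes generated; regenerate with a new seed")
  }
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d exons, %d introns, %d PAS (%d TPA, %d IPA)\n",
              nrow(x$genes), nrow(x$exons), nrow(x$introns), nrow(x$pas),
              sum(x$pas$region_class == "TPA"), sum(x$pas$region_class == "IPA")))
  cat(sprintf("chromosomes: %s\n",
              paste(sprintf("%s (%d nt)", names(x$seqlengths), x$seqlengths),
                    collapse = ", ")))
  invisible(x)
}
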