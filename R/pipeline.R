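#' Pipeline run configuration
#'
#' Assembles every tunable threshold of the analysis with its default:
#' mapping quality >= 10, >= 2 non-genomic clip Ts, 24-nt cluster window,
#' expression filter of 5 reads in at least one sample, p < 0.05,
#' FDR < 0.05, relative-abundance difference > 5%, pseudocount 1. Input
#' paths may point at existing SAM/FASTA/GTF/sample-sheet files, or a
#' `simulate` block (arguments for [sim_config()]) may replace them.
#'
#' @param sam named character vector of per-sample SAM/BAM paths, or `NULL`
#'   to simulate.
#' @param reference_fasta,gtf,sample_sheet input paths (ignored when
#'   simulating).
#' @param simulate `NULL`, or a list of [sim_config()] arguments.
#' @param contrast length-2 character vector of condition names compared in
#'   the APA usage/RED analyses (default: first two conditions seen).
#' @param min_mapq,min_clip_t,cluster_window,min_reads,strict_gt,p_threshold,fdr_threshold,rel_abund_threshold,pseudocount
#'   analysis thresholds (see Details).
#' @param fold_engine `"builtin"` or `"rnafold"`.
#' @param seed integer seed for any simulation randomness.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(sam = NULL, reference_fasta = NULL, gtf = NULL,
                       sample_sheet = NULL, simulate = NULL, contrast = NULL,
                       min_mapq = 10, min_clip_t = 2, cluster_window = 24,
                       min_reads = 5, strict_gt = FALSE, p_threshold = 0.05,
                       fdr_threshold = 0.05, rel_abund_threshold = 0.05,
                       pseudocount = 1, fold_engine = "builtin", seed = 1) {
  stopifnot(min_mapq >= 0, min_clip_t >= 1, cluster_window >= 0,
            min_reads >= 0, p_threshold > 0, fdr_threshold > 0,
            rel_abund_threshold >= 0, pseudocount >= 0)
  structure(list(sam = sam, reference_fasta = reference_fasta, gtf = gtf,
                 sample_sheet = sample_sheet, simulate = simulate,
                 contrast = contrast, min_mapq = min_mapq,
                 min_clip_t = min_clip_t, cluster_window = cluster_window,
                 min_reads = min_reads, strict_gt = strict_gt,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 rel_abund_threshold = rel_abund_threshold,
                 pseudocount = pseudocount, fold_engine = fold_engine,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; a `simulate:` mapping is
#' passed through as [sim_config()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI overrides).
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$sam)) vals$sam <- unlist(vals$sam)
  do.call(run_config, vals)
}

.stage_log <- function(log, stage, t0, msg) {
  line <- sprintf("[%s] %s (%.2f s)", stage, msg,
                  as.numeric(proc.time()[3] - t0))
  cat(line, "\n", sep = "", file = log, append = TRUE)
  invisible(line)
}

#' Run the full stability-analysis pipeline
#'
#' Orchestrates simulate (optional) -> PAS calling -> clustering/assignment
#' -> quantification -> stability -> 3'UTR APA -> intronic APA -> feature
#' regression -> structure scoring, writing every stage's table plus a
#' markdown summary and a structured log into `outdir`. Deterministic given
#' the configuration seed and inputs.
#'
#' With `resume = TRUE`, simulated inputs (and called clusters) already
#' present in `outdir` are reused instead of regenerated; all downstream
#' stages are recomputed, which is cheap and keeps outputs identical to an
#' uninterrupted run.
#'
#' @param config a [run_config()] (or a YAML path).
#' @param outdir output directory.
#' @param resume reuse existing intermediate files in `outdir`.
#' @return invisibly, a list with the main in-memory results
#'   (`clusters`, `fit`, `pairs`, `ipa`, `regression`, `summary`).
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, "run.log")
  if (!resume) unlink(log)
  thr <- config[c("min_mapq", "min_clip_t", "cluster_window", "min_reads",
                  "strict_gt", "p_threshold", "fdr_threshold",
                  "rel_abund_threshold", "pseudocount", "seed")]
  cat(sprintf("threshold %s = %s\n", names(thr), unlist(thr)),
      sep = "", file = log, append = TRUE)

  # -- inputs ----------------------------------------------------------
  t0 <- proc.time()[3]
  simdir <- file.path(outdir, "sim")
  if (!is.null(config$simulate)) {
    paths <- list(gtf = file.path(simdir, "annotation.gtf"),
                  fa = file.path(simdir, "reference.fa"),
                  ss = file.path(simdir, "samples.tsv"),
                  truth = file.path(simdir, "truth.tsv"))
    have <- all(file.exists(unlist(paths))) &&
      length(Sys.glob(file.path(simdir, "*.sam"))) > 0
    if (resume && have) {
      reference <- Biostrings::readDNAStringSet(paths$fa)
      names(reference) <- sub(" .*", "", names(reference))
      annotation <- read_annotation(paths$gtf,
        seqlengths = setNames(Biostrings::width(reference), names(reference)))
      samples <- read_tsv(paths$ss)
      sam_files <- Sys.glob(file.path(simdir, "*.sam"))
      names(sam_files) <- sub("\\.sam$", "", basename(sam_files))
      .stage_log(log, "simulate", t0, "reused existing simulated inputs")
    } else {
      cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
      sim <- simulate_dataset(cfg)
      annotation <- sim$annotation; reference <- sim$reference
      samples <- sim$samples
      reads <- simulate_alignments(sim$counts, annotation, reference, cfg)
      dir.create(simdir, showWarnings = FALSE)
      sam_files <- write_sam_files(reads, simdir, annotation$seqlengths,
                                   sample_ids = samples$sample_id)
      write_gtf(annotation, paths$gtf)
      Biostrings::writeXStringSet(reference, paths$fa)
      write_tsv(samples, paths$ss)
      write_tsv(sim$truth, paths$truth)
      .stage_log(log, "simulate", t0,
                 sprintf("simulated %d genes, %d reads", cfg$n_genes,
                         sum(sim$counts)))
    }
  } else {
    if (is.null(config$sample_sheet) || !file.exists(config$sample_sheet))
      stop("sample sheet not found: ",
           config$sample_sheet %||% "(not specified)")
    samples <- read_tsv(config$sample_sheet)
    reference <- Biostrings::readDNAStringSet(config$reference_fasta)
    names(reference) <- sub(" .*", "", names(reference))
    annotation <- read_annotation(config$gtf,
      seqlengths = setNames(Biostrings::width(reference), names(reference)))
    sam_files <- config$sam
    .stage_log(log, "input", t0, sprintf("loaded %d samples", nrow(samples)))
  }
  missing_samples <- setdiff(samples$sample_id, names(sam_files))
  if (length(missing_samples))
    stop("no alignment file for sample(s): ",
         paste(missing_samples, collapse = ", "))
  conds <- unique(samples$condition)
  contrast <- config$contrast %||% conds[1:2]

  # -- PAS calling + clustering + assignment ---------------------------
  t0 <- proc.time()[3]
  cl_file <- file.path(outdir, "clusters.tsv")
  if (resume && file.exists(cl_file)) {
    clusters <- read_tsv(cl_file)
    rownames(clusters) <- clusters$cluster_id
    .stage_log(log, "callpas", t0, "reused existing clusters")
  } else {
    sites <- call_pas_sites(sam_files[samples$sample_id], reference,
                            min_mapq = config$min_mapq,
                            min_clip_t = config$min_clip_t)
    if (!nrow(sites)) stop("callpas: no PAS reads found")
    cl <- cluster_sites(sites, window = config$cluster_window)
    clusters <- assign_clusters(cl$clusters, annotation)
    write_tsv(clusters, cl_file)
    write_clusters_bed(clusters, file.path(outdir, "clusters.bed"))
    .stage_log(log, "callpas", t0,
               sprintf("%d sites -> %d clusters", nrow(sites), nrow(clusters)))
  }

  # -- quantify --------------------------------------------------------
  t0 <- proc.time()[3]
  counts <- as.matrix(clusters[, samples$sample_id, drop = FALSE])
  counts <- filter_expressed(counts, config$min_reads, config$strict_gt)
  clusters <- clusters[rownames(counts), , drop = FALSE]
  quant <- median_ratio_normalize(counts, samples)
  write_tsv(data.frame(sample_id = names(quant$size_factors),
                       size_factor = quant$size_factors),
            file.path(outdir, "size_factors.tsv"))
  write_tsv(data.frame(cluster_id = rownames(quant$rpm),
                       round(quant$rpm, 4), check.names = FALSE),
            file.path(outdir, "rpm.tsv"))
  .stage_log(log, "quantify", t0,
             sprintf("%d clusters pass the %s%d-read filter",
                     nrow(counts), if (config$strict_gt) ">" else ">=",
                     config$min_reads))

  # -- stability -------------------------------------------------------
  t0 <- proc.time()[3]
  fit <- stability_fit(counts, samples, config$pseudocount, quant = quant)
  st_df <- as.data.frame(fit)
  st_df[-1] <- lapply(st_df[-1], function(v) round(v, 5))
  write_tsv(st_df, file.path(outdir, "stability.tsv"))
  .stage_log(log, "stability", t0,
             sprintf("%d clusters with differential stability (p < %g)",
                     sum(fit$anova$p < config$p_threshold, na.rm = TRUE),
                     config$p_threshold))

  # -- 3'UTR APA -------------------------------------------------------
  t0 <- proc.time()[3]
  total_ids <- samples$sample_id[samples$fraction == "total"]
  pairs <- select_isoform_pairs(clusters, total_ids)
  apa <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    re <- vapply(samples$sample_id, function(s)
      relative_expression(quant$rpm[pairs$dpas_id, s],
                          quant$rpm[pairs$ppas_id, s], config$pseudocount),
      numeric(nrow(pairs)))
    re <- matrix(re, nrow = nrow(pairs),
                 dimnames = list(pairs$gene_id, samples$sample_id))
    cond_re <- vapply(conds, function(cn)
      rowMeans(re[, samples$sample_id[samples$condition == cn &
                                      samples$fraction == "total"],
                  drop = FALSE]), numeric(nrow(pairs)))
    cond_re <- matrix(cond_re, nrow = nrow(pairs),
                      dimnames = list(pairs$gene_id, conds))
    red_contrast <- red(cond_re[, contrast[1]], cond_re[, contrast[2]])
    pool <- function(cn, frac, ids)
      rowSums(counts[ids, samples$sample_id[samples$condition == cn &
                                            samples$fraction == frac],
                     drop = FALSE])
    usage <- apa_usage_test(pool(contrast[1], "total", pairs$ppas_id),
                            pool(contrast[1], "total", pairs$dpas_id),
                            pool(contrast[2], "total", pairs$ppas_id),
                            pool(contrast[2], "total", pairs$dpas_id),
                            config$p_threshold, config$rel_abund_threshold)
    stab <- lapply(conds, function(cn)
      isoform_stability_test(pool(cn, "4sU", pairs$ppas_id),
                             pool(cn, "4sU", pairs$dpas_id),
                             pool(cn, "FT", pairs$ppas_id),
                             pool(cn, "FT", pairs$dpas_id),
                             config$pseudocount, config$fdr_threshold))
    names(stab) <- conds
    apa <- data.frame(pairs, autr_bin = NA_integer_,
                      setNames(as.data.frame(round(cond_re, 5)),
                               paste0("re_", conds)),
                      red_contrast = round(red_contrast, 5), usage,
                      stringsAsFactors = FALSE)
    for (cn in conds) {
      apa[[paste0("delta_ss_", cn)]] <- round(stab[[cn]]$delta_ss, 5)
      apa[[paste0("stab_call_", cn)]] <- stab[[cn]]$call
    }
    if (nrow(pairs) >= 5) {
      mean_dss <- rowMeans(sapply(stab, `[[`, "delta_ss"))
      ab <- quintile_bins(pairs$autr_size, mean_dss,
                          x_name = "autr_size", y_name = "delta_ss")
      apa$autr_bin <- ab$bin
    }
    write_tsv(apa, file.path(outdir, "apa_pairs.tsv"))
  }
  .stage_log(log, "apa", t0,
             sprintf("%d genes with >= 2 terminal-exon PAS isoforms",
                     if (is.null(pairs)) 0L else nrow(pairs)))

  # -- intronic APA ----------------------------------------------------
  t0 <- proc.time()[3]
  ipa <- ipa_analysis(clusters, fit, annotation, samples,
                      pseudocount = config$pseudocount)
  if (!is.null(ipa$events)) {
    ev <- ipa$events
    num <- vapply(ev, is.numeric, logical(1))
    ev[num] <- lapply(ev[num], function(v) round(v, 5))
    write_tsv(ev, file.path(outdir, "ipa_events.tsv"))
  }
  .stage_log(log, "ipa", t0,
             sprintf("%d IPA events",
                     if (is.null(ipa$events)) 0L else nrow(ipa$events)))

  # -- feature regression ----------------------------------------------
  t0 <- proc.time()[3]
  feats <- compute_features(annotation, reference, clusters)
  gene_counts <- aggregate_to_genes(counts, clusters$gene_id)
  gene_fit <- stability_fit(gene_counts, samples, config$pseudocount)
  gene_ss <- rowMeans(gene_fit$mean_ss)
  common <- intersect(feats$gene_id, names(gene_ss))
  X <- feats[match(common, feats$gene_id),
             setdiff(names(feats), "gene_id"), drop = FALSE]
  X <- X[, colSums(!is.na(X)) == nrow(X), drop = FALSE]  # drop all-NA/partial
  regression <- NULL
  if (ncol(X) >= 2 && length(common) > ncol(X) + 1) {
    regression <- regression_rank(X, gene_ss[common])
    write_tsv(as.data.frame(lapply(regression, function(v)
      if (is.numeric(v)) round(v, 5) else v)),
      file.path(outdir, "regression.tsv"))
  }
  nf <- as.data.frame(lapply(feats, function(v)
    if (is.numeric(v)) round(v, 5) else v))
  write_tsv(nf, file.path(outdir, "features.tsv"))
  .stage_log(log, "features", t0,
             sprintf("%d genes with feature vectors", nrow(feats)))

  # -- structure -------------------------------------------------------
  t0 <- proc.time()[3]
  engine <- if (identical(config$fold_engine, "rnafold")) rnafold_engine()
            else builtin_fold_engine()
  utr3 <- utr3_sequences(annotation, reference, clusters)
  structure_tab <- structure_profile(utr3, engine)
  structure_tab$median_mfe <- round(structure_tab$median_mfe, 4)
  write_tsv(structure_tab, file.path(outdir, "structure.tsv"))
  .stage_log(log, "structure", t0,
             sprintf("%d 3'UTRs scored with the %s engine",
                     nrow(structure_tab), engine$name))

  # -- summary ---------------------------------------------------------
  t0 <- proc.time()[3]
  gene_types <- annotation$genes$gene_type[
    match(clusters$gene_id, annotation$genes$gene_id)]
  type_ss <- tapply(rowMeans(fit$mean_ss), gene_types,
                    stats::median, na.rm = TRUE)
  summ <- list(
    n_pas_clusters = nrow(clusters),
    n_tpa = sum(clusters$region_class == "TPA", na.rm = TRUE),
    n_ipa = sum(clusters$region_class == "IPA", na.rm = TRUE),
    n_genes_apa = if (is.null(pairs)) 0L else nrow(pairs),
    n_diff_stability = sum(fit$anova$p < config$p_threshold, na.rm = TRUE)
  )
  for (cn in conds)
    summ[[paste0("median_re_", cn)]] <-
      if (is.null(apa)) NA_real_ else
        round(stats::median(apa[[paste0("re_", cn)]], na.rm = TRUE), 4)
  for (cn in conds) {
    calls <- if (is.null(apa)) character(0) else apa[[paste0("stab_call_", cn)]]
    nb <- sum(calls == "blue", na.rm = TRUE)
    nr <- sum(calls == "red", na.rm = TRUE)
    summ[[paste0("blue_", cn)]] <- nb
    summ[[paste0("red_", cn)]] <- nr
    summ[[paste0("blue_red_ratio_", cn)]] <-
      if (nr > 0) round(nb / nr, 4) else NA_real_
  }
  summ$median_delta_ss_ipa <- if (is.null(ipa$events)) NA_real_ else
    round(stats::median(ipa$events$mean_delta_ss, na.rm = TRUE), 4)
  for (ty in names(type_ss))
    summ[[paste0("median_ss_", ty)]] <- round(unname(type_ss[[ty]]), 4)
  summ_df <- data.frame(metric = names(summ),
                        value = unlist(lapply(summ, format, digits = 8)),
                        stringsAsFactors = FALSE)
  write_tsv(summ_df, file.path(outdir, "summary.tsv"))
  md <- c("# Pipeline summary", "",
          sprintf("- %s: %s", summ_df$metric, summ_df$value))
  writeLines(md, file.path(outdir, "summary.md"))
  .stage_log(log, "summary", t0, "summary written")

  invisible(list(clusters = clusters, fit = fit, pairs = pairs, apa = apa,
                 ipa = ipa, regression = regression,
                 structure = structure_tab, summary = summ,
                 samples = samples, annotation = annotation))
}
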