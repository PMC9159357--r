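#' Filter PAS clusters by minimum expression
#'
#' Keeps rows supported by at least `min_reads` reads in at least one sample
#' (the expression-evidence filter). With `strict_gt = TRUE` the rule becomes
#' strictly greater than `min_reads`.
#'
#' @param counts integer matrix (rows = PAS clusters, columns = samples).
#' @param min_reads threshold (default 5).
#' @param strict_gt require `> min_reads` instead of `>= min_reads`.
#' @return the row-subset matrix.
#' @export
filter_expressed <- function(counts, min_reads = 5, strict_gt = FALSE) {
  if (!nrow(counts)) return(counts)
  mx <- apply(counts, 1, max)
  keep <- if (strict_gt) mx > min_reads else mx >= min_reads
  counts[keep, , drop = FALSE]
}

.median_ratio_sf <- function(counts) {
  # median-of-ratios size factors (DESeq); rows with any zero are excluded
  # from factor estimation
  sf <- tryCatch(DESeq2::estimateSizeFactorsForMatrix(counts),
                 error = function(e) NULL)
  if (is.null(sf) || any(!is.finite(sf)) || any(sf <= 0))
    stop("no rows with all-positive counts; median-ratio factors undefined - ",
         "fall back to library-size scaling")
  sf
}

#' Median-ratio normalization of a PAS count matrix
#'
#' Computes per-sample size factors by the median-of-ratios method (each
#' sample's median ratio of counts to the per-row geometric mean, over rows
#' with no zeros; factors are then rescaled to geometric mean 1 within each
#' normalization set, which makes renormalization of factor-divided counts
#' return unit factors exactly), divides counts by them, and expresses the
#' result on an
#' RPM scale using one common per-million constant per normalization set
#' (10^6 / mean raw library size of the set). A common constant - rather
#' than each sample's own normalized total - preserves the median-ratio
#' cross-sample ratios; rescaling every sample to its own per-million would
#' cancel the size factors exactly and reintroduce composition bias. By
#' default size factors are estimated within fraction type (total, 4sU and
#' FT samples form separate normalization sets), since library composition
#' differs grossly between fractions; set `by_fraction = FALSE` for one
#' global set.
#'
#' @param counts integer matrix, clusters x samples.
#' @param samples optional sample sheet (`sample_id`, `fraction`) used when
#'   `by_fraction = TRUE`.
#' @param by_fraction estimate size factors within fraction type.
#' @return list of class `"pas_quant"`: `size_factors`, `normalized`, `rpm`.
#' @export
median_ratio_normalize <- function(counts, samples = NULL, by_fraction = !is.null(samples)) {
  if (!nrow(counts)) stop("empty count matrix")
  sf <- scale_const <- rep(NA_real_, ncol(counts))
  names(sf) <- colnames(counts)
  if (by_fraction) {
    if (is.null(samples)) stop("samples sheet required for by_fraction = TRUE")
    fr <- samples$fraction[match(colnames(counts), samples$sample_id)]
    if (any(is.na(fr))) stop("samples sheet does not cover all count columns")
    for (f in unique(fr)) {
      j <- which(fr == f)
      s <- .median_ratio_sf(counts[, j, drop = FALSE])
      sf[j] <- s / exp(mean(log(s)))     # geometric mean 1 per set
      scale_const[j] <- 1e6 / mean(colSums(counts[, j, drop = FALSE]))
    }
  } else {
    s <- .median_ratio_sf(counts)
    sf[] <- s / exp(mean(log(s)))
    scale_const[] <- 1e6 / mean(colSums(counts))
  }
  normalized <- sweep(counts, 2, sf, "/")
  rpm <- sweep(normalized, 2, scale_const, "*")
  structure(list(size_factors = sf, normalized = normalized, rpm = rpm),
            class = "pas_quant")
}

#' @export
print.pas_quant <- function(x, ...) {
  cat(sprintf("pas_quant: %d clusters x %d samples\n",
              nrow(x$rpm), ncol(x$rpm)))
  cat("size factors:\n")
  print(round(x$size_factors, 4))
  invisible(x)
}

#' Sum a PAS-level count matrix to gene level
#'
#' @param counts clusters x samples matrix.
#' @param gene_id gene assignment per row (NA rows dropped).
#' @return genes x samples matrix.
#' @export
aggregate_to_genes <- function(counts, gene_id) {
  keep <- !is.na(gene_id)
  rowsum(counts[keep, , drop = FALSE], gene_id[keep])
}
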