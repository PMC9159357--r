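#' Stability Score
#'
#' `SS = log2((FT_rpm + pseudocount) / (fourSU_rpm + pseudocount))`: the log2
#' ratio of a transcript's abundance in the pre-existing (flow-through) RNA
#' fraction to its abundance in the newly made (4sU-labeled) fraction. Higher
#' values mean more stable RNA. The default pseudocount of 1 RPM-unit keeps
#' the score finite at zero counts.
#'
#' @param ft_rpm,fsu_rpm non-negative abundances (RPM) in the FT and 4sU
#'   fractions; vectorized.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return numeric Stability Score(s); `NA` where both inputs are zero and
#'   the pseudocount is 0.
#' @export
stability_score <- function(ft_rpm, fsu_rpm, pseudocount = 1) {
  if (any(ft_rpm < 0, na.rm = TRUE) || any(fsu_rpm < 0, na.rm = TRUE))
    stop("RPM values must be >= 0")
  ss <- log2((ft_rpm + pseudocount) / (fsu_rpm + pseudocount))
  ss[!is.finite(ss)] <- NA_real_
  ss
}

#' Stability Score difference
#'
#' Antisymmetric difference of two Stability Scores, used both between
#' isoforms (distal minus proximal) and between conditions.
#'
#' @param ss_a,ss_b Stability Scores.
#' @return `ss_a - ss_b` (missing where either input is missing).
#' @export
delta_ss <- function(ss_a, ss_b) ss_a - ss_b

#' One-way ANOVA for differential stability across conditions
#'
#' Fixed-effects one-way ANOVA of replicate Stability Scores across
#' conditions, via [stats::oneway.test()] with equal variances (the classical
#' F test with (g-1, N-g) degrees of freedom). Degenerate inputs with zero
#' between- and within-group variance return F = 0, p = 1 by convention.
#'
#' @param values numeric vector of replicate values.
#' @param groups condition labels, same length.
#' @return named numeric `c(F, p)`.
#' @export
anova_differential <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 conditions")
  if (any(table(groups) < 2)) stop("need >= 2 replicates per condition")
  gm <- tapply(values, groups, mean)
  ssb <- sum(table(groups) * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0 && ssb == 0) return(c(F = 0, p = 1))
  if (ssw == 0) return(c(F = Inf, p = 0))
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  c(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Per-cluster stability analysis across conditions
#'
#' Normalizes counts (median-ratio, within fraction type), computes one
#' Stability Score per (condition, replicate) from matched FT/4sU samples,
#' averages replicates per condition, and tests for differential stability
#' across conditions by one-way ANOVA on the replicate scores (raw p plus BH
#' adjusted q).
#'
#' @param counts integer matrix, clusters (or genes) x samples.
#' @param samples sample sheet with `sample_id`, `condition`, `fraction`,
#'   `replicate`; every (condition, replicate) must have both an `FT` and a
#'   `4sU` sample.
#' @param pseudocount passed to [stability_score()].
#' @param quant optional precomputed [median_ratio_normalize()] result.
#' @return object of class `"stability_fit"`: list with `ss` (replicate-level
#'   score matrix), `mean_ss` (clusters x conditions), `anova` (data.frame
#'   `F`, `p`, `q`), `samples`, `pseudocount`.
#' @export
stability_fit <- function(counts, samples, pseudocount = 1, quant = NULL) {
  if (is.null(quant)) quant <- median_ratio_normalize(counts, samples)
  rpm <- quant$rpm
  conds <- unique(samples$condition)
  pairs <- unique(samples[samples$fraction %in% c("FT", "4sU"),
                          c("condition", "replicate")])
  pairs <- pairs[order(match(pairs$condition, conds), pairs$replicate), ]
  ss <- matrix(NA_real_, nrow(rpm), nrow(pairs),
               dimnames = list(rownames(rpm),
                               paste(pairs$condition, pairs$replicate, sep = "_")))
  for (i in seq_len(nrow(pairs))) {
    ft_id <- samples$sample_id[samples$condition == pairs$condition[i] &
                               samples$replicate == pairs$replicate[i] &
                               samples$fraction == "FT"]
    su_id <- samples$sample_id[samples$condition == pairs$condition[i] &
                               samples$replicate == pairs$replicate[i] &
                               samples$fraction == "4sU"]
    if (length(ft_id) != 1 || length(su_id) != 1)
      stop("condition ", pairs$condition[i], " replicate ", pairs$replicate[i],
           " lacks a matched FT/4sU sample pair")
    ss[, i] <- stability_score(rpm[, ft_id], rpm[, su_id], pseudocount)
  }
  mean_ss <- sapply(conds, function(cn)
    rowMeans(ss[, pairs$condition == cn, drop = FALSE]))
  if (is.null(dim(mean_ss))) mean_ss <- matrix(mean_ss, ncol = length(conds),
                                               dimnames = list(rownames(ss), conds))
  grp <- pairs$condition
  test <- if (length(conds) >= 2 && all(table(grp) >= 2)) {
    t(apply(ss, 1, function(v) anova_differential(v, grp)))
  } else {
    matrix(NA_real_, nrow(ss), 2, dimnames = list(NULL, c("F", "p")))
  }
  anova <- data.frame(F = test[, 1], p = test[, 2],
                      q = stats::p.adjust(test[, 2], "BH"),
                      row.names = rownames(ss))
  structure(list(ss = ss, mean_ss = mean_ss, anova = anova,
                 samples = samples, pairs = pairs, pseudocount = pseudocount,
                 quant = quant),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("stability_fit: %d clusters, %d conditions x %d replicate pairs\n",
              nrow(x$ss), ncol(x$mean_ss), max(table(x$pairs$condition))))
  sig <- sum(x$anova$p < 0.05, na.rm = TRUE)
  cat(sprintf("differential stability (ANOVA p < 0.05): %d clusters\n", sig))
  invisible(x)
}

#' @export
summary.stability_fit <- function(object, ...) {
  cat("Mean Stability Score by condition:\n")
  print(round(apply(object$mean_ss, 2, stats::quantile,
                    c(0.25, 0.5, 0.75), na.rm = TRUE), 3))
  cat(sprintf("\nANOVA: %d / %d clusters with p < 0.05 (%d with q < 0.05)\n",
              sum(object$anova$p < 0.05, na.rm = TRUE), nrow(object$anova),
              sum(object$anova$q < 0.05, na.rm = TRUE)))
  invisible(object)
}

#' @export
coef.stability_fit <- function(object, ...) object$mean_ss

#' Export a stability fit as a flat table
#'
#' @param x a `stability_fit`.
#' @param ... unused.
#' @return data.frame with id, replicate scores, condition means, F, p, q.
#' @export
as.data.frame.stability_fit <- function(x, ...) {
  data.frame(id = rownames(x$ss), x$ss,
              setNames(as.data.frame(x$mean_ss),
                       paste0("mean_", colnames(x$mean_ss))),
              x$anova, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Compare two groups of values
#'
#' Two-sided comparison by Wilcoxon rank-sum, two-sample Kolmogorov-Smirnov,
#' one-way ANOVA, or Fisher's exact test (for two count vectors of length 2).
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @param test one of `"wilcoxon"`, `"ks"`, `"anova"`, `"fisher"`.
#' @return list of class `"group_comparison"`: `test`, `statistic`, `p.value`,
#'   `n` (group sizes).
#' @export
group_compare <- function(values_a, values_b,
                          test = c("wilcoxon", "ks", "anova", "fisher")) {
  test <- match.arg(test)
  if (!length(values_a) || !length(values_b)) stop("empty group")
  res <- switch(test,
    wilcoxon = suppressWarnings(stats::wilcox.test(values_a, values_b)),
    ks = suppressWarnings(stats::ks.test(values_a, values_b)),
    anova = {
      v <- c(values_a, values_b)
      g <- rep(c("a", "b"), c(length(values_a), length(values_b)))
      st <- anova_differential(v, g)
      list(statistic = st[["F"]], p.value = st[["p"]])
    },
    fisher = stats::fisher.test(rbind(values_a, values_b)))
  structure(list(test = test, statistic = unname(res$statistic %||% NA_real_),
                 p.value = unname(res$p.value),
                 n = c(length(values_a), length(values_b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %s, p = %.4g (n = %d vs %d)\n", x$test,
              format(x$statistic, digits = 4), x$p.value, x$n[1], x$n[2]))
  invisible(x)
}
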