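#' Select the top-two 3'UTR isoforms per gene
#'
#' For each gene with at least two terminal-exon (TPA) PAS clusters, ranks
#' clusters by combined expression (summed counts over `basis_samples`,
#' normally all total-fraction samples across conditions), takes the top two,
#' and labels them proximal (pPAS) / distal (dPAS) by strand-aware genomic
#' order. Ties in expression are broken toward the more proximal cluster.
#' The aUTR size is the genomic distance between the two summit positions.
#'
#' @param clusters assigned cluster data.frame (with per-sample count
#'   columns, `gene_id`, `region_class`, `summit`, `strand`).
#' @param basis_samples character vector of count-column names to sum for the
#'   expression ranking.
#' @return data.frame with one row per gene: `gene_id`, `ppas_id`, `dpas_id`,
#'   `ppas_summit`, `dpas_summit`, `strand`, `autr_size`.
#' @export
select_isoform_pairs <- function(clusters, basis_samples) {
  stopifnot(all(basis_samples %in% names(clusters)))
  tpa <- clusters[!is.na(clusters$region_class) & clusters$region_class == "TPA", ]
  if (!nrow(tpa)) return(NULL)
  expr <- rowSums(as.matrix(tpa[, basis_samples, drop = FALSE]))
  out <- lapply(split(seq_len(nrow(tpa)), tpa$gene_id), function(idx) {
    if (length(idx) < 2) return(NULL)
    st <- tpa$strand[idx[1]]
    # proximal = 5'-most on the transcript strand
    prox_rank <- if (st == "+") rank(tpa$summit[idx], ties.method = "first")
                 else rank(-tpa$summit[idx], ties.method = "first")
    ord <- idx[order(-expr[idx], prox_rank)]
    top2 <- ord[1:2]
    top2 <- top2[order(if (st == "+") tpa$summit[top2] else -tpa$summit[top2])]
    data.frame(gene_id = tpa$gene_id[idx[1]],
               ppas_id = tpa$cluster_id[top2[1]],
               dpas_id = tpa$cluster_id[top2[2]],
               ppas_summit = tpa$summit[top2[1]],
               dpas_summit = tpa$summit[top2[2]],
               strand = st,
               autr_size = abs(tpa$summit[top2[2]] - tpa$summit[top2[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(out)) rownames(out) <- out$gene_id
  out
}

#' Relative expression of distal versus proximal isoform
#'
#' `RE = log2((dPAS_rpm + pc) / (pPAS_rpm + pc))`; positive values mean the
#' long-3'UTR isoform dominates.
#'
#' @param d_rpm,p_rpm distal / proximal isoform abundances (RPM).
#' @param pseudocount added to both (default 1).
#' @return numeric RE value(s).
#' @export
relative_expression <- function(d_rpm, p_rpm, pseudocount = 1) {
  if (any(d_rpm < 0, na.rm = TRUE) || any(p_rpm < 0, na.rm = TRUE))
    stop("RPM values must be >= 0")
  log2((d_rpm + pseudocount) / (p_rpm + pseudocount))
}

#' Relative expression difference between two samples or conditions
#'
#' `RED = RE_a - RE_b`; positive values indicate 3'UTR lengthening in `a`
#' relative to `b`. Antisymmetric.
#'
#' @param re_a,re_b RE values.
#' @return numeric RED value(s).
#' @export
red <- function(re_a, re_b) re_a - re_b

#' Differential APA isoform usage between two samples
#'
#' Per gene, a two-sided Fisher's exact test on the 2x2 table
#' `[pPAS, dPAS] x [sample1, sample2]` of raw counts, plus the change in
#' relative abundance of the distal isoform `d/(p+d)`. An event is called
#' `lengthened` / `shortened` (in sample 2 relative to sample 1) iff
#' `p < p_threshold` and the absolute relative-abundance difference exceeds
#' `min_rel_diff`. BH-adjusted q values are reported across genes.
#'
#' @param p1,d1 proximal/distal counts in sample (or condition) 1; vectors
#'   over genes.
#' @param p2,d2 same for sample 2.
#' @param p_threshold significance threshold on the raw Fisher p (default
#'   0.05).
#' @param min_rel_diff minimum absolute relative-abundance difference
#'   (default 0.05).
#' @return data.frame: `p`, `q`, `rel1`, `rel2`, `rel_diff` (`rel2 - rel1`),
#'   `call`.
#' @export
apa_usage_test <- function(p1, d1, p2, d2, p_threshold = 0.05,
                           min_rel_diff = 0.05) {
  n <- length(p1)
  stopifnot(length(d1) == n, length(p2) == n, length(d2) == n)
  pv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tab <- matrix(c(p1[i], d1[i], p2[i], d2[i]), 2)
    if (sum(tab) == 0) next
    pv[i] <- stats::fisher.test(tab)$p.value
  }
  rel1 <- ifelse(p1 + d1 > 0, d1 / (p1 + d1), NA_real_)
  rel2 <- ifelse(p2 + d2 > 0, d2 / (p2 + d2), NA_real_)
  diff <- rel2 - rel1
  call <- rep("unchanged", n)
  sig <- !is.na(pv) & pv < p_threshold & !is.na(diff) & abs(diff) > min_rel_diff
  call[sig & diff > 0] <- "lengthened"
  call[sig & diff < 0] <- "shortened"
  call[is.na(pv)] <- NA_character_
  data.frame(p = pv, q = stats::p.adjust(pv, "BH"), rel1 = rel1, rel2 = rel2,
             rel_diff = diff, call = call, stringsAsFactors = FALSE)
}

#' Differential stability of distal versus proximal isoform
#'
#' Per gene and condition, a two-sided Fisher's exact test on the 2x2 table
#' `[pPAS, dPAS] x [4sU, FT]` of replicate-pooled counts. The isoform
#' Stability Score difference `delta_ss = SS(dPAS) - SS(pPAS)` gives the
#' direction (fraction-level scale factors cancel in this within-sample
#' contrast, so pooled counts with a pseudocount are used). Genes with
#' `FDR < fdr_threshold` are called `red` (distal more stable, delta_ss > 0)
#' or `blue` (proximal more stable).
#'
#' @param p_4su,d_4su,p_ft,d_ft replicate-pooled counts per gene in the 4sU
#'   and FT fractions of one condition.
#' @param pseudocount for the delta-SS computation (default 1).
#' @param fdr_threshold BH FDR threshold for calls (default 0.05).
#' @return data.frame: `delta_ss`, `p`, `q`, `call`.
#' @export
isoform_stability_test <- function(p_4su, d_4su, p_ft, d_ft, pseudocount = 1,
                                   fdr_threshold = 0.05) {
  n <- length(p_4su)
  pv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tab <- matrix(c(p_4su[i], d_4su[i], p_ft[i], d_ft[i]), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    pv[i] <- stats::fisher.test(tab)$p.value
  }
  dss <- log2((d_ft + pseudocount) / (d_4su + pseudocount)) -
         log2((p_ft + pseudocount) / (p_4su + pseudocount))
  q <- stats::p.adjust(pv, "BH")
  call <- rep("unchanged", n)
  call[!is.na(q) & q < fdr_threshold & dss > 0] <- "red"
  call[!is.na(q) & q < fdr_threshold & dss < 0] <- "blue"
  call[is.na(pv)] <- NA_character_
  data.frame(delta_ss = dss, p = pv, q = q, call = call,
             stringsAsFactors = FALSE)
}

#' Quintile binning of a variable with a per-bin response
#'
#' Rank-based split into `n_bins` bins of (near-)equal size, ordered by the
#' binning variable (sizes differ by at most 1; ties keep stable input
#' order). The response distribution of the first and last bins is compared
#' by a two-sided Wilcoxon rank-sum test.
#'
#' @param x binning variable (>= `n_bins` finite values required).
#' @param y response analyzed per bin (defaults to `x` itself).
#' @param n_bins number of bins (default 5).
#' @param x_name,y_name labels for reporting.
#' @return list of class `"bin_analysis"`: `bin` (integer bin per input
#'   element, NA where `x` is not finite), `stats` (per-bin n, median and
#'   mean of `y`), `test` (bin 1 vs bin `n_bins` [group_compare()]).
#' @export
quintile_bins <- function(x, y = x, n_bins = 5, x_name = "x", y_name = "y") {
  fin <- which(is.finite(x))
  if (length(fin) < n_bins) stop("need at least ", n_bins, " finite values")
  ord <- fin[order(x[fin])]              # stable for ties
  n <- length(ord)
  bounds <- floor(seq(0, n, length.out = n_bins + 1))
  bin <- rep(NA_integer_, length(x))
  for (b in seq_len(n_bins))
    bin[ord[(bounds[b] + 1):bounds[b + 1]]] <- b
  stats_df <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    yy <- y[which(bin == b)]
    data.frame(bin = b, n = length(yy),
               x_median = stats::median(x[which(bin == b)], na.rm = TRUE),
               y_median = stats::median(yy, na.rm = TRUE),
               y_mean = mean(yy, na.rm = TRUE))
  }))
  test <- group_compare(y[which(bin == 1)], y[which(bin == n_bins)],
                        "wilcoxon")
  structure(list(bin = bin, stats = stats_df, test = test,
                 x_name = x_name, y_name = y_name),
            class = "bin_analysis")
}

#' @export
print.bin_analysis <- function(x, ...) {
  cat(sprintf("bin_analysis of %s by %s quintiles\n", x$y_name, x$x_name))
  print(x$stats, row.names = FALSE)
  cat(sprintf("bin 1 vs bin %d: Wilcoxon p = %.4g\n",
              max(x$stats$bin), x$test$p.value))
  invisible(x)
}

#' Intronic polyadenylation isoform analysis
#'
#' For every gene carrying at least one intronic (IPA) and one terminal-exon
#' (TPA) PAS cluster, pairs each IPA cluster with a reference TPA isoform
#' (the most abundant TPA cluster by default, or the sum of all TPA
#' clusters), and reports the per-condition Stability Score difference
#' `delta_ss = SS(IPA) - SS(TPA)` along with the relative abundance
#' `log2(IPA / TPA)` in the total fraction. Quintile-bin analyses relate the
#' IPA isoform's mean SS to host-intron size and splice-site strengths.
#'
#' @param clusters assigned cluster data.frame with count columns.
#' @param fit a [stability_fit()] on the same clusters.
#' @param annotation a `genome_annotation` (host-intron sizes and splice
#'   scores).
#' @param samples sample sheet.
#' @param tpa_ref `"top"` (most abundant TPA cluster) or `"sum"` (all TPA
#'   clusters pooled; delta-SS then uses the abundance-weighted pool).
#' @param pseudocount for the pooled-count SS in `tpa_ref = "sum"` mode.
#' @return list of class `"ipa_analysis"`: `events` data.frame and `bins`
#'   (quintile [quintile_bins()] analyses by intron size, 5'SS and 3'SS
#'   score, where available).
#' @export
ipa_analysis <- function(clusters, fit, annotation, samples,
                         tpa_ref = c("top", "sum"), pseudocount = 1) {
  tpa_ref <- match.arg(tpa_ref)
  ipa <- clusters[!is.na(clusters$region_class) & clusters$region_class == "IPA", ]
  if (!nrow(ipa))
    return(structure(list(events = NULL, bins = list()), class = "ipa_analysis"))
  tpa <- clusters[!is.na(clusters$region_class) & clusters$region_class == "TPA", ]
  total_ids <- samples$sample_id[samples$fraction == "total"]
  conds <- colnames(fit$mean_ss)

  events <- lapply(seq_len(nrow(ipa)), function(i) {
    gt <- tpa[tpa$gene_id == ipa$gene_id[i], ]
    if (!nrow(gt)) return(NULL)
    if (tpa_ref == "top") {
      ref_id <- gt$cluster_id[which.max(gt$total)]
      dss <- fit$mean_ss[ipa$cluster_id[i], ] - fit$mean_ss[ref_id, ]
      tpa_total <- sum(as.matrix(gt[gt$cluster_id == ref_id, total_ids]))
    } else {
      ref_id <- "TPA_sum"
      # pool TPA counts per fraction/condition, SS from pooled rpm-equivalents
      dss <- vapply(conds, function(cn) {
        su <- samples$sample_id[samples$condition == cn & samples$fraction == "4sU"]
        ft <- samples$sample_id[samples$condition == cn & samples$fraction == "FT"]
        ipa_ss <- fit$mean_ss[ipa$cluster_id[i], cn]
        pool_ft <- sum(fit$quant$rpm[gt$cluster_id, ft])
        pool_su <- sum(fit$quant$rpm[gt$cluster_id, su])
        ipa_ss - log2((pool_ft / length(ft) + pseudocount) /
                      (pool_su / length(su) + pseudocount))
      }, numeric(1))
      tpa_total <- sum(as.matrix(gt[, total_ids]))
    }
    ipa_total <- sum(as.matrix(ipa[i, total_ids]))
    it <- annotation$introns[annotation$introns$gene_id == ipa$gene_id[i] &
                             annotation$introns$rank == ipa$host_intron[i], ]
    data.frame(gene_id = ipa$gene_id[i], ipa_id = ipa$cluster_id[i],
               tpa_ref = ref_id, host_intron = ipa$host_intron[i],
               intron_size = if (nrow(it)) it$size[1] else NA_integer_,
               ss5_score = if (nrow(it)) it$ss5_score[1] else NA_real_,
               ss3_score = if (nrow(it)) it$ss3_score[1] else NA_real_,
               rel_abundance = log2((ipa_total + pseudocount) /
                                    (tpa_total + pseudocount)),
               mean_ss_ipa = mean(fit$mean_ss[ipa$cluster_id[i], ]),
               t(setNames(dss, paste0("delta_ss_", conds))),
               mean_delta_ss = mean(dss),
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, events)
  bins <- list()
  if (!is.null(events) && nrow(events) >= 5) {
    for (v in c("intron_size", "ss5_score", "ss3_score")) {
      if (all(is.na(events[[v]]))) {
        warning("missing ", v, "; bin analysis skipped")
        next
      }
      bins[[v]] <- quintile_bins(events[[v]], events$mean_ss_ipa,
                                 x_name = v, y_name = "mean_ss_ipa")
    }
  }
  structure(list(events = events, bins = bins), class = "ipa_analysis")
}

#' @export
print.ipa_analysis <- function(x, ...) {
  if (is.null(x$events)) {
    cat("ipa_analysis: no IPA events\n")
    return(invisible(x))
  }
  cat(sprintf("ipa_analysis: %d IPA events in %d genes\n", nrow(x$events),
              length(unique(x$events$gene_id))))
  cat(sprintf("median delta SS (IPA - TPA): %.3f\n",
              stats::median(x$events$mean_delta_ss, na.rm = TRUE)))
  invisible(x)
}
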