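.region_seqs <- function(reference, chrom, start0, end0, strand) {
  # sense-strand sequences for 0-based half-open genomic intervals
  refstr <- setNames(as.character(reference), names(reference))
  s <- substring(refstr[chrom], start0 + 1L, end0)
  x <- Biostrings::DNAStringSet(s)
  neg <- strand == "-"
  if (any(neg)) x[neg] <- Biostrings::reverseComplement(x[neg])
  x
}

.base_content <- function(seqs) {
  f <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  n <- pmax(rowSums(f), 1L)
  data.frame(gc = (f[, "C"] + f[, "G"]) / n, u = f[, "T"] / n,
             a = f[, "A"] / n, g = f[, "G"] / n, c = f[, "C"] / n)
}

.gene_regions <- function(annotation, clusters = NULL) {
  # per-gene genomic intervals (0-based half-open) of gene body, 3'-most
  # exon, 3'UTR (3'-most exon start to distal PAS) and aUTR (pPAS to dPAS)
  g <- annotation$genes
  if (!is.null(clusters)) {
    tp <- clusters[!is.na(clusters$region_class) & clusters$region_class == "TPA",
                   c("gene_id", "summit")]
    names(tp) <- c("gene_id", "position")
  } else {
    tp <- annotation$pas[annotation$pas$region_class == "TPA",
                         c("gene_id", "position")]
  }
  le <- annotation$exons[annotation$exons$is_last, ]
  ex_w <- tapply(annotation$exons$end - annotation$exons$start,
                 annotation$exons$gene_id, sum)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gid <- g$gene_id[i]; st <- g$strand[i]
    pp <- tp$position[tp$gene_id == gid]
    if (!length(pp)) return(NULL)
    lex <- le[le$gene_id == gid, ]
    pp <- if (st == "+") sort(pp) else sort(pp, decreasing = TRUE)
    dpas <- pp[length(pp)]; ppas <- pp[1]
    utr3 <- if (st == "+") c(lex$start, dpas + 1L) else c(dpas, lex$end)
    autr <- if (length(pp) >= 2) {
      if (st == "+") c(ppas + 1L, dpas + 1L) else c(dpas, ppas)
    } else c(NA_integer_, NA_integer_)
    if (utr3[2] <= utr3[1]) return(NULL)
    data.frame(gene_id = gid, chrom = g$chrom[i], strand = st,
               gene_start = g$start[i], gene_end = g$end[i],
               utr3_start = utr3[1], utr3_end = utr3[2],
               autr_start = autr[1], autr_end = autr[2],
               lastexon_start = lex$start, lastexon_end = lex$end,
               n_exons = g$n_exons[i], mature_len = unname(ex_w[gid]),
               pas_count_utr3 = length(pp), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) stop("no genes with a defined 3'UTR")
  d
}

#' Extract 3'UTR sequences (sense strand)
#'
#' The 3'UTR of each gene runs from the 3'-most exon start to the distal PAS
#' (annotated PAS, or TPA cluster summits when `clusters` is given).
#'
#' @param annotation a `genome_annotation`.
#' @param reference [Biostrings::DNAStringSet].
#' @param clusters optional assigned cluster data.frame.
#' @return named character vector of sense-strand sequences (names =
#'   gene ids).
#' @export
utr3_sequences <- function(annotation, reference, clusters = NULL) {
  d <- .gene_regions(annotation, clusters)
  s <- .region_seqs(reference, d$chrom, d$utr3_start, d$utr3_end, d$strand)
  setNames(as.character(s), d$gene_id)
}

#' Per-gene sequence and architecture features
#'
#' Computes, on the transcribed (sense) strand: GC and U content of the gene
#' body, 3'-most exon, 3'UTR (3'-most exon start to the distal PAS) and aUTR
#' (proximal-to-distal PAS interval, multi-PAS genes only); region sizes;
#' exon-junction density (junctions per kb of mature transcript); and the
#' number of terminal-exon PASs. PAS positions come from `clusters` (summits
#' of assigned TPA clusters) when given, otherwise from the annotation's PAS
#' records.
#'
#' @param annotation a `genome_annotation`.
#' @param reference [Biostrings::DNAStringSet].
#' @param clusters optional assigned cluster data.frame; its TPA summits
#'   replace annotated PAS positions.
#' @return data.frame, one row per gene with a defined 3'UTR.
#' @export
compute_features <- function(annotation, reference, clusters = NULL) {
  d <- .gene_regions(annotation, clusters)

  bad <- d$gene_start < 0 | d$gene_end > annotation$seqlengths[d$chrom]
  if (any(bad)) stop("region outside reference for gene(s): ",
                     paste(d$gene_id[bad], collapse = ", "))
  gene_c <- .base_content(.region_seqs(reference, d$chrom, d$gene_start,
                                       d$gene_end, d$strand))
  le_c <- .base_content(.region_seqs(reference, d$chrom, d$lastexon_start,
                                     d$lastexon_end, d$strand))
  u3_c <- .base_content(.region_seqs(reference, d$chrom, d$utr3_start,
                                     d$utr3_end, d$strand))
  has_autr <- !is.na(d$autr_start)
  au_c <- data.frame(gc = rep(NA_real_, nrow(d)), u = NA_real_)
  if (any(has_autr))
    au_c[has_autr, c("gc", "u")] <-
      .base_content(.region_seqs(reference, d$chrom[has_autr],
                                 d$autr_start[has_autr], d$autr_end[has_autr],
                                 d$strand[has_autr]))[, c("gc", "u")]

  data.frame(gene_id = d$gene_id,
             gene_GC = gene_c$gc, lastexon_GC = le_c$gc, utr3_GC = u3_c$gc,
             aUTR_GC = au_c$gc,
             gene_U = gene_c$u, utr3_U = u3_c$u, aUTR_U = au_c$u,
             gene_size = d$gene_end - d$gene_start,
             utr3_size = d$utr3_end - d$utr3_start,
             aUTR_size = ifelse(has_autr, d$autr_end - d$autr_start, NA_real_),
             junction_density = (d$n_exons - 1) / (d$mature_len / 1000),
             pas_count_utr3 = d$pas_count_utr3,
             row.names = d$gene_id, stringsAsFactors = FALSE)
}

#' Rank features by individual and cumulative R-squared
#'
#' Each feature's individual R-squared is the squared Pearson correlation
#' with the response (equivalently the R-squared of the one-variable
#' least-squares fit); the association sign is the correlation's sign.
#' Features are sorted by decreasing individual R-squared, and the cumulative
#' R-squared at rank j is the R-squared of the ordinary least-squares fit on
#' the top-j features combined (z-scored for conditioning; R-squared is
#' scale-invariant). Rows with missing values are dropped (tallied in the
#' attribute `"n_dropped"`); constant features get individual R-squared 0 and
#' are excluded from the cumulative fits.
#'
#' @param features numeric data.frame/matrix (columns = features).
#' @param response numeric response, same length as `nrow(features)`.
#' @return data.frame of class `"regression_report"`: `feature`, `r`,
#'   `r2_individual`, `sign`, `rank`, `r2_cumulative`.
#' @export
regression_rank <- function(features, response) {
  X <- as.data.frame(features)
  if (ncol(X) < 2) stop("need >= 2 features")
  ok <- stats::complete.cases(X) & is.finite(response)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]; y <- response[ok]
  if (nrow(X) <= ncol(X) + 1) stop("need n > number of features + 1")
  sds <- vapply(X, stats::sd, numeric(1))
  r <- vapply(seq_along(X), function(j)
    if (sds[j] == 0) 0 else stats::cor(X[[j]], y), numeric(1))
  r2 <- r^2
  ord <- order(-r2)
  Z <- scale(as.matrix(X[, sds > 0, drop = FALSE]))
  cum <- rep(NA_real_, ncol(X))
  run <- character(0)
  for (pos in seq_along(ord)) {
    f <- names(X)[ord[pos]]
    if (sds[ord[pos]] > 0) run <- c(run, f)
    cum[pos] <- if (length(run))
      summary(stats::lm(y ~ Z[, run, drop = FALSE]))$r.squared else 0
  }
  out <- data.frame(feature = names(X)[ord], r = r[ord],
                    r2_individual = r2[ord], sign = sign(r[ord]),
                    rank = seq_along(ord), r2_cumulative = cum,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("regression_report", "data.frame")
  out
}

#' @export
print.regression_report <- function(x, digits = 3, ...) {
  cat("Feature ranking by individual R^2 (cumulative = top-j OLS fit):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0) cat(sprintf("(%d rows with missing values dropped)\n", nd))
  invisible(x)
}

#' Hexamer enrichment between two sequence sets
#'
#' Counts overlapping hexamer occurrences in a foreground and a background
#' sequence set and tests each hexamer's enrichment by a two-sided Fisher's
#' exact test on `[this hexamer, all other hexamers] x [fg, bg]`, with BH
#' adjustment across the 4096 hexamers. The top enriched hexamers (odds
#' ratio > 1, `q < q_threshold`, at most `top_k`) are stacked ungapped into a
#' 4 x 6 position-frequency matrix.
#'
#' @param fg,bg foreground / background sequences ([Biostrings::DNAStringSet]
#'   or character vectors over A/C/G/T, each length >= 6 nt).
#' @param mode `"occurrence"` pools overlapping occurrence counts across
#'   sequences; `"presence"` counts sequences containing the hexamer.
#' @param top_k,q_threshold selection of motif-matrix hexamers.
#' @return list of class `"hexamer_table"`: `table` (4096-row data.frame:
#'   `hexamer`, `fg_count`, `bg_count`, `odds_ratio`, `p`, `q`), `top`
#'   (enriched hexamers used), `pfm` (4 x 6 matrix, rows A/C/G/U).
#' @export
hexamer_enrichment <- function(fg, bg, mode = c("occurrence", "presence"),
                               top_k = 10, q_threshold = 0.05) {
  mode <- match.arg(mode)
  as_set <- function(x, label) {
    if (!length(x)) stop("empty ", label, " sequence set")
    x <- Biostrings::DNAStringSet(x)
    x <- x[Biostrings::width(x) >= 6]
    if (!length(x)) stop("no ", label, " sequences of length >= 6")
    x
  }
  fg <- as_set(fg, "foreground"); bg <- as_set(bg, "background")
  count <- function(x) {
    oc <- Biostrings::oligonucleotideFrequency(x, 6)
    if (mode == "presence") colSums(oc > 0) else colSums(oc)
  }
  fgc <- count(fg); bgc <- count(bg)
  fg_tot <- sum(fgc); bg_tot <- sum(bgc)
  pv <- or <- numeric(length(fgc))
  for (i in seq_along(fgc)) {
    tab <- matrix(c(fgc[i], fg_tot - fgc[i], bgc[i], bg_tot - bgc[i]), 2)
    ft <- stats::fisher.test(tab)
    pv[i] <- ft$p.value
    or[i] <- (fgc[i] / (fg_tot - fgc[i])) / (bgc[i] / (bg_tot - bgc[i]))
  }
  tab <- data.frame(hexamer = names(fgc), fg_count = unname(fgc),
                    bg_count = unname(bgc), odds_ratio = or, p = pv,
                    q = stats::p.adjust(pv, "BH"), stringsAsFactors = FALSE)
  enr <- tab[tab$odds_ratio > 1 & tab$q < q_threshold, ]
  enr <- enr[order(enr$p), ]
  top <- utils::head(enr$hexamer, top_k)
  pfm <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  if (length(top)) {
    chars <- do.call(rbind, strsplit(top, ""))
    chars[chars == "T"] <- "U"
    for (j in 1:6) {
      tb <- table(factor(chars[, j], levels = c("A", "C", "G", "U")))
      pfm[, j] <- as.numeric(tb) / length(top)
    }
  }
  structure(list(table = tab, top = top, pfm = pfm, mode = mode),
            class = "hexamer_table")
}

#' @export
print.hexamer_table <- function(x, ...) {
  cat(sprintf("hexamer_table (%s mode): %d enriched at q < 0.05\n", x$mode,
              sum(x$table$odds_ratio > 1 & x$table$q < 0.05, na.rm = TRUE)))
  if (length(x$top))
    cat("top enriched:", paste(x$top, collapse = " "), "\n")
  invisible(x)
}

#' Write a position-frequency matrix in MEME minimal motif format
#'
#' @param pfm 4 x width matrix with rows A/C/G/U (or T).
#' @param file output path.
#' @param name motif name.
#' @param nsites number of contributing sites recorded in the header.
#' @return the path, invisibly.
#' @export
write_meme_motif <- function(pfm, file, name = "motif1", nsites = 20) {
  w <- ncol(pfm)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     w, nsites),
             apply(pfm, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")))
  writeLines(lines, file)
  invisible(file)
}
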