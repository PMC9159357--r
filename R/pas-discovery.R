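.cigar_op_sum <- function(cigar, ops) {
  u <- unique(cigar)
  m <- regmatches(u, gregexpr("\\d+[MIDNSHP=X]", u))
  w <- vapply(m, function(parts) {
    op <- substr(parts, nchar(parts), nchar(parts))
    sum(as.integer(substr(parts, 1, nchar(parts) - 1))[op %in% ops])
  }, numeric(1))
  w[match(cigar, u)]
}

.lead_clip <- function(cigar) {
  out <- integer(length(cigar))
  hit <- grepl("^\\d+S", cigar)
  out[hit] <- as.integer(sub("^(\\d+)S.*", "\\1", cigar[hit]))
  out
}

.trail_clip <- function(cigar) {
  out <- integer(length(cigar))
  hit <- grepl("\\d+S$", cigar)
  out[hit] <- as.integer(sub(".*?(\\d+)S$", "\\1", cigar[hit]))
  out
}

# count leading 5' clip Ts (in read orientation) that are non-genomic when the
# alignment is extended onto the reference; a clip T matching the reference
# base it would occupy is genomic and terminates the run
.nongenomic_t_run <- function(clip, ref_ext, t, reverse) {
  n <- length(clip)
  run <- integer(n)
  if (!n) return(run)
  alive <- which(t >= 1)
  maxt <- max(t)
  for (j in seq_len(maxt)) {
    alive <- alive[t[alive] >= j]
    if (!length(alive)) break
    if (reverse) {
      # read 5'-most clip base is the last SEQ char; stored SEQ is
      # reference-forward, so a read-orientation T reads as A
      i <- t[alive] - j + 1L
      ok <- substr(clip[alive], i, i) == "A" &
            substr(ref_ext[alive], i, i) != "A"
    } else {
      ok <- substr(clip[alive], j, j) == "T" &
            substr(ref_ext[alive], j, j) != "T"
    }
    run[alive[ok]] <- j
    alive <- alive[ok]
  }
  run
}

#' Call PAS reads and their cleavage sites from one alignment file
#'
#' Implements the poly(A)-site read-calling rule for 3'-end sequencing
#' libraries: a read is a PAS read iff its mapping quality is at least
#' `min_mapq` and it carries at least `min_clip_t` consecutive non-genomic Ts
#' at the start of its 5' soft-clip (in read orientation). "Non-genomic" is
#' decided by laying the clip back onto the reference: a clip T that matches
#' the base it would occupy is genomic and terminates the run. The cleavage
#' site is the genomic position (0-based) of the read base adjacent to the
#' clip on the transcribed strand; the site strand is the transcript strand
#' implied by the clip side (reference-reverse read with trailing clip =>
#' plus-strand transcript, and vice versa).
#'
#' @param file SAM or BAM path (SAM is converted via [Rsamtools::asBam()]).
#' @param reference [Biostrings::DNAStringSet]; every aligned contig must be
#'   present.
#' @param min_mapq minimum mapping quality (default 10).
#' @param min_clip_t minimum number of consecutive non-genomic clip Ts
#'   (default 2).
#' @param min_aligned_len minimum aligned query length (defensive filter,
#'   default 23 nt).
#' @return data.frame of cleavage sites: `chrom`, `strand`, `position`
#'   (0-based last transcribed nt), `count`; attribute `"stats"` tallies
#'   reads seen/kept/called.
#' @export
call_pas_reads <- function(file, reference, min_mapq = 10, min_clip_t = 2,
                           min_aligned_len = 23) {
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(file, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("flag", "rname", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  n_seen <- length(res$flag)
  keep <- !bitwAnd(res$flag, 4L) & !is.na(res$pos) & res$mapq >= min_mapq
  flag <- res$flag[keep]; chrom <- as.character(res$rname[keep])
  pos <- res$pos[keep]; cigar <- res$cigar[keep]
  seqs <- as.character(res$seq[keep])

  missing_contig <- setdiff(unique(chrom), names(reference))
  if (length(missing_contig))
    stop("reference sequence missing for contig(s): ",
         paste(missing_contig, collapse = ", "))
  refstr <- setNames(as.character(reference), names(reference))

  qal <- .cigar_op_sum(cigar, c("M", "I", "=", "X"))
  len_ok <- qal >= min_aligned_len
  flag <- flag[len_ok]; chrom <- chrom[len_ok]; pos <- pos[len_ok]
  cigar <- cigar[len_ok]; seqs <- seqs[len_ok]
  refw <- .cigar_op_sum(cigar, c("M", "D", "N", "=", "X"))
  reverse <- bitwAnd(flag, 16L) > 0L

  out <- list(); n_called <- 0L
  for (rv in c(FALSE, TRUE)) {
    sel <- which(reverse == rv)
    if (!length(sel)) next
    t <- if (rv) .trail_clip(cigar[sel]) else .lead_clip(cigar[sel])
    has <- t >= min_clip_t
    sel <- sel[has]; t <- t[has]
    if (!length(sel)) next
    ns <- nchar(seqs[sel])
    if (rv) {
      clip <- substr(seqs[sel], ns - t + 1L, ns)
      # clip laid back onto positions aln_end+1 .. aln_end+t (1-based)
      a_end1 <- pos[sel] + refw[sel] - 1L
      ref_ext <- substr(refstr[chrom[sel]], a_end1 + 1L, a_end1 + t)
      site_pos <- a_end1 - 1L          # 0-based last aligned base
      site_strand <- "+"
    } else {
      clip <- substr(seqs[sel], 1L, t)
      ref_ext <- substr(refstr[chrom[sel]], pos[sel] - t, pos[sel] - 1L)
      site_pos <- pos[sel] - 1L        # 0-based first aligned base
      site_strand <- "-"
    }
    run <- .nongenomic_t_run(clip, ref_ext, t, reverse = rv)
    is_pas <- run >= min_clip_t
    n_called <- n_called + sum(is_pas)
    if (any(is_pas))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom[sel][is_pas], strand = site_strand,
        position = site_pos[is_pas], stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), strand = character(), position = integer())
  if (nrow(sites)) {
    key <- paste(sites$chrom, sites$strand, sites$position)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
    sites <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                        position = as.integer(parts[, 3]),
                        count = as.integer(agg$Freq), stringsAsFactors = FALSE)
    sites <- sites[order(sites$chrom, sites$strand, sites$position), ]
    rownames(sites) <- NULL
  } else {
    sites$count <- integer(0)
  }
  attr(sites, "stats") <- c(reads_seen = n_seen, reads_kept = sum(keep),
                            pas_reads = n_called)
  sites
}

#' Call cleavage sites across multiple samples
#'
#' Runs [call_pas_reads()] on each file and merges the per-sample site counts
#' on (chrom, strand, position).
#'
#' @param files named character vector of SAM/BAM paths (names = sample ids).
#' @param reference [Biostrings::DNAStringSet].
#' @param ... passed to [call_pas_reads()].
#' @return data.frame with `chrom`, `strand`, `position` and one count column
#'   per sample.
#' @export
call_pas_sites <- function(files, reference, ...) {
  if (is.null(names(files)) || any(names(files) == ""))
    stop("files must be named by sample id")
  per <- lapply(files, call_pas_reads, reference = reference, ...)
  keys <- unique(unlist(lapply(per, function(d)
    paste(d$chrom, d$strand, d$position))))
  if (!length(keys)) {
    out <- data.frame(chrom = character(), strand = character(),
                      position = integer())
    for (s in names(files)) out[[s]] <- integer(0)
    return(out)
  }
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                    position = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  for (s in names(files)) {
    d <- per[[s]]
    m <- match(keys, paste(d$chrom, d$strand, d$position))
    out[[s]] <- ifelse(is.na(m), 0L, d$count[m])
  }
  out <- out[order(out$chrom, out$strand, out$position), ]
  rownames(out) <- NULL
  out
}

#' Cluster cleavage sites into PAS clusters
#'
#' Greedy summit clustering within a fixed window: repeatedly take the
#' unassigned site with the highest total count (ties broken toward the
#' smaller coordinate), absorb all unassigned sites within `window` nt on the
#' same chromosome and strand, and report the summit position with summed
#' counts. Deterministic; summits of distinct same-strand clusters end up
#' separated by more than `window` nt.
#'
#' @param sites data.frame with `chrom`, `strand`, `position` and one or more
#'   count columns (all remaining columns are treated as counts).
#' @param window clustering window in nt (default 24).
#' @return list with `clusters` (data.frame: `cluster_id`, `chrom`, `strand`,
#'   `summit`, `n_sites`, per-sample counts, `total`) and `membership`
#'   (integer cluster index per input site row).
#' @export
cluster_sites <- function(sites, window = 24) {
  if (window < 0) stop("window must be >= 0")
  count_cols <- setdiff(names(sites), c("chrom", "strand", "position"))
  if (!length(count_cols)) stop("sites must carry at least one count column")
  cm <- as.matrix(sites[, count_cols, drop = FALSE])
  total <- rowSums(cm)
  membership <- integer(nrow(sites))
  summits <- list()
  cl <- 0L
  for (grp in split(seq_len(nrow(sites)),
                    paste(sites$chrom, sites$strand))) {
    ord <- grp[order(-total[grp], sites$position[grp])]
    assigned <- setNames(rep(FALSE, length(grp)), grp)
    for (i in ord) {
      if (assigned[[as.character(i)]]) next
      cl <- cl + 1L
      free <- grp[!assigned]
      mem <- free[abs(sites$position[free] - sites$position[i]) <= window]
      membership[mem] <- cl
      assigned[as.character(mem)] <- TRUE
      summits[[cl]] <- c(i, mem)
    }
  }
  counts <- do.call(rbind, lapply(summits, function(v)
    colSums(cm[v[-1], , drop = FALSE])))
  summit_row <- vapply(summits, `[`, integer(1), 1)
  clusters <- data.frame(chrom = sites$chrom[summit_row],
                         strand = sites$strand[summit_row],
                         summit = sites$position[summit_row],
                         n_sites = vapply(summits, function(v) length(v) - 1L,
                                          integer(1)),
                         stringsAsFactors = FALSE)
  clusters <- cbind(clusters, as.data.frame(counts))
  clusters$total <- rowSums(counts)
  ord <- order(clusters$chrom, clusters$summit, clusters$strand)
  remap <- integer(nrow(clusters)); remap[ord] <- seq_along(ord)
  clusters <- clusters[ord, ]
  clusters <- cbind(cluster_id = sprintf("PAS%05d", seq_len(nrow(clusters))),
                    clusters, stringsAsFactors = FALSE)
  rownames(clusters) <- clusters$cluster_id
  list(clusters = clusters, membership = remap[membership])
}

#' Assign PAS clusters to genes and transcript regions
#'
#' A cluster is assigned to the gene whose strand matches and whose span
#' contains the summit. Region class is `TPA` if the summit falls in the
#' gene's 3'-most exon, `IPA` if in an intron (the host intron rank is
#' recorded), `other_exonic` if in a non-last exon, and `intergenic` for
#' unassigned clusters. If several same-strand genes contain the summit the
#' gene with the closest 3' end wins, with a warning.
#'
#' @param clusters data.frame of clusters (from [cluster_sites()]`$clusters`).
#' @param annotation a `genome_annotation`.
#' @return `clusters` with `gene_id`, `region_class` and `host_intron` columns.
#' @export
assign_clusters <- function(clusters, annotation) {
  g <- annotation$genes
  gene_gr <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$start + 1L, g$end),
                                    strand = g$strand)
  cl_gr <- GenomicRanges::GRanges(clusters$chrom,
                                  IRanges::IRanges(clusters$summit + 1L,
                                                   clusters$summit + 1L),
                                  strand = clusters$strand)
  hits <- GenomicRanges::findOverlaps(cl_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  gene_id <- rep(NA_character_, nrow(clusters))
  if (length(qh)) {
    dup <- unique(qh[duplicated(qh)])
    if (length(dup)) {
      warning(length(dup),
              " cluster(s) overlap multiple same-strand genes; assigned to the gene with the closest 3' end")
      keep <- rep(TRUE, length(qh))
      for (q in dup) {
        idx <- which(qh == q)
        end3 <- ifelse(g$strand[sh[idx]] == "+", g$end[sh[idx]] - 1L,
                       g$start[sh[idx]])
        best <- idx[which.min(abs(clusters$summit[q] - end3))]
        keep[setdiff(idx, best)] <- FALSE
      }
      qh <- qh[keep]; sh <- sh[keep]
    }
    gene_id[qh] <- g$gene_id[sh]
  }
  region <- ifelse(is.na(gene_id), "intergenic", NA_character_)
  host_intron <- rep(NA_integer_, nrow(clusters))
  ex <- annotation$exons; intr <- annotation$introns
  for (i in which(!is.na(gene_id))) {
    p <- clusters$summit[i]
    e <- ex[ex$gene_id == gene_id[i] & ex$start <= p & p < ex$end, ]
    if (nrow(e)) {
      region[i] <- if (any(e$is_last)) "TPA" else "other_exonic"
      next
    }
    it <- intr[intr$gene_id == gene_id[i] & intr$start <= p & p < intr$end, ]
    if (nrow(it)) {
      region[i] <- "IPA"
      host_intron[i] <- it$rank[1]
    } else {
      region[i] <- "other_exonic"
    }
  }
  clusters$gene_id <- gene_id
  clusters$region_class <- region
  clusters$host_intron <- host_intron
  clusters
}

#' Write PAS clusters as BED6+ with a sidecar count table
#'
#' @param clusters assigned cluster data.frame.
#' @param bed_file BED output path (0-based).
#' @param counts_file optional TSV path for the per-sample counts.
#' @param sample_ids count column names to place in the sidecar.
#' @return `bed_file`, invisibly.
#' @export
write_clusters_bed <- function(clusters, bed_file, counts_file = NULL,
                               sample_ids = NULL) {
  bed <- data.frame(clusters$chrom, clusters$summit, clusters$summit + 1L,
                    clusters$cluster_id, clusters$total, clusters$strand,
                    clusters$gene_id %||% NA, clusters$region_class %||% NA)
  utils::write.table(bed, bed_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(counts_file)) {
    if (is.null(sample_ids))
      sample_ids <- setdiff(names(clusters),
                            c("cluster_id", "chrom", "strand", "summit",
                              "n_sites", "total", "gene_id", "region_class",
                              "host_intron"))
    write_tsv(clusters[, c("cluster_id", sample_ids)], counts_file)
  }
  invisible(bed_file)
}
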