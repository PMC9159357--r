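#' Simulate aligned 3'-end reads as SAM records
#'
#' Emits one single-end aligned record per counted read. The record's 3'
#' genomic end (on the transcribed strand) is the cleavage site, optionally
#' jittered by up to `microheterogeneity` nt, and the poly(A) tail is encoded
#' as a soft-clip of consecutive Ts at the read's 5' end in read orientation:
#' a plus-strand transcript yields a reference-reverse record (`FLAG 16`) with
#' a trailing `S` CIGAR operation (As in the stored, reference-forward SEQ); a
#' minus-strand transcript yields a forward record with a leading `S`
#' operation (literal Ts in SEQ). A configurable fraction of reads is emitted
#' as internal-priming-like decoys at random positions with only 0-1 clipped
#' Ts, and a configurable fraction draws a mapping quality below 10.
#'
#' @param counts isoforms x samples integer matrix (rownames = PAS ids present
#'   in `annotation$pas`).
#' @param annotation a `genome_annotation`.
#' @param reference [Biostrings::DNAStringSet] reference.
#' @param config a [sim_config()] supplying read length, tail range and noise
#'   parameters.
#' @param seed integer seed.
#' @return data.frame of SAM fields (`sample_id`, `qname`, `flag`, `rname`,
#'   `pos` 1-based, `mapq`, `cigar`, `seq`) for all samples; write with
#'   [write_sam_files()].
#' @export
simulate_alignments <- function(counts, annotation, reference, config,
                                seed = config$seed + 3L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  set.seed(seed)
  p <- annotation$pas[rownames(counts), , drop = FALSE]
  if (any(is.na(p$pas_id))) stop("counts rownames must be PAS ids from the annotation")
  L <- config$read_length
  refstr <- setNames(as.character(reference), names(reference))
  seqlen <- annotation$seqlengths

  per_sample <- lapply(seq_len(ncol(counts)), function(j) {
    idx <- rep(seq_len(nrow(counts)), counts[, j])
    if (!length(idx)) return(NULL)
    n <- length(idx)
    chrom <- p$chrom[idx]
    pos <- p$position[idx]
    strand <- p$strand[idx]
    tail_t <- sample(config$tail_range[1]:config$tail_range[2], n, replace = TRUE)

    if (config$microheterogeneity > 0) {
      shift <- sample(seq(-config$microheterogeneity, config$microheterogeneity),
                      n, replace = TRUE)
      pos <- pos + shift
    }
    decoy <- runif(n) < config$decoy_fraction
    if (any(decoy)) {
      nd <- sum(decoy)
      dchrom <- sample(names(seqlen), nd, replace = TRUE)
      chrom[decoy] <- dchrom
      pos[decoy] <- vapply(dchrom, function(cn)
        sample.int(seqlen[[cn]] - 2L * L, 1) + L, integer(1))
      strand[decoy] <- sample(c("+", "-"), nd, replace = TRUE)
      tail_t[decoy] <- sample(0:1, nd, replace = TRUE)
    }
    if (any(pos - L + 1 < 0) || any(pos + max(tail_t) >= seqlen[chrom]))
      stop("cleavage site outside chromosome bounds")

    mapq <- rep(40L, n)
    low <- runif(n) < config$low_mapq_fraction
    if (any(low)) mapq[low] <- sample(0:9, sum(low), replace = TRUE)

    plus <- strand == "+"
    flag <- ifelse(plus, 16L, 0L)
    pos1 <- ifelse(plus, pos - L + 2L, pos + 1L)           # SAM POS, 1-based
    aln <- character(n)
    aln[plus] <- substring(refstr[chrom[plus]], pos[plus] - L + 2L, pos[plus] + 1L)
    aln[!plus] <- substring(refstr[chrom[!plus]], pos[!plus] + 1L, pos[!plus] + L)
    clip <- ifelse(plus, strrep("A", tail_t), strrep("T", tail_t))
    seqs <- ifelse(plus, paste0(aln, clip), paste0(clip, aln))
    cigar <- ifelse(tail_t == 0, paste0(L, "M"),
                    ifelse(plus, paste0(L, "M", tail_t, "S"),
                           paste0(tail_t, "S", L, "M")))
    data.frame(sample_id = colnames(counts)[j],
               qname = sprintf("%s_r%07d", colnames(counts)[j], seq_len(n)),
               flag = flag, rname = chrom, pos = pos1, mapq = mapq,
               cigar = cigar, seq = seqs, stringsAsFactors = FALSE)
  })
  do.call(rbind, per_sample)
}

#' Write SAM records to a file
#'
#' Minimal valid single-end SAM with `@HD`/`@SQ` headers and constant base
#' qualities.
#'
#' @param reads data.frame as returned by [simulate_alignments()] (one
#'   sample's rows).
#' @param file output path (`.sam`).
#' @param seqlengths named integer vector of reference lengths.
#' @return the file path, invisibly.
#' @export
write_sam <- function(reads, file, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  body <- if (is.null(reads) || nrow(reads) == 0) character(0) else
    paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
          reads$cigar, "*", 0L, 0L, reads$seq, strrep("I", nchar(reads$seq)),
          sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Write per-sample SAM files
#'
#' @param reads data.frame from [simulate_alignments()] covering all samples.
#' @param dir output directory (created if needed).
#' @param seqlengths named integer vector of reference lengths.
#' @param sample_ids samples to write; defaults to those present in `reads`.
#'   Samples with zero reads still get a header-only file.
#' @return named character vector of file paths.
#' @export
write_sam_files <- function(reads, dir, seqlengths,
                            sample_ids = unique(reads$sample_id)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- setNames(file.path(dir, paste0(sample_ids, ".sam")), sample_ids)
  for (s in sample_ids)
    write_sam(reads[reads$sample_id == s, , drop = FALSE], paths[[s]], seqlengths)
  paths
}
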