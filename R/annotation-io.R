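.gtf_attr <- function(...) {
  kv <- list(...)
  parts <- mapply(function(k, v) ifelse(is.na(v), NA_character_,
                                        sprintf('%s "%s"', k, v)),
                  names(kv), kv, SIMPLIFY = FALSE)
  apply(do.call(cbind, parts), 1, function(r)
    paste(r[!is.na(r)], collapse = "; "))
}

#' Write a genome annotation to GTF
#'
#' Gene, exon and intron features plus one `PAS` feature per poly(A) site.
#' Intron splice-site strengths (`ss5_score`, `ss3_score`) and PAS metadata
#' travel as GTF attributes. Coordinates convert from the internal 0-based
#' half-open convention to GTF's 1-based inclusive one.
#'
#' @param annotation a `genome_annotation`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_gtf <- function(annotation, file) {
  g <- annotation$genes; e <- annotation$exons; i <- annotation$introns
  p <- annotation$pas
  rows <- c(
    sprintf("%s\tapastab\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, g$start + 1L, g$end, g$strand,
            .gtf_attr(gene_id = g$gene_id, gene_type = g$gene_type,
                      n_exons = g$n_exons)),
    sprintf("%s\tapastab\texon\t%d\t%d\t.\t%s\t.\t%s",
            e$chrom, e$start + 1L, e$end, e$strand,
            .gtf_attr(gene_id = e$gene_id, exon_number = e$rank,
                      is_last = tolower(e$is_last))),
    if (nrow(i))
      sprintf("%s\tapastab\tintron\t%d\t%d\t.\t%s\t.\t%s",
              i$chrom, i$start + 1L, i$end, i$strand,
              .gtf_attr(gene_id = i$gene_id, intron_number = i$rank,
                        ss5_score = i$ss5_score, ss3_score = i$ss3_score)),
    sprintf("%s\tapastab\tPAS\t%d\t%d\t.\t%s\t.\t%s",
            p$chrom, p$position + 1L, p$position + 1L, p$strand,
            .gtf_attr(gene_id = p$gene_id, pas_id = p$pas_id,
                      region_class = p$region_class, tpa_rank = p$tpa_rank,
                      host_intron = p$host_intron))
  )
  writeLines(rows, file)
  invisible(file)
}

#' Read a genome annotation from GTF
#'
#' Parses a GTF written by [write_gtf()] (or any GTF carrying the same
#' feature types and attributes) back into a `genome_annotation`.
#'
#' @param file GTF path.
#' @param seqlengths named integer vector of chromosome lengths; if `NULL`,
#'   taken from the maximum annotated end per chromosome.
#' @return a `genome_annotation`.
#' @export
read_annotation <- function(file, seqlengths = NULL) {
  gr <- rtracklayer::import(file, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$start0 <- df$start - 1L   # back to 0-based half-open
  # attribute columns absent from the file (e.g. host_intron when no gene
  # has an intronic PAS) come back as all-NA
  col <- function(d, nm) if (nm %in% names(d)) d[[nm]] else
    rep(NA_character_, nrow(d))
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))

  gd <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gd$gene_id, chrom = gd$chrom, strand = gd$strand,
                      start = gd$start0, end = gd$end,
                      gene_type = gd$gene_type, n_exons = int(gd$n_exons),
                      stringsAsFactors = FALSE)
  ed <- df[df$type == "exon", ]
  exons <- data.frame(gene_id = ed$gene_id, rank = int(ed$exon_number),
                      chrom = ed$chrom, strand = ed$strand,
                      start = ed$start0, end = ed$end,
                      is_last = ed$is_last == "true", stringsAsFactors = FALSE)
  id <- df[df$type == "intron", ]
  introns <- if (nrow(id))
    data.frame(gene_id = id$gene_id, rank = int(id$intron_number),
               chrom = id$chrom, strand = id$strand,
               start = id$start0, end = id$end, size = id$end - id$start0,
               ss5_score = num(id$ss5_score), ss3_score = num(id$ss3_score),
               stringsAsFactors = FALSE)
  else data.frame(gene_id = character(), rank = integer(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  size = integer(), ss5_score = numeric(), ss3_score = numeric())
  pd <- df[df$type == "PAS", ]
  pas <- data.frame(pas_id = pd$pas_id, gene_id = pd$gene_id, chrom = pd$chrom,
                    strand = pd$strand, position = pd$start0,
                    region_class = pd$region_class,
                    tpa_rank = int(col(pd, "tpa_rank")),
                    host_intron = int(col(pd, "host_intron")),
                    stringsAsFactors = FALSE)
  rownames(pas) <- pas$pas_id
  if (is.null(seqlengths)) {
    seqlengths <- tapply(df$end, df$chrom, max) + 300L
    seqlengths <- setNames(as.integer(seqlengths), names(seqlengths))
  }
  structure(list(genes = genes, exons = exons, introns = introns, pas = pas,
                 seqlengths = seqlengths),
            class = "genome_annotation")
}

#' Write simulated ground truth and sample sheet as TSV
#'
#' @param x a data.frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV written by [write_tsv()]
#' @param file path.
#' @return data.frame.
#' @export
read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
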