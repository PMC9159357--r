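# minimal hand-built annotation: one plus-strand and one minus-strand
# single-exon gene with known sequence content
make_toy_annotation <- function() {
  genes <- data.frame(gene_id = c("gP", "gM"), chrom = "t",
                      strand = c("+", "-"), start = c(10L, 60L),
                      end = c(40L, 90L), gene_type = "mRNA", n_exons = 1L,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gP", "gM"), rank = 1L, chrom = "t",
                      strand = c("+", "-"), start = c(10L, 60L),
                      end = c(40L, 90L), is_last = TRUE,
                      stringsAsFactors = FALSE)
  introns <- data.frame(gene_id = character(), rank = integer(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(), size = integer(),
                        ss5_score = numeric(), ss3_score = numeric())
  pas <- data.frame(pas_id = c("gP_TPA1", "gM_TPA1"),
                    gene_id = c("gP", "gM"), chrom = "t",
                    strand = c("+", "-"), position = c(35L, 65L),
                    region_class = "TPA", tpa_rank = 1L,
                    host_intron = NA_integer_, stringsAsFactors = FALSE)
  rownames(pas) <- pas$pas_id
  structure(list(genes = genes, exons = exons, introns = introns, pas = pas,
                 seqlengths = c(t = 120L)), class = "genome_annotation")
}

test_that("base content is computed on the sense strand", {
  ref_chars <- rep("G", 120)
  ref_chars[11:40] <- rep(c("G", "C"), 15)      # gP body: GC alternating
  ref_chars[61:90] <- "A"                       # gM forward = A => sense = U
  ref <- Biostrings::DNAStringSet(setNames(paste(ref_chars, collapse = ""), "t"))
  ann <- make_toy_annotation()
  f <- compute_features(ann, ref)
  expect_equal(f["gP", "utr3_GC"], 1)
  expect_equal(f["gP", "utr3_U"], 0)
  expect_equal(f["gM", "utr3_U"], 1)            # minus strand: A reads as U
  expect_equal(f["gM", "utr3_GC"], 0)
  expect_equal(f$junction_density, c(0, 0))     # single-exon genes
  expect_equal(f$pas_count_utr3, c(1, 1))
  # 3'UTR runs from the last-exon start to the distal PAS
  expect_equal(f["gP", "utr3_size"], 26)        # [10, 36)
  expect_equal(f["gM", "utr3_size"], 25)        # [65, 90)
})

test_that("content fractions are proper fractions on simulated genomes", {
  sim <- small_sim()
  f <- compute_features(sim$annotation, sim$reference)
  for (col in c("gene_GC", "lastexon_GC", "utr3_GC", "gene_U", "utr3_U"))
    expect_true(all(f[[col]] >= 0 & f[[col]] <= 1))
  expect_true(all(f$utr3_GC + f$utr3_U <= 1 + 1e-12))
  expect_true(all(f$utr3_size > 0 & f$gene_size > 0))
  multi <- !is.na(f$aUTR_size)
  expect_true(all(f$aUTR_size[multi] > 0))
})

test_that("regression ranking recovers a perfect predictor and is stable", {
  set.seed(41)
  x1 <- rnorm(100); x2 <- rnorm(100)
  rep1 <- suppressWarnings(regression_rank(data.frame(x1 = x1, x2 = x2), 2 * x1))
  expect_equal(rep1$feature[1], "x1")
  expect_equal(rep1$r2_individual[1], 1)
  expect_equal(rep1$sign[1], 1)
  # cumulative R^2 is non-decreasing along the ranking
  y <- x1 + 0.5 * x2 + rnorm(100)
  X <- data.frame(x1 = x1, x2 = x2, x3 = rnorm(100), x4 = rnorm(100))
  rep2 <- regression_rank(X, y)
  expect_true(all(diff(rep2$r2_cumulative) >= -1e-12))
  # affine rescaling of a feature changes nothing
  X2 <- X; X2$x1 <- 100 * X2$x1 - 7
  rep3 <- regression_rank(X2, y)
  expect_equal(rep3$r2_individual, rep2$r2_individual, tolerance = 1e-9)
  expect_equal(rep3$r2_cumulative, rep2$r2_cumulative, tolerance = 1e-9)
  # constant feature gets zero R^2 and does not break the cumulative fit
  X3 <- X; X3$x3 <- 5
  rep4 <- regression_rank(X3, y)
  expect_equal(rep4$r2_individual[rep4$feature == "x3"], 0)
  expect_false(anyNA(rep4$r2_cumulative))
})

test_that("hexamer counting is overlapping and self-comparison is null", {
  h <- hexamer_enrichment("GCGCGCGC", "GCGCGCGC")
  tab <- h$table
  expect_equal(tab$fg_count[tab$hexamer == "GCGCGC"], 2)
  expect_equal(tab$fg_count[tab$hexamer == "CGCGCG"], 1)
  expect_equal(sum(tab$fg_count), 3)            # 8 - 6 + 1 overlapping windows
  expect_true(all(tab$odds_ratio[tab$fg_count > 0] == 1))
  expect_equal(min(tab$q), 1)
  expect_equal(length(h$top), 0)
  expect_error(hexamer_enrichment(character(0), "ACGTAC"), "empty")
})

test_that("a planted hexamer is recovered as enriched", {
  set.seed(51)
  bg <- random_seqs(200, 60)
  fg <- random_seqs(200, 60)
  substr(fg[1:100], 20, 25) <- "TGTGTG"
  h <- hexamer_enrichment(fg, bg)
  expect_true("TGTGTG" %in% h$top)
  expect_lt(h$table$q[h$table$hexamer == "TGTGTG"], 0.05)
  expect_equal(dim(h$pfm), c(4L, 6L))
  expect_equal(colSums(h$pfm), rep(1, 6), tolerance = 1e-12)
  # Fisher p agrees with hypergeometric enumeration on small counts
  i <- which(h$table$hexamer == "TGTGTG")
  small_fg <- c("AATGTGTGAA", "CCTGTGTGCC")
  small_bg <- c("AACCGGTTAA", "GGAATTCCGG")
  hs <- hexamer_enrichment(small_fg, small_bg)
  ts <- hs$table[hs$table$hexamer == "TGTGTG", ]
  fg_tot <- sum(hs$table$fg_count); bg_tot <- sum(hs$table$bg_count)
  expect_equal(ts$p, oracle_fisher_p(ts$fg_count, fg_tot - ts$fg_count,
                                     ts$bg_count, bg_tot - ts$bg_count),
               tolerance = 1e-9)
})

test_that("MEME motif output is well-formed", {
  pfm <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  f <- tempfile(fileext = ".meme")
  write_meme_motif(pfm, f, name = "m1")
  lines <- readLines(f)
  expect_true(any(grepl("^MOTIF m1", lines)))
  expect_equal(sum(grepl("^0\\.250000", lines)), 6)
})
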