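test_that("labeling model closed forms are exact", {
  # half-life 1 h, 1 h pulse: half the pool is newly made
  ef <- expected_fractions(s = log(2), k = log(2), t = 1)
  expect_equal(ef$total, 1)
  expect_equal(ef$labeled, 0.5)
  expect_equal(ef$unlabeled, 0.5)
  expect_equal(implied_ss(log(2), 1), 0)

  # half-life 0.5 h: FT fraction 0.25, labeled 0.75, SS = log2(1/3)
  ef2 <- expected_fractions(1, 2 * log(2), 1)
  expect_equal(ef2$unlabeled / ef2$total, 0.25)
  expect_equal(ef2$labeled / ef2$total, 0.75)
  expect_equal(implied_ss(2 * log(2), 1), log2(1 / 3))

  # very slow decay: nearly everything is pre-existing
  ef3 <- expected_fractions(1, 1e-8, 1)
  expect_equal(ef3$unlabeled / ef3$total, 1, tolerance = 1e-6)

  expect_error(expected_fractions(1, 0, 1), "decay rate")
  expect_error(expected_fractions(1, 1, -1), "labeling time")
})

test_that("total = labeled + unlabeled exactly and SS is monotone in k", {
  set.seed(42)
  s <- rlnorm(200); k <- rlnorm(200); t <- runif(200, 0.1, 4)
  ef <- expected_fractions(s, k, t)
  expect_equal(ef$total, ef$labeled + ef$unlabeled)
  kgrid <- 10^seq(-3, 1.5, length.out = 100)
  expect_true(all(diff(implied_ss(kgrid, 1)) < 0))
  expect_true(all(diff(implied_ss(kgrid, 0.5)) < 0))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 15, depth = 2000, seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$annotation$pas, b$annotation$pas)
  expect_identical(a$truth, b$truth)
  expect_identical(a$counts, b$counts)
  ra <- simulate_alignments(a$counts, a$annotation, a$reference, cfg)
  rb <- simulate_alignments(b$counts, b$annotation, b$reference, cfg)
  expect_identical(ra, rb)
})

test_that("configuration forces annotation structure", {
  cfg <- sim_config(n_genes = 1, pas_per_gene = c("2" = 1),
                    ipa_probability = 0, seed = 3)
  ann <- simulate_annotation(cfg)$annotation
  expect_equal(nrow(ann$genes), 1)
  expect_equal(sum(ann$pas$region_class == "TPA"), 2)
  expect_equal(sum(ann$pas$region_class == "IPA"), 0)

  cfg2 <- sim_config(n_genes = 20, pas_per_gene = c("2" = 1),
                     ipa_probability = 0, autr_size_range = c(500, 500),
                     seed = 4)
  ann2 <- simulate_annotation(cfg2)$annotation
  d <- tapply(ann2$pas$position, ann2$pas$gene_id,
              function(p) abs(diff(sort(p))))
  expect_true(all(unlist(d) == 500))
})

test_that("count sampling respects depth, ratios and determinism", {
  expected <- matrix(c(3, 1), 2, 3, dimnames = list(c("i1", "i2"),
                                                    c("s1", "s2", "s3")))
  z <- simulate_counts(expected, depth = 0)
  expect_true(all(z == 0))
  big <- simulate_counts(expected, depth = 1e5, seed = 9)
  ratio <- big["i1", ] / big["i2", ]
  expect_true(all(abs(ratio - 3) < 0.2))
  expect_identical(simulate_counts(expected, 500, seed = 1),
                   simulate_counts(expected, 500, seed = 1))
  expect_error(simulate_counts(matrix(0, 2, 2), 10), "zero total abundance")
})

test_that("sample sheet spans conditions x fractions x replicates uniquely", {
  ss <- sample_sheet(sim_config())
  expect_equal(nrow(ss), 3 * 3 * 2)
  expect_false(any(duplicated(ss[, c("condition", "fraction", "replicate")])))
  expect_setequal(unique(ss$fraction), c("total", "4sU", "FT"))
})

test_that("annotation GTF round-trips, with and without intronic PASs", {
  for (ipa in c(0.5, 0)) {
    ann <- simulate_annotation(sim_config(n_genes = 12, ipa_probability = ipa,
                                          seed = 3))$annotation
    f <- tempfile(fileext = ".gtf")
    write_gtf(ann, f)
    back <- read_annotation(f, seqlengths = ann$seqlengths)
    expect_equal(back$genes[, c("gene_id", "start", "end", "strand")],
                 ann$genes[, c("gene_id", "start", "end", "strand")],
                 ignore_attr = TRUE)
    expect_equal(back$pas$position, ann$pas$position)
    expect_equal(back$pas$region_class, ann$pas$region_class)
    expect_equal(back$pas$host_intron, ann$pas$host_intron)
    if (nrow(ann$introns))
      expect_equal(sort(back$introns$ss5_score), sort(ann$introns$ss5_score))
  }
})

test_that("read records encode poly(A) evidence with the strand convention", {
  cfg <- sim_config(n_genes = 10, depth = 500, seed = 8)
  sim <- simulate_dataset(cfg)
  reads <- simulate_alignments(sim$counts, sim$annotation, sim$reference, cfg)
  p <- sim$annotation$pas
  # plus-strand transcripts: reference-reverse records, trailing clip of As
  plus_ids <- rownames(sim$counts)[p[rownames(sim$counts), "strand"] == "+"]
  i <- which(reads$flag == 16L)[1]
  expect_match(reads$cigar[i], "^50M[0-9]+S$")
  expect_match(reads$seq[i], "A+$")
  # minus-strand transcripts: forward records, leading clip of literal Ts
  j <- which(reads$flag == 0L)[1]
  expect_match(reads$cigar[j], "^[0-9]+S50M$")
  expect_match(reads$seq[j], "^T+")
  # every read's 3' end sits on a true PAS (no noise configured)
  pos0 <- reads$pos - 1L
  end3 <- ifelse(reads$flag == 16L, pos0 + cfg$read_length - 1L, pos0)
  expect_true(all(end3 %in% p$position))
})
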