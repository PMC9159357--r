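make_tpa_clusters <- function(summits, counts, strand = "+", gene = "G1") {
  data.frame(cluster_id = sprintf("C%d", seq_along(summits)), chrom = "c",
             strand = strand, summit = summits, n_sites = 1L, s1 = counts,
             total = counts, gene_id = gene, region_class = "TPA",
             stringsAsFactors = FALSE)
}

test_that("top-two isoform selection ranks, orders and tie-breaks", {
  cl <- make_tpa_clusters(c(100L, 600L, 1200L), c(100, 5, 90))
  pair <- select_isoform_pairs(cl, "s1")
  expect_equal(pair$ppas_id, "C1")       # top two are C1 (100) and C3 (90)
  expect_equal(pair$dpas_id, "C3")
  expect_equal(pair$autr_size, 1100)

  # single PAS -> no pair
  expect_null(select_isoform_pairs(make_tpa_clusters(100L, 10), "s1"))

  # expression tie: the more proximal cluster wins the contested slot
  cl2 <- make_tpa_clusters(c(100L, 600L, 1200L), c(50, 50, 80))
  pair2 <- select_isoform_pairs(cl2, "s1")
  expect_equal(sort(c(pair2$ppas_id, pair2$dpas_id)), c("C1", "C3"))

  # minus strand: proximal is the higher coordinate
  cl3 <- make_tpa_clusters(c(100L, 900L), c(40, 60), strand = "-")
  pair3 <- select_isoform_pairs(cl3, "s1")
  expect_equal(pair3$ppas_id, "C2")
  expect_equal(pair3$dpas_id, "C1")
  expect_equal(pair3$autr_size, 800)
})

test_that("RE and RED formulas", {
  expect_equal(relative_expression(4, 16, pseudocount = 0), -2)
  expect_equal(relative_expression(8, 8), 0)
  expect_equal(red(1.5, 0.5), 1)
  expect_equal(red(0.3, 1.1), -red(1.1, 0.3))
  expect_error(relative_expression(-1, 2), ">= 0")
})

test_that("APA usage test: Fisher p, relative abundance and calls", {
  r <- apa_usage_test(50, 50, 50, 50)
  expect_equal(r$p, 1)
  expect_equal(r$call, "unchanged")

  r2 <- apa_usage_test(3, 1, 1, 3)
  expect_equal(r2$p, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-9)
  expect_equal(r2$p, 0.4857, tolerance = 1e-3)
  expect_equal(r2$call, "unchanged")

  r3 <- apa_usage_test(900, 100, 500, 500)
  expect_lt(r3$p, 1e-10)
  expect_equal(r3$rel_diff, 0.4)
  expect_equal(r3$call, "lengthened")

  # swapping the samples flips the direction only
  r4 <- apa_usage_test(500, 500, 900, 100)
  expect_equal(r4$p, r3$p)
  expect_equal(r4$rel_diff, -r3$rel_diff)
  expect_equal(r4$call, "shortened")

  # all-zero table -> no call
  r5 <- apa_usage_test(0, 0, 0, 0)
  expect_true(is.na(r5$p) && is.na(r5$call))
})

test_that("isoform stability test direction and significance", {
  # dPAS relatively enriched in FT -> distal more stable -> red
  r <- isoform_stability_test(200, 50, 100, 100)
  expect_gt(r$delta_ss, 0)
  expect_lt(r$p, 0.05)
  expect_equal(r$call, "red")
  expect_equal(r$p, oracle_fisher_p(200, 50, 100, 100), tolerance = 1e-9)
  # equal proportions -> p = 1, delta 0
  r2 <- isoform_stability_test(60, 30, 60, 30)
  expect_equal(r2$p, 1)
  expect_equal(r2$delta_ss, 0)
  expect_equal(r2$call, "unchanged")
  # empty margin -> no call
  r3 <- isoform_stability_test(0, 0, 10, 5)
  expect_true(is.na(r3$p))
})

test_that("quintile bins are balanced, ordered and permutation-invariant", {
  x <- c(10, 2, 8, 1, 9, 3, 7, 4, 6, 5)
  b <- quintile_bins(x)
  expect_equal(as.integer(table(b$bin)), rep(2L, 5))
  # bins ordered by the variable
  expect_true(all(tapply(x, b$bin, max)[-5] <
                  tapply(x, b$bin, min)[-1]))
  # shuffling input yields the same value-to-bin mapping
  set.seed(2)
  perm <- sample(10)
  b2 <- quintile_bins(x[perm])
  expect_equal(b2$bin[order(x[perm])], b$bin[order(x)])
  expect_error(quintile_bins(1:4), "at least 5")
  # sizes differ by at most one when n is not divisible by 5
  b3 <- quintile_bins(rnorm(23))
  expect_lte(diff(range(table(b3$bin))), 1)
})

test_that("quintile-bin test detects a trend in the response", {
  set.seed(9)
  x <- runif(200, 100, 2000)
  y <- -0.001 * x + rnorm(200, 0, 0.3)
  b <- quintile_bins(x, y, x_name = "autr_size", y_name = "delta_ss")
  expect_lt(b$test$p.value, 0.01)
  expect_gt(b$stats$y_median[1], b$stats$y_median[5])
})

test_that("distal isoforms destabilized 4-fold give the expected signatures", {
  cfg <- sim_config(n_genes = 150, depth = 5e4, dpas_k_factor = 4,
                    dpas_affected_frac = 0.5,
                    pas_per_gene = c("1" = 0.2, "2" = 0.6, "3" = 0.2),
                    seed = 19)
  sim <- simulate_dataset(cfg)
  counts <- filter_expressed(sim$counts)
  quant <- median_ratio_normalize(counts, sim$samples)
  cl <- truth_clusters(sim, counts)
  total_ids <- sim$samples$sample_id[sim$samples$fraction == "total"]
  pairs <- select_isoform_pairs(cl, total_ids)
  pool <- function(fr, ids) rowSums(counts[ids, sim$samples$sample_id[
    sim$samples$condition == "cellA" & sim$samples$fraction == fr],
    drop = FALSE])
  st <- isoform_stability_test(pool("4sU", pairs$ppas_id),
                               pool("4sU", pairs$dpas_id),
                               pool("FT", pairs$ppas_id),
                               pool("FT", pairs$dpas_id))
  blue <- sum(st$call == "blue", na.rm = TRUE)
  red_n <- sum(st$call == "red", na.rm = TRUE)
  expect_gt(blue, red_n)   # proximal isoforms dominate the stable calls
  # RE higher in the newly made fraction than in the pre-existing one for
  # genes with a destabilized distal isoform
  kp <- sim$truth[pairs$ppas_id, "k_base"]
  kd <- sim$truth[pairs$dpas_id, "k_base"]
  pert <- kd / kp > 2
  re_fr <- function(fr) {
    ids <- sim$samples$sample_id[sim$samples$fraction == fr]
    rowMeans(sapply(ids, function(s)
      relative_expression(quant$rpm[pairs$dpas_id, s],
                          quant$rpm[pairs$ppas_id, s])))
  }
  expect_gt(mean(re_fr("4sU")[pert] - re_fr("FT")[pert]), 0)
})

test_that("IPA events are unstable relative to terminal-exon isoforms", {
  cfg <- sim_config(n_genes = 100, depth = 5e4, ipa_probability = 0.6,
                    seed = 23)
  sim <- simulate_dataset(cfg)
  counts <- filter_expressed(sim$counts)
  fit <- stability_fit(counts, sim$samples)
  cl <- truth_clusters(sim, counts)
  ia <- ipa_analysis(cl, fit, sim$annotation, sim$samples)
  expect_gt(nrow(ia$events), 10)
  expect_lt(median(ia$events$mean_delta_ss), 0)
  # no IPA clusters -> empty result
  ia0 <- ipa_analysis(cl[cl$region_class != "IPA", ], fit, sim$annotation,
                      sim$samples)
  expect_null(ia0$events)
})
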