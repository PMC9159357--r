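test_that("expression filter keeps rows with enough reads in any sample", {
  m <- rbind(a = c(5L, 0L, 0L), b = c(4L, 4L, 4L), c = c(0L, 9L, 1L))
  f <- filter_expressed(m, min_reads = 5)
  expect_equal(rownames(f), c("a", "c"))          # boundary row kept (>= 5)
  fs <- filter_expressed(m, min_reads = 5, strict_gt = TRUE)
  expect_equal(rownames(fs), "c")                 # strict rule drops the 5
  empty <- m[0, , drop = FALSE]
  expect_equal(filter_expressed(empty), empty)
  # raising the threshold never increases the retained set
  set.seed(1)
  r <- matrix(rpois(300, 4), 50)
  kept <- vapply(0:15, function(t) nrow(filter_expressed(r, t)), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("median-ratio factors match the closed form and hand oracle", {
  m <- rbind(c(10, 20), c(30, 60))
  colnames(m) <- c("s1", "s2")
  q <- median_ratio_normalize(m, by_fraction = FALSE)
  expect_equal(unname(q$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(q$normalized[, 1], q$normalized[, 2])

  # identical samples -> unit factors
  id <- cbind(s1 = c(4, 9, 2), s2 = c(4, 9, 2))
  expect_equal(unname(median_ratio_normalize(id, by_fraction = FALSE)$size_factors),
               c(1, 1))

  # hand oracle on random matrices: median of ratios to row geometric means
  # over rows without zeros (median taken on the log scale, as in DESeq,
  # so the even-n interpolation is geometric)
  set.seed(7)
  for (i in 1:20) {
    r <- matrix(rpois(60, 20) + 1L, 12)
    colnames(r) <- paste0("s", 1:5)
    gm <- exp(rowMeans(log(r)))
    sf_oracle <- apply(r / gm, 2, function(v) exp(median(log(v))))
    sf_oracle <- sf_oracle / exp(mean(log(sf_oracle)))
    q2 <- median_ratio_normalize(r, by_fraction = FALSE)
    expect_equal(unname(q2$size_factors), unname(sf_oracle), tolerance = 1e-9)
  }
})

test_that("normalization is ratio-equivariant and idempotent", {
  set.seed(8)
  m <- matrix(rpois(80, 30) + 1L, 20)
  colnames(m) <- paste0("s", 1:4)
  q <- median_ratio_normalize(m, by_fraction = FALSE)
  # scaling one sample by c raises its factor c-fold relative to the others
  # (factor ratios, not the factors themselves, are identified), and leaves
  # normalized cross-sample ratios untouched
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  q2 <- median_ratio_normalize(m2, by_fraction = FALSE)
  expect_equal(q2$size_factors[2] / q2$size_factors[1],
               3 * q$size_factors[2] / q$size_factors[1], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sweep(q2$normalized, 1, q2$normalized[, 1], "/"),
               sweep(q$normalized, 1, q$normalized[, 1], "/"),
               tolerance = 1e-9)
  # renormalizing factor-divided counts gives unit factors
  q3 <- median_ratio_normalize(q$normalized, by_fraction = FALSE)
  expect_equal(unname(q3$size_factors), rep(1, 4), tolerance = 1e-9)
})

test_that("all-zero-containing rows leave factors undefined with guidance", {
  m <- rbind(c(0, 5), c(3, 0))
  colnames(m) <- c("s1", "s2")
  expect_error(median_ratio_normalize(m, by_fraction = FALSE),
               "library-size")
})

test_that("per-fraction normalization uses fraction-specific factor sets", {
  sim <- small_sim()
  counts <- filter_expressed(sim$counts)
  q <- median_ratio_normalize(counts, sim$samples)
  fr <- sim$samples$fraction[match(colnames(counts), sim$samples$sample_id)]
  # doubling every 4sU library leaves factors (geometric mean 1 per set)
  # and RPM values unchanged, and does not touch the other fractions
  counts2 <- counts
  counts2[, fr == "4sU"] <- counts2[, fr == "4sU"] * 2L
  q2 <- median_ratio_normalize(counts2, sim$samples)
  expect_equal(q2$size_factors, q$size_factors, tolerance = 1e-9)
  expect_equal(q2$rpm[, fr == "4sU"], q$rpm[, fr == "4sU"], tolerance = 1e-9)
  expect_equal(q2$rpm[, fr != "4sU"], q$rpm[, fr != "4sU"], tolerance = 1e-12)
})

test_that("gene aggregation sums cluster counts and drops unassigned rows", {
  m <- rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  g <- c("gA", "gA", NA)
  a <- aggregate_to_genes(m, g)
  expect_equal(dim(a), c(1L, 2L))
  expect_equal(unname(a["gA", ]), c(4, 6))
})
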