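# Independent oracle implementations used to cross-check package code.
# These deliberately use different code paths / textbook formulas.

# brute-force greedy summit clustering on one chrom/strand: repeatedly pick
# the remaining site with max total (ties -> smallest position) and remove
# everything within the window
oracle_cluster <- function(positions, totals, window = 24) {
  remaining <- data.frame(pos = positions, tot = totals)
  out <- list()
  while (nrow(remaining)) {
    best <- remaining[order(-remaining$tot, remaining$pos), ][1, ]
    mem <- abs(remaining$pos - best$pos) <= window
    out[[length(out) + 1]] <- list(summit = best$pos,
                                   count = sum(remaining$tot[mem]),
                                   members = sort(remaining$pos[mem]))
    remaining <- remaining[!mem, , drop = FALSE]
  }
  out[order(vapply(out, `[[`, numeric(1), "summit"))]
}

# exhaustive two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # col 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by full permutation enumeration (tie-free data)
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs); p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# textbook one-way ANOVA F and p
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  g <- nlevels(groups); N <- length(values)
  gm <- tapply(values, groups, mean); ns <- table(groups)
  ssb <- sum(ns * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  F <- (ssb / (g - 1)) / (ssw / (N - g))
  c(F = F, p = stats::pf(F, g - 1, N - g, lower.tail = FALSE))
}

# random DNA sequences
random_seqs <- function(n, len, prob = rep(0.25, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob), collapse = ""), "")
}

# small simulated dataset shared across tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(n_genes = 40, depth = 3000,
                                            ipa_probability = 0.3, seed = 7))
    cache
  }
})
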