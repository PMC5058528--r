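test_that("allele-frequency estimators behave per method", {
  # HWE algebra: a quarter of samples band-absent -> q = 0.5
  expect_equal(estimate_allele_freq(5, 20, "sqrt"), 0.5)
  # estimator contrast at the boundary
  expect_identical(estimate_allele_freq(0, 20, "sqrt"), 0)
  expect_gt(estimate_allele_freq(0, 20, "zhivotovsky"), 0)
  # Bayesian posterior mean vs numerical quadrature of the posterior
  post_mean <- function(k, n) {
    num <- integrate(function(q) q * q^(2 * k) * (1 - q^2)^(n - k), 0, 1,
                     rel.tol = 1e-12)$value
    den <- integrate(function(q) q^(2 * k) * (1 - q^2)^(n - k), 0, 1,
                     rel.tol = 1e-12)$value
    num / den
  }
  expect_equal(estimate_allele_freq(5, 20, "zhivotovsky"), post_mean(5, 20),
               tolerance = 1e-4)
  expect_equal(estimate_allele_freq(12, 30, "zhivotovsky"),
               post_mean(12, 30), tolerance = 1e-4)
  # bias-corrected square root exceeds the naive estimate away from 0
  expect_gt(estimate_allele_freq(5, 20, "lynch_milligan"),
            estimate_allele_freq(5, 20, "sqrt"))
  expect_error(estimate_allele_freq(5, 0), "n must be")
  expect_error(estimate_allele_freq(25, 20), "n_absent")
})

test_that("gene diversity follows Nei's algebra on fixed cases", {
  # all bands fixed present -> no diversity (square-root estimator exact)
  m <- toy_matrix(matrix(1L, 10, 4))
  gd <- gene_diversity(m, "host", method = "sqrt")
  expect_equal(gd$HJ, 0)
  expect_equal(gd$HS, 0)
  expect_identical(gd$n_polymorphic, 0L)
  # two pops fixed for alternative states: HS = 0, HJ = 0.5 at that locus
  calls <- matrix(c(rep(1L, 5), rep(0L, 5)), ncol = 1)
  m2 <- toy_matrix(calls, host = rep(c("glabra", "coriacea"), each = 5))
  gd2 <- gene_diversity(m2, "host", method = "sqrt")
  expect_equal(gd2$HS, 0)
  expect_equal(gd2$HJ, 0.5)
})

test_that("HS on a truth-known fixture matches the generator expectation", {
  cfg <- sim_config(seed = 41, miscall_rate = 0, n_outlier_loci = 0,
                    background_fst = 0.057)
  mk <- simulate_dominant_markers(cfg)
  gd <- gene_diversity(mk$matrix, "host", method = "sqrt")
  q_true <- 1 - mk$truth$p_host
  expected_hs <- mean(2 * q_true * (1 - q_true))
  expect_lt(abs(gd$HS - expected_hs), 0.02)
})

test_that("global FST equals a brute-force component oracle on small toys", {
  # independent loop-based implementation of the variance components
  brute_fst <- function(calls, groups, method = "sqrt") {
    num_t <- den_t <- 0
    for (l in seq_len(ncol(calls))) {
      qs <- c(); vs <- c()
      for (g in unique(groups)) {
        x <- calls[groups == g, l]
        q <- estimate_allele_freq(sum(x == 0), length(x), method)
        qs <- c(qs, q)
        vs <- c(vs, (1 - q^2) / (4 * length(x)))
      }
      r <- length(qs)
      s2 <- sum((qs - mean(qs))^2) / (r - 1)
      num <- s2 - mean(vs)
      den <- mean(qs) * (1 - mean(qs)) + s2 / r
      num_t <- num_t + num
      den_t <- den_t + den
    }
    num_t / den_t
  }
  set.seed(7)
  for (rep in 1:5) {
    calls <- matrix(rbinom(20 * 5, 1, runif(1, 0.2, 0.8)), 20, 5)
    groups <- rep(c("a", "b"), each = 10)
    m <- toy_matrix(calls, host = groups)
    f <- fst_dominant(m, "host", n_perm = 0, method = "sqrt")
    expect_equal(f$fst, brute_fst(calls, groups), tolerance = 1e-10)
  }
})

test_that("fixed alternative bands drive FST towards 1", {
  calls <- cbind(matrix(rep(c(1L, 0L), c(10, 10)), 20, 3),
                 matrix(rep(c(0L, 1L), c(10, 10)), 20, 3))
  m <- toy_matrix(calls, host = rep(c("a", "b"), each = 10))
  f <- fst_dominant(m, "host", n_perm = 0, method = "sqrt")
  expect_gt(f$fst, 0.95)
})

test_that("FST recovery at the study's host-level magnitude", {
  cfg <- sim_config(seed = 42, background_fst = 0.125, miscall_rate = 0,
                    n_outlier_loci = 0)
  mk <- simulate_dominant_markers(cfg)
  f <- fst_dominant(mk$matrix, "host", n_perm = 200, seed = 1)
  # realized truth from the recorded per-host frequencies
  p <- mk$truth$p_host
  vb <- colSums(sweep(p, 2, colMeans(p))^2)
  den <- colMeans(p) * (1 - colMeans(p)) + vb / 2
  realized <- sum(vb) / sum(den)
  expect_lt(abs(f$fst - realized), 0.02)
  expect_lt(f$p, 0.01)
})

test_that("permutation p-values are invariant to sample order", {
  cfg <- sim_config(seed = 43, n_locations = 1,
                    n_per_group_per_location = 12, n_neutral_loci = 40,
                    n_outlier_loci = 0, miscall_rate = 0)
  mk <- simulate_dominant_markers(cfg)
  m <- mk$matrix
  f1 <- fst_dominant(m, "host", n_perm = 199, seed = 9)
  ord <- rev(seq_len(nrow(m$calls)))
  m2 <- m
  m2$calls <- m$calls[ord, , drop = FALSE]
  m2$meta <- m$meta[ord, , drop = FALSE]
  f2 <- fst_dominant(m2, "host", n_perm = 199, seed = 9)
  expect_equal(f1$fst, f2$fst, tolerance = 1e-12)
  # identical global statistic; permutation p within Monte-Carlo noise
  expect_lt(abs(f1$p - f2$p), 0.15)
})

test_that("null permutation p-values are roughly uniform", {
  set.seed(11)
  ps <- replicate(30, {
    calls <- matrix(rbinom(16 * 25, 1, 0.5), 16, 25)
    m <- toy_matrix(calls, host = sample(rep(c("a", "b"), each = 8)))
    fst_dominant(m, "host", n_perm = 199)$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("trimmed mean FST drops the configured tails", {
  expect_equal(trimmed_mean_fst(1:10, trim = 0.30), 5.5)
  expect_equal(trimmed_mean_fst(rep(3.2, 12)), 3.2)
  # a sub-100 permutation request is allowed but warns
  expect_warning(
    fst_dominant(toy_matrix(matrix(rbinom(40, 1, 0.5), 8, 5)), "host",
                 n_perm = 50),
    "coarse")
  x <- rnorm(50)
  expect_equal(trimmed_mean_fst(x, trim = 0), mean(x))
  expect_error(trimmed_mean_fst(1:10, trim = 0.5), "trim")
  expect_error(trimmed_mean_fst(1:3, trim = 0.3), "too few")
})
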