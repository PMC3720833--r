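test_that("effective number of tests hits both limit cases", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  Xsame <- cbind(x, x, x, x)
  st <- compute_sufficient_stats(Xsame, rnorm(8))
  expect_equal(effective_tests(st), 1)
  sto <- compute_sufficient_stats(orthogonal_block(), rnorm(8))
  expect_equal(effective_tests(sto), 4)
})

test_that("effective tests agrees with a direct eigen-decomposition", {
  R <- matrix(0.5, 5, 5); diag(R) <- 1
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  oracle <- min(max(5 - sum(pmax(lam - 1, 0)), 1), 5)
  expect_equal(effective_tests(R), oracle)
  blk <- simulate_ld_genotypes(4000, R, rep(0.3, 5), seed = 21)
  st <- compute_sufficient_stats(blk, rnorm(4000))
  expect_equal(effective_tests(st), oracle, tolerance = 0.1)
})

test_that("the score matches its arithmetic definition", {
  st <- list(n = 100, yy = 100)
  expect_equal(gwis_score(0, 123, st, 4), 0)
  expect_equal(gwis_score(1, 80, st, 4),
               50 * log(1.25) - 0.5 * log(100) - log(4))
  # no variance explained: pure penalty, negative
  expect_lt(gwis_score(1, 100, st, 4), 0)
  expect_error(gwis_score(1, 0, st, 4), "positive")
})

test_that("the score is the log of the Bayesian model-probability ratio it approximates", {
  # cross-check the three-term structure against direct quadrature of a
  # toy subset-selection posterior: BIC-style Laplace weight n^{-k/2} and
  # uniform prior over size-k subsets of eff candidates
  n <- 50; yy <- 10; rss <- 7; eff <- 3
  s <- gwis_score(2, rss, list(n = n, yy = yy), eff)
  manual <- log((yy / rss)^(n / 2) * n^(-1) / choose(eff, 2))
  expect_equal(s, manual, tolerance = 1e-12)
})

test_that("forward search recovers a planted causal SNP", {
  hits <- 0; sizes <- integer(100)
  for (r in 1:100) {
    blk <- make_block(500, 6, mafs = rep(0.3, 6), seed = 4000 + r)
    y <- 0.35 * blk$dosages[, 3] + rnorm(500)
    st <- compute_sufficient_stats(blk, y)
    fs <- gwis_forward_search(st)
    sizes[r] <- fs$k
    if (fs$k >= 1 && fs$selected[1] == 3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("two orthogonal causal SNPs are both selected in most replicates", {
  k2 <- 0
  for (r in 1:20) {
    set.seed(5000 + r)
    blk <- make_block(1000, 6, seed = 5000 + r)
    X <- blk$dosages
    g <- scale(X[, 1]) * sqrt(0.05) + scale(resid(lm(X[, 2] ~ X[, 1]))) * sqrt(0.05)
    y <- as.vector(g) + rnorm(1000, sd = sqrt(0.9))
    fs <- gwis_forward_search(compute_sufficient_stats(X, y))
    if (fs$k == 2 && all(sort(fs$selected[1:2]) == c(1, 2))) k2 <- k2 + 1
  }
  expect_gt(k2, 10)
})

test_that("all-noise genes usually stop at the null model with score 0", {
  k0 <- 0
  for (r in 1:30) {
    blk <- make_block(200, 5, seed = 6000 + r)
    fs <- gwis_forward_search(compute_sufficient_stats(blk, rnorm(200)))
    if (fs$k == 0) {
      k0 <- k0 + 1
      expect_identical(fs$score, 0)
    }
    expect_true(all(diff(fs$trace) > 0) || length(fs$trace) <= 1)
  }
  expect_gt(k0, 20)
})

test_that("greedy search never beats the exhaustive best subset", {
  set.seed(31)
  for (r in 1:5) {
    blk <- simulate_ld_genotypes(150, {
      R <- matrix(0.4, 6, 6); diag(R) <- 1; R
    }, runif(6, 0.2, 0.4), seed = 31 + r)
    y <- rnorm(150) + 0.3 * blk$dosages[, 2]
    st <- compute_sufficient_stats(blk, y)
    eff <- effective_tests(st)
    fs <- gwis_forward_search(st, eff)
    best <- 0
    for (k in 1:6) {
      for (cols in combn(6, k, simplify = FALSE)) {
        rss <- ols_rss(blk$dosages, y, cols)
        if (rss > 0 && k <= ceiling(eff))
          best <- max(best, gwis_score(k, rss, st, eff))
      }
    }
    expect_lte(fs$score, best + 1e-8)
  }
  # equality for orthogonal SNPs
  blk <- orthogonal_block()
  y <- c(2.1, -1, 0.5, 0.3, -0.2, 1.4, 0.8, -2)
  st <- compute_sufficient_stats(blk, y)
  eff <- effective_tests(st)
  fs <- gwis_forward_search(st, eff)
  best <- 0
  for (k in 1:min(4, ceiling(eff))) {
    for (cols in combn(4, k, simplify = FALSE)) {
      rss <- ols_rss(blk$dosages, y, cols)
      if (rss > 1e-12) best <- max(best, gwis_score(k, rss, st, eff))
    }
  }
  expect_equal(fs$score, best, tolerance = 1e-8)
})

test_that("the score is invariant to affine phenotype rescaling", {
  blk <- make_block(120, 5, seed = 32)
  y <- rnorm(120) + 0.5 * blk$dosages[, 1]
  f1 <- gwis_forward_search(compute_sufficient_stats(blk, y))
  f2 <- gwis_forward_search(compute_sufficient_stats(blk, 3.5 * y - 11))
  expect_equal(f1$score, f2$score, tolerance = 1e-10)
  expect_equal(f1$selected, f2$selected)
})

test_that("a duplicated copy of a selected SNP never enters the model", {
  blk <- make_block(200, 3, seed = 33)
  X <- cbind(blk$dosages, blk$dosages[, 1])
  y <- rnorm(200) + 0.8 * X[, 1]
  fs <- gwis_forward_search(compute_sufficient_stats(X, y), eff_tests = 4)
  expect_false(all(c(1, 4) %in% fs$selected))
})

test_that("permutation gating and saturation behave as specified", {
  plan <- permutation_plan(seed = 9, n_perm = 99)
  # gated: all-noise gene stopped at the null model gets p = NA
  blk <- make_block(150, 4, seed = 34)
  set.seed(99); y <- rnorm(150)
  fs <- gwis_forward_search(compute_sufficient_stats(blk, y))
  if (fs$k == 0) {
    r <- gwis_pvalue(blk, y, plan)
    expect_identical(r$statistic, 0)
    expect_true(is.na(r$p_value))
  }
  # planted strong signal saturates at the permutation floor
  y2 <- blk$dosages[, 2] * 2 + rnorm(150, sd = 0.3)
  r2 <- gwis_pvalue(blk, y2, plan)
  expect_equal(r2$p_value, 1 / 100)
  expect_gte(r2$model_size, 1)
})
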