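# Independent oracle: marginal likelihood of y ~ N(a + b x, s2 I) with
# a ~ N(0, tau0^2), b ~ N(0, sigma_a^2), by nested adaptive quadrature.
quad_log10_bf <- function(x, y, sigma_a, tau0) {
  n <- length(y)
  s2 <- sum((y - mean(y))^2) / n
  loglik <- function(a, b) sum(dnorm(y, a + b * x, sqrt(s2), log = TRUE))
  m1_inner <- function(a) {
    vapply(a, function(ai)
      integrate(function(b) vapply(b, function(bi)
        exp(loglik(ai, bi) - loglik(mean(y), 0)), numeric(1)) *
          dnorm(b, 0, sigma_a),
        -6 * sigma_a, 6 * sigma_a, rel.tol = 1e-10)$value, numeric(1))
  }
  lim <- mean(y) + c(-8, 8) * sqrt(s2)
  m1 <- integrate(function(a) m1_inner(a) * dnorm(a, 0, tau0),
                  lim[1], lim[2], rel.tol = 1e-10)$value
  m0 <- integrate(function(a) vapply(a, function(ai)
    exp(loglik(ai, 0) - loglik(mean(y), 0)), numeric(1)) * dnorm(a, 0, tau0),
    lim[1], lim[2], rel.tol = 1e-10)$value
  log10(m1 / m0)
}

test_that("a null prior (sigma_a = 0) gives a Bayes factor of exactly 1", {
  set.seed(50)
  x <- rbinom(30, 2, 0.3)
  y <- rnorm(30)
  expect_identical(bf_linear(x, y, bf_config(sigma_a = 0)), 0)
  expect_identical(bf_logistic(x, rbinom(30, 1, 0.5),
                               bf_config(sigma_a = 0)), 0)
})

test_that("closed-form linear BF matches adaptive quadrature to 1e-6 log10", {
  set.seed(51)
  x <- rbinom(50, 2, 0.35)
  y <- 0.25 * x + rnorm(50)
  cfg <- bf_config(sigma_a = 0.5, tau0 = 3)
  expect_equal(bf_linear(x, y, cfg), quad_log10_bf(x, y, 0.5, 3),
               tolerance = 1e-6)
  # and on null data
  y0 <- rnorm(50)
  expect_equal(bf_linear(x, y0, cfg), quad_log10_bf(x, y0, 0.5, 3),
               tolerance = 1e-6)
})

test_that("null-data linear BFs carry the Occam penalty on average", {
  set.seed(52)
  lbf <- replicate(200, {
    x <- rbinom(1000, 2, 0.3)
    bf_linear(x, rnorm(1000))
  })
  expect_lt(mean(lbf), 0)
})

test_that("Laplace logistic BF is within 0.15 log10 of grid integration", {
  set.seed(53)
  x <- rbinom(40, 2, 0.4)
  y <- rbinom(40, 1, plogis(-0.3 + 0.6 * (x - mean(x))))
  cfg <- bf_config(sigma_a = 0.8, tau0 = 4)
  # brute-force 2-D grid over (a, b)
  grid_logml <- function(W, sds) {
    a <- seq(-6, 6, length.out = 401)
    b <- if (ncol(W) == 2) seq(-4, 4, length.out = 401) else 0
    lp <- outer(a, b, Vectorize(function(ai, bi) {
      eta <- W %*% c(ai, bi)[seq_len(ncol(W))]
      sum(y * eta - log1p(exp(eta))) +
        sum(dnorm(c(ai, bi)[seq_len(ncol(W))], 0, sds, log = TRUE))
    }))
    m <- max(lp)
    da <- diff(a)[1]
    db <- if (length(b) > 1) diff(b)[1] else 1
    m + log(sum(exp(lp - m)) * da * db)
  }
  lg1 <- grid_logml(cbind(1, x), c(4, 0.8))
  lg0 <- grid_logml(matrix(1, 40, 1), 4)
  expect_equal(bf_logistic(x, y, cfg), (lg1 - lg0) / log(10),
               tolerance = 0.15)
})

test_that("balanced null logistic BFs are small and negative in expectation", {
  set.seed(54)
  lbf <- replicate(20, {
    x <- rbinom(500, 2, 0.3)
    bf_logistic(x, rbinom(500, 1, 0.5))
  })
  expect_lt(mean(lbf), 0)
  expect_lt(max(abs(lbf)), 2)
})

test_that("the gene statistic is the mean BF and collapses for copies", {
  set.seed(55)
  x <- rbinom(80, 2, 0.3)
  y <- 0.4 * x + rnorm(80)
  single <- bimbam_gene(matrix(x), y)
  expect_equal(single$statistic, 10^bf_linear(x, y))
  copies <- bimbam_gene(cbind(x, x, x), y)
  expect_equal(copies$statistic, single$statistic, tolerance = 1e-12)
  # two distinct SNPs: arithmetic mean of the BFs, not of the logs
  x2 <- rbinom(80, 2, 0.4)
  both <- bimbam_gene(cbind(x, x2), y)
  expect_equal(both$statistic,
               mean(c(10^bf_linear(x, y), 10^bf_linear(x2, y))),
               tolerance = 1e-10)
})

test_that("linear BF is invariant to phenotype centering and allele flips", {
  set.seed(56)
  x <- rbinom(60, 2, 0.25)
  y <- 0.3 * x + rnorm(60)
  cfg <- bf_config(sigma_a = 0.2, tau0 = 1e6)
  b0 <- bf_linear(x, y, cfg)
  expect_equal(bf_linear(x, y - mean(y), cfg), b0, tolerance = 1e-6)
  expect_equal(bf_linear(2 - x, y, cfg), b0, tolerance = 1e-6)
})

test_that("log10 BF grows with sample size for a fixed true effect", {
  set.seed(57)
  lbf_n <- vapply(c(200, 800, 3200), function(n) {
    mean(replicate(10, {
      x <- rbinom(n, 2, 0.3)
      bf_linear(x, 0.2 * x + rnorm(n))
    }))
  }, numeric(1))
  expect_true(all(diff(lbf_n) > 0))
})

test_that("monomorphic SNPs are rejected from BF computation", {
  expect_error(bf_linear(rep(1, 20), rnorm(20)), "monomorphic")
})
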