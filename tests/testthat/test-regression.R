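test_that("sufficient statistics match brute-force centered products", {
  set.seed(7)
  blk <- make_block(50, 5, seed = 7)
  y <- rnorm(50)
  st <- compute_sufficient_stats(blk, y)
  Xc <- scale(blk$dosages, scale = FALSE)
  expect_equal(st$gg, crossprod(Xc), ignore_attr = TRUE)
  expect_equal(st$gy, as.vector(crossprod(Xc, y - mean(y))))
  expect_equal(st$yy, sum((y - mean(y))^2))
})

test_that("identical SNP columns share all gg entries", {
  X <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1))
  st <- compute_sufficient_stats(X, c(1, 3, 2, 5))
  expect_equal(st$gg[1, 2], st$gg[1, 1])
  expect_equal(st$gg[1, 2], st$gg[2, 2])
})

test_that("a phenotype orthogonal to the SNPs gives vanishing gy", {
  set.seed(8)
  blk <- make_block(40, 4, seed = 8)
  y0 <- rnorm(40)
  y <- resid(lm(y0 ~ blk$dosages))  # exact residualization
  st <- compute_sufficient_stats(blk, y)
  expect_lt(max(abs(st$gy)), 1e-10)
})

test_that("zero-variance phenotype is an error", {
  blk <- make_block(10, 2, seed = 1)
  expect_error(compute_sufficient_stats(blk, rep(1, 10)), "variance")
})

test_that("single-SNP linear fits match lm() to 6 significant digits", {
  set.seed(100)
  blk <- make_block(100, 3, seed = 100)
  y <- 0.3 * blk$dosages[, 2] + rnorm(100)
  st <- compute_sufficient_stats(blk, y)
  for (j in 1:3) {
    fit <- linear_fit_single(st, j)
    ref <- summary(lm(y ~ blk$dosages[, j]))$coefficients[2, ]
    expect_rel_equal(fit$beta, ref["Estimate"], 1e-6)
    expect_rel_equal(fit$se, ref["Std. Error"], 1e-6)
    expect_rel_equal(fit$p, ref["Pr(>|t|)"], 1e-6)
  }
})

test_that("single-SNP fit limit cases behave", {
  x <- c(0, 1, 2, 0, 1, 2)
  st <- compute_sufficient_stats(matrix(x), 2 * x)        # y proportional to x
  fit <- linear_fit_single(st, 1)
  expect_equal(fit$p, 0)
  y <- c(1, -1, 0, -1, 1, 0)                              # exactly orthogonal
  st2 <- compute_sufficient_stats(matrix(x), y)
  expect_equal(st2$gy[1], 0)
  fit2 <- linear_fit_single(st2, 1)
  expect_equal(fit2$beta, 0)
  expect_equal(fit2$statistic, 0)
  expect_equal(fit2$p, 1)
  # monomorphic SNP flagged, not fit
  stm <- suppressWarnings(compute_sufficient_stats(cbind(x, 1), 2 * x))
  expect_warning(expect_null(linear_fit_single(stm, 2)), "monomorphic")
})

test_that("covariate residualization equals joint fitting (Frisch-Waugh)", {
  set.seed(9)
  blk <- make_block(80, 3, seed = 9)
  cv <- cbind(rnorm(80), rbinom(80, 1, 0.5))
  y <- 0.5 * cv[, 1] + 0.3 * blk$dosages[, 1] + rnorm(80)
  st <- compute_sufficient_stats(blk, y, covariates = cv)
  for (j in 1:3) {
    fit <- linear_fit_single(st, j)
    ref <- summary(lm(y ~ cv + blk$dosages[, j]))$coefficients[4, ]
    expect_rel_equal(fit$beta, ref["Estimate"], 1e-8)
    expect_rel_equal(fit$se, ref["Std. Error"], 1e-8)
  }
})

test_that("IRLS logistic regression matches glm() and flags separation", {
  # intercept-only closed form
  y <- c(rep(1, 30), rep(0, 70))
  fit0 <- logistic_irls(matrix(1, 100, 1), y)
  expect_equal(fit0$beta, log(0.3 / 0.7), tolerance = 1e-8)
  # null covariate, n = 200, against glm
  set.seed(200)
  x <- rnorm(200)
  yb <- rbinom(200, 1, 0.5)
  fit <- logistic_irls(cbind(1, x), yb)
  ref <- glm(yb ~ x, family = binomial())
  expect_lt(max(abs(fit$beta - unname(coef(ref)))), 1e-6)
  expect_lt(max(abs(fit$se - unname(summary(ref)$coefficients[, 2]))), 1e-5)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-6)
  # perfect separation: all cases dosage 2, controls dosage 0
  xs <- c(rep(2, 20), rep(0, 20))
  ys <- c(rep(1, 20), rep(0, 20))
  sep <- logistic_irls(cbind(1, xs), ys, max_iter = 100)
  expect_true(sep$separated)
})

test_that("IRLS log-likelihood is non-decreasing across iterations", {
  set.seed(11)
  X <- cbind(1, rnorm(60), rbinom(60, 2, 0.3))
  y <- rbinom(60, 1, plogis(X %*% c(-0.5, 1, 0.8)))
  ll <- function(b) sum(y * (X %*% b) - log1p(exp(X %*% b)))
  lls <- vapply(1:8, function(k) ll(logistic_irls(X, y, max_iter = k)$beta),
                numeric(1))
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("Gram-Schmidt rejects in-span SNPs and is additive when orthogonal", {
  X <- orthogonal_block()$dosages
  y <- rnorm(8)
  st <- compute_sufficient_stats(X, y)
  s0 <- ortho_init(st)
  s1 <- gram_schmidt_add(s0, 1)
  red1 <- s0$rss - s1$rss
  s2a <- gram_schmidt_add(s0, 2)
  red2 <- s0$rss - s2a$rss
  s12 <- gram_schmidt_add(s1, 2)
  expect_equal(s0$rss - s12$rss, red1 + red2, tolerance = 1e-10)
  # duplicate of a selected SNP is rejected
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  std <- compute_sufficient_stats(Xd, y)
  sd1 <- gram_schmidt_add(ortho_init(std), 1)
  sd2 <- gram_schmidt_add(sd1, 2)
  expect_true(attr(sd2, "rejected"))
  expect_equal(sd2$selected, sd1$selected)
})

test_that("forward Gram-Schmidt RSS equals the OLS refit on selected columns", {
  set.seed(12)
  N <- 60
  base <- matrix(rbinom(N * 3, 2, 0.3), N, 3)
  # correlated 6-SNP block
  X <- cbind(base, pmin(pmax(base + matrix(rbinom(N * 3, 1, 0.3), N, 3) -
                               matrix(rbinom(N * 3, 1, 0.3), N, 3), 0), 2))
  y <- rnorm(N) + 0.4 * X[, 2]
  st <- compute_sufficient_stats(X, y)
  s <- gram_schmidt_add(gram_schmidt_add(ortho_init(st), 2), 4)
  expect_rel_equal(s$rss, ols_rss(X, y, c(2, 4)), 1e-8)
  # property over random subsets
  for (cols in list(1, c(1, 5), c(2, 3, 6), c(1, 2, 3, 4))) {
    s <- ortho_init(st)
    for (j in cols) s <- gram_schmidt_add(s, j)
    if (!isTRUE(attr(s, "rejected")))
      expect_rel_equal(s$rss, ols_rss(X, y, cols), 1e-8)
  }
})

test_that("null single-SNP scan is calibrated at the 5% level", {
  set.seed(13)
  blk <- make_block(300, 1000, mafs = runif(1000, 0.1, 0.5), seed = 13)
  y <- rnorm(300)
  scan <- single_snp_scan(blk, y)
  frac <- mean(scan$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("logistic scan suppresses Wald statistics under separation", {
  X <- cbind(c(rep(2, 15), rep(0, 15)), rbinom(30, 2, 0.4))
  snps <- data.frame(id = c("sep", "ok"), chrom = "1", pos = c(1000L, 2000L),
                     ref = "A", alt = "G", maf = NA_real_)
  blk <- genotype_block(X, snps)
  y <- c(rep(1, 15), rep(0, 15))
  scan <- single_snp_scan(blk, y, model = "logistic")
  expect_true(is.na(scan$p[1]))
  expect_false(is.na(scan$p[2]))
})
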