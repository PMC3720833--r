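#' Bayes-factor prior configuration
#'
#' Prior for the single-SNP regression `y ~ a + b x`: independent zero-mean
#' Gaussians with SD `tau0` on the intercept (large, effectively flat) and
#' `sigma_a` on the additive effect -- `sigma_a` is the adjustable "typical
#' additive variance for a SNP".  `sigma_a = 0` collapses the alternative
#' onto the null, giving a Bayes factor of exactly 1.
#'
#' @param sigma_a prior SD of the dosage effect (dosage scale).
#' @param tau0 prior SD of the intercept.
#' @export
bf_config <- function(sigma_a = 0.2, tau0 = 1e6) {
  stopifnot(sigma_a >= 0, tau0 > 0)
  structure(list(sigma_a = sigma_a, tau0 = tau0), class = "bf_config")
}

# Closed-form log10 Bayes factor for the Gaussian model with fixed residual
# variance sigma2 (the null MLE yy/n), from raw moments.  Vectorized over
# sxy (and, when vectors, sx/sxx), which is all a phenotype permutation
# changes.  Derivation: with prior beta ~ N(0, D), D = diag(tau0^2,
# sigma_a^2), the marginal of y is Gaussian with covariance
# sigma2 I + W D W'; the BF is the ratio of that density to the
# intercept-only one, reduced to 2x2 algebra by Woodbury.
bf_linear_core <- function(n, sx, sxx, sy, syy, sxy, sigma_a, tau0, sigma2) {
  if (sigma_a == 0) return(rep(0, length(sxy)))
  d1 <- tau0^2; d2 <- sigma_a^2
  a <- sigma2 / d1 + n          # A = sigma2 D^-1 + W'W
  c <- sx
  e <- sigma2 / d2 + sxx
  det_a <- a * e - c^2
  q1 <- syy - (e * sy^2 - 2 * c * sy * sxy + a * sxy^2) / det_a
  q0 <- syy - sy^2 / a
  # det(I + D^{1/2} W'W D^{1/2} / sigma2) for models 1 and 0
  logdet1 <- log((1 + d1 * n / sigma2) * (1 + d2 * sxx / sigma2) -
                   d1 * d2 * sx^2 / sigma2^2)
  logdet0 <- log1p(d1 * n / sigma2)
  (-0.5 * (logdet1 - logdet0) - (q1 - q0) / (2 * sigma2)) / log(10)
}

#' Single-SNP linear Bayes factor
#'
#' Closed-form log10 Bayes factor of `y ~ a + b x` against `y ~ a`, with
#' the Gaussian prior of [bf_config()] and residual variance fixed at the
#' null maximum-likelihood value `var(y) * (n-1)/n`.  Exact Gaussian
#' algebra; validated against adaptive quadrature of the marginal
#' likelihood over `(a, b)`.
#'
#' @param x dosage column (must be polymorphic).
#' @param y phenotype values.
#' @param config a [bf_config()].
#' @return log10 Bayes factor (scalar).
#' @export
bf_linear <- function(x, y, config = bf_config()) {
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  if (stats::var(x) == 0) stop("monomorphic SNP: Bayes factor undefined")
  n <- length(yv)
  syy_c <- sum((yv - mean(yv))^2)
  bf_linear_core(n, sum(x), sum(x^2), sum(yv), sum(yv^2), sum(x * yv),
                 config$sigma_a, config$tau0, syy_c / n)
}

# Penalized logistic log-posterior (up to the prior normalizing constant)
# and its gradient; W includes the intercept column, prec = 1/prior var.
logit_post <- function(beta, W, y, prec) {
  eta <- as.vector(W %*% beta)
  list(value = sum(y * eta - log1p(exp(eta))) - sum(prec * beta^2) / 2,
       grad = as.vector(crossprod(W, y - 1 / (1 + exp(-eta)))) - prec * beta)
}

# Fletcher-Reeves nonlinear conjugate gradient ascent on the penalized
# logistic log-likelihood.  Backtracking line search; restart every
# length(beta) * 5 iterations; converged when the gradient infinity-norm
# drops below tol.
fletcher_reeves <- function(W, y, prec, tol = 1e-6, max_iter = 200) {
  beta <- rep(0, ncol(W))
  st <- logit_post(beta, W, y, prec)
  g <- st$grad
  d <- g
  gg_old <- sum(g^2)
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol)
      return(list(beta = beta, value = st$value, converged = TRUE, iter = it))
    alpha <- 1
    repeat {
      cand <- beta + alpha * d
      stc <- logit_post(cand, W, y, prec)
      if (is.finite(stc$value) &&
          stc$value >= st$value + 1e-4 * alpha * sum(g * d)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { stc <- st; cand <- beta; break }
    }
    beta <- cand
    st <- stc
    g <- st$grad
    gg_new <- sum(g^2)
    d <- if (it %% (5 * length(beta)) == 0 || gg_old == 0) g else
      g + (gg_new / gg_old) * d
    gg_old <- gg_new
  }
  list(beta = beta, value = st$value, converged = max(abs(g)) < tol,
       iter = max_iter)
}

# Laplace-approximate log marginal likelihood of a penalized logistic
# model; d = ncol(W), prior SDs sds.  Includes the prior normalization, so
# differences are log Bayes factors.
laplace_logml <- function(W, y, sds, tol = 1e-6) {
  prec <- 1 / sds^2
  fit <- fletcher_reeves(W, y, prec, tol = tol)
  if (!fit$converged) {
    warning("Fletcher-Reeves did not converge; falling back to IRLS mode")
    irls <- logistic_irls(W, y, penalty = prec)
    post <- logit_post(irls$beta, W, y, prec)
    fit <- list(beta = irls$beta, value = post$value)
  }
  eta <- as.vector(W %*% fit$beta)
  p <- 1 / (1 + exp(-eta))
  H <- crossprod(W, W * (p * (1 - p))) + diag(prec, ncol(W))
  fit$value - sum(log(sds)) - 0.5 * determinant(H)$modulus[1]
}

#' Single-SNP logistic Bayes factor (Laplace approximation)
#'
#' Posterior modes of the penalized logistic models (with and without the
#' SNP) are located by Fletcher-Reeves conjugate gradients; the marginal
#' likelihoods come from the Laplace determinant of the Hessian at each
#' mode, and their ratio is the Bayes factor.  Falls back to an IRLS-found
#' mode with a warning if CG stalls.
#'
#' @inheritParams bf_linear
#' @param y 0/1 phenotype.
#' @return log10 Bayes factor.
#' @export
bf_logistic <- function(x, y, config = bf_config()) {
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  if (!all(yv %in% c(0, 1))) stop("logistic Bayes factor needs a 0/1 phenotype")
  if (stats::var(x) == 0) stop("monomorphic SNP: Bayes factor undefined")
  if (config$sigma_a == 0) return(0)
  W1 <- cbind(1, x)
  W0 <- matrix(1, length(yv), 1)
  lm1 <- laplace_logml(W1, yv, c(config$tau0, config$sigma_a))
  lm0 <- laplace_logml(W0, yv, config$tau0)
  (lm1 - lm0) / log(10)
}

#' BIMBAM gene statistic: average single-SNP Bayes factor
#'
#' The gene statistic is the arithmetic mean of the per-SNP Bayes factors
#' (of the factors themselves, not their logs) over all polymorphic SNPs in
#' the gene; the empirical p-value ranks it against the shared phenotype
#' permutation stream.  A single-SNP gene's statistic equals that SNP's BF,
#' and duplicated SNPs leave the statistic unchanged.
#'
#' @param block gene-level [genotype_block()] or dosage matrix.
#' @param y phenotype.
#' @param config a [bf_config()].
#' @param plan a [permutation_plan()]; `NULL` skips the p-value.
#' @param model `"linear"` or `"logistic"` (permutations for the logistic
#'   model refit every Laplace BF and are accordingly slow).
#' @param perms optional precomputed shuffle matrix (shared stream).
#' @return one-row gene-result data frame; the per-SNP log10 BF vector is
#'   attached as attribute `"log10_bf"`.
#' @export
bimbam_gene <- function(block, y, config = bf_config(), plan = NULL,
                        model = c("linear", "logistic"), perms = NULL) {
  model <- match.arg(model)
  X <- if (inherits(block, "genotype_block")) block$dosages else as.matrix(block)
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  keep <- apply(X, 2, stats::var) > 0
  M <- ncol(X)
  if (!any(keep)) {
    res <- gene_result("bimbam", NA_real_, NA_real_, 0L, M, M)
    attr(res, "log10_bf") <- rep(NA_real_, M)
    return(res)
  }
  Xp <- X[, keep, drop = FALSE]
  n <- length(yv)
  mean_bf <- function(lbf) exp(logsumexp(lbf * log(10)) - log(length(lbf)))
  if (model == "linear") {
    sx <- colSums(Xp); sxx <- colSums(Xp^2)
    sy <- sum(yv); syy <- sum(yv^2)
    sigma2 <- sum((yv - mean(yv))^2) / n
    lbf <- bf_linear_core(n, sx, sxx, sy, syy, as.vector(crossprod(Xp, yv)),
                          config$sigma_a, config$tau0, sigma2)
    stat <- mean_bf(lbf)
    p <- NA_real_; B <- 0L
    if (!is.null(plan)) {
      if (is.null(perms)) perms <- shuffle_stream(plan, n)
      B <- ncol(perms)
      Sxy <- crossprod(Xp, matrix(yv[perms], nrow = n))
      null_stats <- vapply(seq_len(B), function(b)
        mean_bf(bf_linear_core(n, sx, sxx, sy, syy, Sxy[, b],
                               config$sigma_a, config$tau0, sigma2)),
        numeric(1))
      p <- empirical_p(stat, null_stats)
    }
  } else {
    lbf <- vapply(seq_len(ncol(Xp)), function(j)
      bf_logistic(Xp[, j], yv, config), numeric(1))
    stat <- mean_bf(lbf)
    p <- NA_real_; B <- 0L
    if (!is.null(plan)) {
      if (is.null(perms)) perms <- shuffle_stream(plan, n)
      B <- ncol(perms)
      null_stats <- vapply(seq_len(B), function(b) {
        yb <- yv[perms[, b]]
        mean_bf(vapply(seq_len(ncol(Xp)), function(j)
          bf_logistic(Xp[, j], yb, config), numeric(1)))
      }, numeric(1))
      p <- empirical_p(stat, null_stats)
    }
  }
  res <- gene_result("bimbam", stat, p, B, M, M)
  full <- rep(NA_real_, M)
  full[keep] <- lbf
  attr(res, "log10_bf") <- full
  res
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
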