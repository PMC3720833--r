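#' Per-gene sufficient statistics
#'
#' Everything the gene-based tests need from individual-level data: the
#' centered genotype-genotype inner-product matrix `gg = Xc'Xc`, the
#' centered genotype-phenotype products `gy = Xc'yc`, the phenotype sum of
#' squares about its mean `yy`, plus the genotype means, phenotype mean and
#' degrees-of-freedom bookkeeping.  When covariates are supplied both
#' genotypes and phenotype are first residualized on `[1, covariates]`
#' (the Frisch-Waugh projection), so all downstream linear fits are
#' identical to joint fits that include the covariates.
#'
#' @param block a [genotype_block()] or a bare dosage matrix.
#' @param y a [phenotype_vector()] or numeric vector.
#' @param covariates optional numeric matrix (`N x C`), without intercept.
#' @return class `"suff_stats"`: list with `n`, `gg`, `gy`, `yy`, `g_means`,
#'   `y_mean`, `n_covariates`, `df_null` (residual df of the
#'   intercept+covariate model) and `snp_ids`.
#' @export
compute_sufficient_stats <- function(block, y, covariates = NULL) {
  X <- if (inherits(block, "genotype_block")) block$dosages else as.matrix(block)
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  if (length(yv) != nrow(X)) stop("phenotype length != sample count")
  if (stats::var(yv) <= 0) stop("phenotype variance must be positive")
  n <- nrow(X)
  g_means <- colMeans(X)
  y_mean <- mean(yv)
  n_cov <- 0L
  if (!is.null(covariates)) {
    C <- cbind(1, as.matrix(covariates))
    n_cov <- ncol(C) - 1L
    q <- qr(C)
    Xc <- qr.resid(q, X)
    yc <- qr.resid(q, yv)
  } else {
    Xc <- sweep(X, 2, g_means)
    yc <- yv - y_mean
  }
  structure(list(n = n,
                 gg = crossprod(Xc),
                 gy = as.vector(crossprod(Xc, yc)),
                 yy = sum(yc^2),
                 g_means = g_means,
                 y_mean = y_mean,
                 n_covariates = n_cov,
                 df_null = n - 1L - n_cov,
                 snp_ids = colnames(X)),
            class = "suff_stats")
}

# Subset a suff_stats object to SNP indices j (used by the gene loop).
subset_stats <- function(stats, j) {
  structure(list(n = stats$n,
                 gg = stats$gg[j, j, drop = FALSE],
                 gy = stats$gy[j],
                 yy = stats$yy,
                 g_means = stats$g_means[j],
                 y_mean = stats$y_mean,
                 n_covariates = stats$n_covariates,
                 df_null = stats$df_null,
                 snp_ids = stats$snp_ids[j]),
            class = "suff_stats")
}

#' Single-SNP linear fit from sufficient statistics
#'
#' Ordinary least squares of the (covariate-residualized, centered)
#' phenotype on one SNP column: `beta = gy[j]/gg[j,j]`,
#' `RSS = yy - gy[j]^2/gg[j,j]`, F on (1, n - 2 - n_covariates) df.
#'
#' @param stats a [compute_sufficient_stats()] object.
#' @param j SNP column index.
#' @return list `beta, se, statistic` (F), `p`, `df`; or `NULL` with a
#'   warning for a monomorphic SNP (`gg[j,j] == 0`).
#' @export
linear_fit_single <- function(stats, j) {
  sxx <- stats$gg[j, j]
  if (sxx <= 0) {
    warning("monomorphic SNP at column ", j, "; excluded from fitting")
    return(NULL)
  }
  df <- stats$df_null - 1L
  beta <- stats$gy[j] / sxx
  rss <- max(stats$yy - stats$gy[j]^2 / sxx, 0)
  if (rss == 0) {
    return(list(beta = beta, se = 0, statistic = Inf, p = 0, df = df))
  }
  Fst <- (stats$yy - rss) / (rss / df)
  list(beta = beta,
       se = sqrt(rss / df / sxx),
       statistic = Fst,
       p = stats::pf(Fst, 1, df, lower.tail = FALSE),
       df = df)
}

# Vectorized per-SNP linear statistics for one phenotype cross-product
# vector gy (all SNPs at once); dg = diag(gg).  Returns F statistics.
f_stats_vec <- function(gy, dg, yy, df) {
  sxx <- pmax(dg, .Machine$double.eps)
  expl <- gy^2 / sxx
  rss <- pmax(yy - expl, yy * 1e-15)
  ifelse(dg <= 0, NA_real_, expl / (rss / df))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Plain Newton/IRLS on the binomial log-likelihood with step-halving
#' whenever a step would decrease the likelihood, so the log-likelihood is
#' non-decreasing across iterations.  Standard errors come from the inverse
#' observed information at the final iterate.  Perfect separation is
#' flagged when coefficients diverge (`max |beta| > 30` on the logit scale
#' for standardized-scale designs); the fit is returned with
#' `separated = TRUE` and Wald statistics should not be trusted.
#'
#' @param X design matrix including the intercept column.
#' @param y 0/1 response.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param max_iter maximum Newton iterations.
#' @param penalty optional Gaussian prior precision vector (diagonal), used
#'   by the Bayes-factor code; 0 = unpenalized.
#' @return list `beta, se, loglik, converged, separated, n_iter, deviance`.
#' @export
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 25, penalty = NULL) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("logistic response must be 0/1")
  d <- ncol(X)
  if (is.null(penalty)) penalty <- rep(0, d)
  beta <- rep(0, d)
  ll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(penalty * b^2) / 2
  }
  ll_old <- ll(beta)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    H <- crossprod(X, X * w) + diag(penalty, d)
    g <- as.vector(crossprod(X, y - p)) - penalty * beta
    delta <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, d), g)
    })
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- ll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; ll_new <- ll_old; break }
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_old <- ll_new
    if (moved < tol) { converged <- TRUE; break }
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- pmax(p * (1 - p), 1e-12)
  H <- crossprod(X, X * w) + diag(penalty, d)
  Hinv <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-8, d)))
  separated <- max(abs(beta)) > 10 && !converged
  loglik <- sum(y * eta - log1p(exp(eta)))
  list(beta = beta, se = sqrt(pmax(diag(Hinv), 0)), loglik = loglik,
       converged = converged, separated = separated, n_iter = it,
       deviance = -2 * loglik)
}

# Deviance of the intercept-only logistic model (closed form).
logistic_null_deviance <- function(y) {
  p <- mean(y)
  if (p <= 0 || p >= 1) return(0)
  n <- length(y)
  -2 * (sum(y) * log(p) + (n - sum(y)) * log(1 - p))
}

# ---- incremental Gram-Schmidt over sufficient statistics ----------------

#' Initialize the orthonormalization state for forward selection
#'
#' The state tracks, entirely in sufficient-statistic space, an orthonormal
#' basis (under the `gg` inner product) for the selected SNPs, together with
#' the residual genotype-phenotype products and residual diagonal of `gg`
#' for every candidate SNP, and the current residual sum of squares of the
#' phenotype.  Adding a SNP is O(P) given the state.
#'
#' @param stats a [compute_sufficient_stats()] object (possibly gene-subset).
#' @param eps_collinear relative threshold on residual variance below which
#'   a candidate is declared in the span of the selected set (scale-free:
#'   multiplied by the SNP's original `gg` diagonal).
#' @return class `"ortho_state"`.
#' @export
ortho_init <- function(stats, eps_collinear = 1e-8) {
  P <- length(stats$gy)
  dg <- diag(stats$gg)
  structure(list(stats = stats,
                 selected = integer(0),
                 basis = matrix(0, P, 0),   # coefficients over raw SNPs
                 gy_res = stats$gy,
                 dg_res = dg,
                 dg0 = dg,
                 rss = stats$yy,
                 eps = eps_collinear * pmax(dg, .Machine$double.eps)),
            class = "ortho_state")
}

#' Add one SNP to the orthonormal basis
#'
#' The new direction is SNP `j` minus its projection on the selected
#' directions, normalized under the `gg` inner product; residual products
#' and the phenotype RSS are updated for all SNPs.  A SNP whose residual
#' variance falls below the collinearity threshold is rejected (it lies in
#' the span of the selected set).
#'
#' @param state an [ortho_init()] state.
#' @param j candidate SNP index.
#' @return the updated state, or the input state with attribute
#'   `"rejected" = TRUE` when `j` is numerically collinear.
#' @export
gram_schmidt_add <- function(state, j) {
  if (state$dg_res[j] <= state$eps[j]) {
    attr(state, "rejected") <- TRUE
    return(state)
  }
  stats <- state$stats
  P <- length(state$gy_res)
  nrm <- sqrt(state$dg_res[j])
  # raw-coordinate coefficients of the new orthonormal direction
  c_raw <- numeric(P)
  c_raw[j] <- 1
  if (ncol(state$basis) > 0) {
    # projection coefficients of e_j on previous directions: (gg C)[j, ]
    proj <- as.vector(crossprod(state$basis, stats$gg[, j]))
    c_raw <- c_raw - as.vector(state$basis %*% proj)
  }
  c_new <- c_raw / nrm
  w <- as.vector(stats$gg %*% c_new)        # gg inner products with all SNPs
  t_new <- state$gy_res[j] / nrm            # c_new' gy (residual form)
  state$selected <- c(state$selected, j)
  state$basis <- cbind(state$basis, c_new)
  state$gy_res <- state$gy_res - t_new * w
  state$dg_res <- pmax(state$dg_res - w^2, 0)
  state$rss <- max(state$rss - t_new^2, 0)
  attr(state, "rejected") <- FALSE
  state
}

#' Single-SNP association scan
#'
#' One fit per polymorphic SNP over the whole input (genic and intergenic
#' alike): ordinary least squares for `model = "linear"`, IRLS logistic
#' regression (intercept + covariates + SNP) for `model = "logistic"`.
#'
#' @param block a [genotype_block()].
#' @param y a [phenotype_vector()] or numeric vector.
#' @param covariates optional covariate matrix.
#' @param model `"linear"` or `"logistic"`.
#' @return data frame `snp_id, beta, se, statistic, p, maf, n`; monomorphic
#'   SNPs carry `NA` fits.  The `statistic` column is the F statistic
#'   (linear) or the 1-df Wald chi-square (logistic).
#' @export
single_snp_scan <- function(block, y, covariates = NULL,
                            model = c("linear", "logistic")) {
  model <- match.arg(model)
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  X <- block$dosages
  P <- ncol(X)
  out <- data.frame(snp_id = block$snps$id,
                    beta = NA_real_, se = NA_real_,
                    statistic = NA_real_, p = NA_real_,
                    maf = block$snps$maf, n = nrow(X),
                    stringsAsFactors = FALSE)
  if (model == "linear") {
    stats <- compute_sufficient_stats(block, yv, covariates)
    dg <- diag(stats$gg)
    poly <- dg > 0
    df <- stats$df_null - 1L
    sxx <- ifelse(poly, dg, NA_real_)
    beta <- stats$gy / sxx
    rss <- pmax(stats$yy - stats$gy^2 / sxx, 0)
    Fst <- ifelse(rss > 0, (stats$yy - rss) / (rss / df), Inf)
    out$beta <- beta
    out$se <- sqrt(rss / df / sxx)
    out$statistic <- Fst
    out$p <- stats::pf(Fst, 1, df, lower.tail = FALSE)
  } else {
    base <- if (is.null(covariates)) matrix(1, nrow(X), 1) else
      cbind(1, as.matrix(covariates))
    for (j in seq_len(P)) {
      if (stats::var(X[, j]) == 0) next
      fit <- logistic_irls(cbind(base, X[, j]), yv)
      k <- ncol(base) + 1L
      if (fit$separated) {
        out$beta[j] <- fit$beta[k]
        next  # Wald statistics suppressed under separation
      }
      out$beta[j] <- fit$beta[k]
      out$se[j] <- fit$se[k]
      wald <- (fit$beta[k] / fit$se[k])^2
      out$statistic[j] <- wald
      out$p[j] <- stats::pchisq(wald, 1, lower.tail = FALSE)
    }
  }
  out
}
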