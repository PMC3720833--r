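#' Effective number of tests in a gene
#'
#' Phenotype-independent measure of the number of independent signals among
#' the gene's SNPs, computed from the eigenvalues of the SNP correlation
#' matrix: `Me = P - sum(max(lambda_i - 1, 0))`, clamped to `[1, P]`.  Equals
#' `P` for pairwise-uncorrelated SNPs and 1 when all SNPs are copies of one
#' another.  Used as the subset-selection penalty scale in the GWiS score.
#'
#' @param stats a [compute_sufficient_stats()] object (gene-level), or a
#'   correlation matrix directly.
#' @return a single number in `[1, P]` (monomorphic SNPs are excluded from
#'   `P`).
#' @export
effective_tests <- function(stats) {
  if (is.matrix(stats)) {
    R <- stats
  } else {
    dg <- diag(stats$gg)
    keep <- dg > 0
    if (!any(keep)) return(1)
    g <- stats$gg[keep, keep, drop = FALSE]
    s <- sqrt(diag(g))
    R <- g / tcrossprod(s)
  }
  P <- ncol(R)
  if (P == 1) return(1)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min(max(P - sum(pmax(lam - 1, 0)), 1), P)
}

# ln of the generalized binomial coefficient C(eff, k) for real eff >= 1.
lchoose_real <- function(eff, k) {
  if (k <= 0) return(0)
  if (k >= eff) return(0)  # C(eff, eff) = 1; search stops past this point
  lgamma(eff + 1) - lgamma(k + 1) - lgamma(eff - k + 1)
}

#' GWiS model score
#'
#' Approximate log posterior model probability for a `k`-SNP linear model:
#' a likelihood-ratio term `(n/2) ln(yy / rss_k)`, a BIC penalty
#' `(k/2) ln(n)`, and a subset-selection penalty `ln C(eff_tests, k)` with
#' the generalized (Gamma-function) binomial over the real-valued effective
#' number of tests.  The null model scores exactly 0.
#'
#' @param k model size (number of selected SNPs).
#' @param rss_k residual sum of squares of the k-SNP model; must be > 0.
#' @param stats the gene's [compute_sufficient_stats()] (supplies `n`, `yy`).
#' @param eff_tests the gene's [effective_tests()].
#' @return the score (a real; negative when the fit does not justify the
#'   penalties).
#' @export
gwis_score <- function(k, rss_k, stats, eff_tests) {
  if (k == 0) return(0)
  if (rss_k <= 0) stop("rss_k must be positive (perfect fit must be caught upstream)")
  (stats$n / 2) * log(stats$yy / rss_k) -
    (k / 2) * log(stats$n) -
    lchoose_real(eff_tests, k)
}

# Core greedy forward search over sufficient statistics.  Returns the
# selected model and both the reported score (max(final, 0), 0 for the null
# model) and the continuous raw statistic (best score over non-empty
# models, sign kept) used for permutation ranking.
gwis_search_core <- function(gg, dg, gy, yy, n, eff, kmax,
                             eps = 1e-8 * pmax(dg, .Machine$double.eps)) {
  P <- length(gy)
  gy_res <- gy
  dg_res <- dg
  rss <- yy
  basis <- matrix(0, P, 0)
  sel <- integer(0)
  trace <- numeric(0)
  score_cur <- 0
  raw <- -Inf
  ln_n <- log(n)
  k <- 0
  while (k < kmax) {
    ok <- dg_res > eps
    if (length(sel)) ok[sel] <- FALSE
    if (!any(ok)) break
    red <- ifelse(ok, gy_res^2 / dg_res, -Inf)
    j <- as.integer(which.max(red))  # ties: lowest index wins
    rss_new <- rss - red[j]
    if (rss_new <= 0) rss_new <- yy * 1e-15
    s <- (n / 2) * log(yy / rss_new) - ((k + 1) / 2) * ln_n -
      lchoose_real(eff, k + 1)
    if (s > raw) raw <- s
    if (s <= score_cur) break
    # accept j: orthonormal update
    nrm <- sqrt(dg_res[j])
    c_raw <- numeric(P); c_raw[j] <- 1
    if (ncol(basis) > 0) {
      proj <- as.vector(crossprod(basis, gg[, j]))
      c_raw <- c_raw - as.vector(basis %*% proj)
    }
    c_new <- c_raw / nrm
    w <- as.vector(gg %*% c_new)
    t_new <- gy_res[j] / nrm
    gy_res <- gy_res - t_new * w
    dg_res <- pmax(dg_res - w^2, 0)
    rss <- rss_new
    basis <- cbind(basis, c_new)
    sel <- c(sel, j)
    k <- k + 1
    score_cur <- s
    trace <- c(trace, s)
  }
  list(k = length(sel), selected = sel, score = max(score_cur, 0),
       raw = raw, trace = trace, rss = rss)
}

#' Greedy forward search for the GWiS gene statistic
#'
#' Starting from the null model, the SNP giving the maximal score increase
#' is added (via incremental Gram-Schmidt orthonormalization) until no
#' remaining SNP increases the score or the model size reaches
#' `ceiling(eff_tests)`.  Exact score ties break to the lowest SNP index.
#'
#' For `model = "logistic"` the likelihood-ratio term is replaced by half
#' the deviance reduction from [logistic_irls()] refits (intercept and any
#' covariates always included); penalties are unchanged.
#'
#' @param stats gene-level [compute_sufficient_stats()].
#' @param eff_tests the gene's [effective_tests()]; computed when `NULL`.
#' @param max_k optional cap on model size.
#' @param model `"linear"` (sufficient statistics only) or `"logistic"`.
#' @param block,y,covariates raw data, required for the logistic model.
#' @return list with `k`, `selected` (SNP indices, in entry order), `score`
#'   (reported statistic, `>= 0`, 0 for the null model), `raw` (continuous
#'   search maximum over non-empty models, may be negative), `trace`
#'   (strictly increasing accepted scores) and `rss` (linear model only).
#' @export
gwis_forward_search <- function(stats, eff_tests = NULL, max_k = Inf,
                                model = c("linear", "logistic"),
                                block = NULL, y = NULL, covariates = NULL) {
  model <- match.arg(model)
  if (is.null(eff_tests)) eff_tests <- effective_tests(stats)
  P <- length(stats$gy)
  kmax <- min(P, ceiling(eff_tests), max_k)
  if (model == "linear") {
    return(gwis_search_core(stats$gg, diag(stats$gg), stats$gy, stats$yy,
                            stats$n, eff_tests, kmax))
  }
  # logistic: greedy refits on deviance
  X <- if (inherits(block, "genotype_block")) block$dosages else as.matrix(block)
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  base <- if (is.null(covariates)) matrix(1, nrow(X), 1) else
    cbind(1, as.matrix(covariates))
  dev0 <- logistic_irls(base, yv)$deviance
  dg <- diag(stats$gg)
  sel <- integer(0)
  trace <- numeric(0)
  score_cur <- 0
  raw <- -Inf
  dev_cur <- dev0
  ln_n <- log(stats$n)
  while (length(sel) < kmax) {
    cand <- setdiff(which(dg > 0), sel)
    if (!length(cand)) break
    devs <- vapply(cand, function(j)
      logistic_irls(cbind(base, X[, c(sel, j), drop = FALSE]), yv)$deviance,
      numeric(1))
    j <- cand[which.min(devs)]
    k1 <- length(sel) + 1L
    s <- (dev0 - min(devs)) / 2 - (k1 / 2) * ln_n - lchoose_real(eff_tests, k1)
    if (s > raw) raw <- s
    if (s <= score_cur) break
    sel <- c(sel, j)
    dev_cur <- min(devs)
    score_cur <- s
    trace <- c(trace, s)
  }
  list(k = length(sel), selected = sel, score = max(score_cur, 0),
       raw = raw, trace = trace, rss = NA_real_, deviance = dev_cur)
}

#' GWiS gene p-value by phenotype permutation
#'
#' The observed forward-search statistic is ranked against the same search
#' applied to phenotype permutations from the shared Fisher-Yates stream:
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`.  Following the reference
#' procedure, only genes whose reported score exceeds 0 undergo permutation
#' when `gate = TRUE` (the default); a gene stopped at the null model gets
#' `p = NA` and is reported non-significant.  `gate = FALSE` ranks the
#' continuous search maximum for every gene (used for calibration studies,
#' where the gated conditional p-values are by construction the significant
#' tail).
#'
#' @param block gene-level [genotype_block()] (or dosage matrix).
#' @param y phenotype.
#' @param plan a [permutation_plan()].
#' @param covariates optional covariates (residualized out once).
#' @param gate apply the score > 0 permutation gate.
#' @param perms optional precomputed shuffle matrix (shared stream).
#' @return one-row data frame in gene-result form: `method, statistic,
#'   p_value, n_permutations, model_size, snp_count`.
#' @export
gwis_pvalue <- function(block, y, plan, covariates = NULL, gate = TRUE,
                        perms = NULL) {
  stats <- compute_sufficient_stats(block, y, covariates)
  eff <- effective_tests(stats)
  obs <- gwis_forward_search(stats, eff)
  if (gate && obs$score <= 0) {
    return(gene_result("gwis", obs$score, NA_real_, 0L, obs$k,
                       length(stats$gy)))
  }
  X <- if (inherits(block, "genotype_block")) block$dosages else as.matrix(block)
  prep <- perm_prep(X, y, covariates)
  if (is.null(perms)) perms <- shuffle_stream(plan, stats$n)
  Gy <- crossprod(prep$Xc, matrix(prep$yc[perms], nrow = stats$n))
  dg <- diag(stats$gg)
  kmax <- min(length(stats$gy), ceiling(eff))
  raws <- vapply(seq_len(ncol(Gy)), function(b)
    gwis_search_core(stats$gg, dg, Gy[, b], stats$yy, stats$n, eff,
                     kmax)$raw,
    numeric(1))
  p <- empirical_p(obs$raw, raws)
  gene_result("gwis", obs$score, p, ncol(Gy), obs$k, length(stats$gy))
}

# Uniform one-row gene-result constructor shared by all methods.
gene_result <- function(method, statistic, p_value, n_perm, model_size,
                        snp_count, gene_id = NA_character_) {
  data.frame(gene_id = gene_id, method = method, statistic = statistic,
             p_value = p_value, n_permutations = n_perm,
             model_size = model_size, snp_count = snp_count,
             stringsAsFactors = FALSE)
}

# Centered / covariate-residualized design and phenotype, shared by the
# permutation drivers (residualization happens once, before shuffling).
perm_prep <- function(X, y, covariates = NULL) {
  X <- as.matrix(X)
  yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
  if (!is.null(covariates)) {
    q <- qr(cbind(1, as.matrix(covariates)))
    list(Xc = qr.resid(q, X), yc = qr.resid(q, yv))
  } else {
    list(Xc = sweep(X, 2, colMeans(X)), yc = yv - mean(yv))
  }
}
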