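#' VEGAS gene statistic
#'
#' The sum of the single-SNP chi-squares over the gene's SNPs.
#'
#' @param chi2_per_snp vector of per-SNP 1-df chi-square (or F) statistics;
#'   `NA` entries (monomorphic SNPs) are dropped.
#' @return the sum (a scalar).
#' @export
vegas_statistic <- function(chi2_per_snp) {
  sum(chi2_per_snp, na.rm = TRUE)
}

#' VEGAS gene test with permutation p-value
#'
#' Per-SNP F statistics are computed from the gene's sufficient statistics,
#' summed, and the sum is ranked against the same quantity under phenotype
#' permutations from the shared stream.  (In summary mode the driver uses
#' [simulate_null_z()] draws instead; see [gene_scan()].)
#'
#' @param block gene-level [genotype_block()] or dosage matrix.
#' @param y phenotype.
#' @param plan a [permutation_plan()]; `NULL` skips the p-value.
#' @param covariates optional covariates.
#' @param perms optional precomputed shuffle matrix (shared stream).
#' @return one-row gene-result data frame.
#' @export
vegas_gene <- function(block, y, plan = NULL, covariates = NULL,
                       perms = NULL) {
  stats <- compute_sufficient_stats(block, y, covariates)
  dg <- diag(stats$gg)
  df <- stats$df_null - 1L
  obs <- vegas_statistic(f_stats_vec(stats$gy, dg, stats$yy, df))
  p <- NA_real_; B <- 0L
  if (!is.null(plan)) {
    X <- if (inherits(block, "genotype_block")) block$dosages else as.matrix(block)
    prep <- perm_prep(X, y, covariates)
    if (is.null(perms)) perms <- shuffle_stream(plan, stats$n)
    B <- ncol(perms)
    Gy <- crossprod(prep$Xc, matrix(prep$yc[perms], nrow = stats$n))
    nulls <- vapply(seq_len(B), function(b)
      vegas_statistic(f_stats_vec(Gy[, b], dg, stats$yy, df)), numeric(1))
    p <- empirical_p(obs, nulls)
  }
  gene_result("vegas", obs, p, B, length(dg), length(dg))
}

#' Effective number of independent p-values (GATES)
#'
#' `Me = M - sum(max(lambda_i - 1, 0))` over the eigenvalues of the p-value
#' correlation matrix, clamped to `[1, M]`: the identity matrix gives `M`,
#' a rank-one all-ones matrix gives 1.
#'
#' @param r_p M x M p-value correlation matrix.
#' @export
gates_m_e <- function(r_p) {
  M <- ncol(r_p)
  if (M == 1) return(1)
  lam <- eigen(r_p, symmetric = TRUE, only.values = TRUE)$values
  min(max(M - sum(pmax(lam - 1, 0)), 1), M)
}

#' GATES gene p-value (extended Simes)
#'
#' With ascending single-SNP p-values `p_(1) <= ... <= p_(M)` the gene
#' p-value is `min_j { Me * p_(j) / Me(j) }`, where `Me(j)` is the
#' effective number of independent p-values among the top `j` SNPs
#' ([gates_m_e()] on the leading submatrix of the reordered correlation
#' matrix) and `Me = Me(M)`.  For independent SNPs `Me(j) = j` and the
#' statistic reduces exactly to the Simes p-value.  No permutations are
#' needed: the statistic is approximately uniform under the null and is
#' itself the p-value.
#'
#' By default the p-value correlation is approximated by the absolute
#' genotype correlation; pass a different `r_p` to substitute another
#' estimator without touching the procedure.
#'
#' @param p_values per-SNP p-values (`NA` entries dropped).
#' @param genotype_corr SNP genotype correlation matrix (signed; its
#'   absolute value is used), or `NULL` for independent SNPs.
#' @param r_p optional explicit p-value correlation matrix overriding the
#'   genotype approximation.
#' @return the gene p-value in (0, 1\], or `NA` for an empty gene.
#' @export
gates_pvalue <- function(p_values, genotype_corr = NULL, r_p = NULL) {
  keep <- which(!is.na(p_values))
  if (!length(keep)) return(NA_real_)
  p <- p_values[keep]
  M <- length(p)
  if (is.null(r_p)) {
    r_p <- if (is.null(genotype_corr)) diag(1, M) else
      abs(genotype_corr[keep, keep, drop = FALSE])
  } else {
    r_p <- r_p[keep, keep, drop = FALSE]
  }
  o <- order(p)
  p <- p[o]
  r_p <- r_p[o, o, drop = FALSE]
  me_j <- vapply(seq_len(M), function(j)
    gates_m_e(r_p[seq_len(j), seq_len(j), drop = FALSE]), numeric(1))
  me <- me_j[M]
  min(max(min(me * p / me_j), .Machine$double.xmin), 1)
}

# Shared helper: observed per-SNP F statistics and their permutation nulls.
minsnp_machinery <- function(block, y, plan, covariates, perms) {
  stats <- compute_sufficient_stats(block, y, covariates)
  dg <- diag(stats$gg)
  df <- stats$df_null - 1L
  Fobs <- f_stats_vec(stats$gy, dg, stats$yy, df)
  Fnull <- NULL
  if (!is.null(plan)) {
    X <- if (inherits(block, "genotype_block")) block$dosages else as.matrix(block)
    prep <- perm_prep(X, y, covariates)
    if (is.null(perms)) perms <- shuffle_stream(plan, stats$n)
    Gy <- crossprod(prep$Xc, matrix(prep$yc[perms], nrow = stats$n))
    Fnull <- apply(Gy, 2, f_stats_vec, dg = dg, yy = stats$yy, df = df)
    if (is.null(dim(Fnull))) Fnull <- matrix(Fnull, nrow = 1)
  }
  list(stats = stats, Fobs = Fobs, Fnull = Fnull, df = df)
}

#' MinSNP: best single-SNP p-value in the gene
#'
#' Each SNP gets a p-value -- parametric from the F distribution for common
#' SNPs, empirical from the shared permutation stream for SNPs with minor
#' allele frequency below `maf_switch`, where the parametric tail is
#' unreliable.  The gene's p-value is the best (smallest) of these, with no
#' gene-size correction; the statistic is the best F.
#'
#' @inheritParams vegas_gene
#' @param maf_switch MAF threshold below which the per-SNP p-value comes
#'   from permutations.
#' @return one-row gene-result data frame (`model_size = 1`).
#' @export
minsnp <- function(block, y, plan = NULL, covariates = NULL,
                   maf_switch = 0.01, perms = NULL) {
  mach <- minsnp_machinery(block, y, plan, covariates, perms)
  M <- length(mach$Fobs)
  mafs <- if (inherits(block, "genotype_block")) block$snps$maf else {
    f <- colMeans(as.matrix(block)) / 2
    pmin(f, 1 - f)
  }
  p_snp <- stats::pf(mach$Fobs, 1, mach$df, lower.tail = FALSE)
  B <- if (is.null(mach$Fnull)) 0L else ncol(mach$Fnull)
  rare <- which(!is.na(mach$Fobs) & mafs < maf_switch)
  if (length(rare) && B > 0) {
    for (j in rare)
      p_snp[j] <- empirical_p(mach$Fobs[j], mach$Fnull[j, ])
  }
  best <- if (all(is.na(p_snp))) NA_integer_ else which.min(p_snp)
  gene_result("minsnp",
              if (is.na(best)) NA_real_ else mach$Fobs[best],
              if (is.na(best)) NA_real_ else p_snp[best],
              B, 1L, M)
}

#' MinSNP-Gene: best-F statistic with gene-level permutation p
#'
#' The gene statistic is the best single-SNP F within the gene; its p-value
#' comes from gene-level permutations of the phenotype (the max-F null),
#' which corrects for gene size.  For `M` independent SNPs this approaches
#' the Sidak bound `1 - (1 - p_min)^M`.
#'
#' @inheritParams vegas_gene
#' @return one-row gene-result data frame (`model_size = 1`).
#' @export
minsnp_gene <- function(block, y, plan = NULL, covariates = NULL,
                        perms = NULL) {
  mach <- minsnp_machinery(block, y, plan, covariates, perms)
  M <- length(mach$Fobs)
  obs <- suppressWarnings(max(mach$Fobs, na.rm = TRUE))
  if (!is.finite(obs) && obs == -Inf)
    return(gene_result("minsnp_gene", NA_real_, NA_real_, 0L, 1L, M))
  p <- NA_real_; B <- 0L
  if (!is.null(mach$Fnull)) {
    B <- ncol(mach$Fnull)
    nulls <- apply(mach$Fnull, 2, max, na.rm = TRUE)
    p <- empirical_p(obs, nulls)
  }
  gene_result("minsnp_gene", obs, p, B, 1L, M)
}
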