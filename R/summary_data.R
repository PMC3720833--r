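#' Per-gene LD cache over a reference panel
#'
#' Wraps a [read_panel()] with a cache of fetched genotype-dosage columns
#' and pairwise correlations.  Entries are computed on demand ("dynamically
#' when needed"), never genome-wide, and the cache is meant to live for one
#' gene: memory stays bounded by gene size.  Lookup is pair-order
#' symmetric.
#'
#' @param panel a [read_panel()] object.
#' @return class `"panel_ld"`.
#' @export
panel_ld <- function(panel) {
  structure(list(panel = panel,
                 geno = new.env(parent = emptyenv()),
                 corr = new.env(parent = emptyenv())),
            class = "panel_ld")
}

# Panel genotype dosages for one SNP (haplotypes paired in file order),
# cached; NULL on index miss.
panel_genotype <- function(ld, snp_id) {
  g <- get0(snp_id, envir = ld$geno, inherits = FALSE)
  if (!is.null(g)) return(g)
  h <- panel_fetch(ld$panel, snp_id)
  if (is.null(h)) return(NULL)
  if (length(h) %% 2L != 0L) stop("odd haplotype count for ", snp_id)
  g <- h[c(TRUE, FALSE)] + h[c(FALSE, TRUE)]
  assign(snp_id, g, envir = ld$geno)
  g
}

# Pairwise panel genotype correlation, cached symmetrically.
panel_corr <- function(ld, id_i, id_j) {
  key <- paste(sort(c(id_i, id_j)), collapse = "\r")
  r <- get0(key, envir = ld$corr, inherits = FALSE)
  if (!is.null(r)) return(r)
  gi <- panel_genotype(ld, id_i)
  gj <- panel_genotype(ld, id_j)
  if (is.null(gi) || is.null(gj)) return(NULL)
  r <- if (stats::var(gi) == 0 || stats::var(gj) == 0) 0 else
    stats::cor(gi, gj)
  assign(key, r, envir = ld$corr)
  r
}

#' Genotype covariance of two SNPs estimated from a reference panel
#'
#' The panel supplies only the correlation `r_ij`; the variance scale comes
#' from the study minor-allele frequencies via the Hardy-Weinberg dosage
#' variance `2 f (1 - f)`:
#' `cov_ij = r_ij * sqrt(2 f_i (1 - f_i) * 2 f_j (1 - f_j))`.
#' For `i = j` this is exactly `2 f (1 - f)` (0.5 at `f = 0.5`).
#'
#' @param ld a [panel_ld()] cache (or [read_panel()], wrapped on the fly).
#' @param id_i,id_j SNP ids.
#' @param f_i,f_j study minor-allele frequencies.
#' @return per-observation covariance estimate, or `NULL` when either SNP
#'   is absent from the panel.
#' @export
cov_from_panel <- function(ld, id_i, id_j, f_i, f_j) {
  if (inherits(ld, "reference_panel")) ld <- panel_ld(ld)
  v_i <- 2 * f_i * (1 - f_i)
  if (id_i == id_j) return(v_i)
  r <- panel_corr(ld, id_i, id_j)
  if (is.null(r)) return(NULL)
  v_j <- 2 * f_j * (1 - f_j)
  r * sqrt(v_i * v_j)
}

#' Genotype-phenotype inner product recovered from summary statistics
#'
#' Inverts the single-SNP least-squares relations
#' `beta = S_xy / S_xx` and `se^2 = (S_yy - beta S_xy) / ((n-2) S_xx)`
#' for the centered products, given the phenotype moments:
#' `S_xx = S_yy / (se^2 (n-2) + beta^2)` and `S_xy = beta * S_xx`.
#' This is the unique consistent inversion and is exact (no reference
#' panel enters).
#'
#' @param rec one summary record (list/row with `beta`, `se`, `n`).
#' @param pheno_var,pheno_mean phenotype moments of the original study
#'   (defaults: z-score scale, mean 0 and variance 1).
#' @return list `sxy` (centered genotype-phenotype product), `sxx`
#'   (centered genotype sum of squares), `syy`.
#' @export
xty_from_summary <- function(rec, pheno_var = 1, pheno_mean = 0) {
  if (!(rec$se > 0)) stop("summary record rejected: se must be positive")
  syy <- pheno_var * (rec$n - 1)
  sxx <- syy / (rec$se^2 * (rec$n - 2) + rec$beta^2)
  list(sxy = rec$beta * sxx, sxx = sxx, syy = syy)
}

#' Gene sufficient statistics from summary records plus a reference panel
#'
#' Assembles the same object [compute_sufficient_stats()] produces from
#' individual-level data, so GWiS, BIMBAM, VEGAS and the MinSNP tests run
#' unchanged on it: the `gg` diagonal and `gy` come from the exact
#' least-squares inversion of (beta, se, n) ([xty_from_summary()]),
#' off-diagonal `gg` entries scale the panel correlation by the recovered
#' diagonals, and `yy` comes from the phenotype variance.  SNPs absent
#' from the panel are dropped with a message.  Panel allele orientation is
#' checked against the study MAF and flipped when the folded frequencies
#' disagree.
#'
#' @param records summary data frame (`snp_id, beta, se, maf, n`).
#' @param panel a [read_panel()] or [panel_ld()] object.
#' @param pheno_moments list with `mean` and `variance` of the study
#'   phenotype (defaults to the z-score scale: 0 and 1).
#' @return a `"suff_stats"` object with extra fields `z` (per-SNP z-scores),
#'   `R` (panel LD correlation), `maf` and `records`; or `NULL` when no
#'   record survives.
#' @export
gene_stats_from_summary <- function(records, panel,
                                    pheno_moments = list(mean = 0,
                                                         variance = 1)) {
  ld <- if (inherits(panel, "panel_ld")) panel else panel_ld(panel)
  present <- vapply(records$snp_id, function(id)
    !is.null(panel_genotype(ld, id)), logical(1))
  if (any(!present))
    message(sum(!present), " SNP(s) absent from panel dropped: ",
            paste(records$snp_id[!present], collapse = ", "))
  records <- records[present, , drop = FALSE]
  M <- nrow(records)
  if (M == 0) return(NULL)
  n <- as.integer(round(stats::median(records$n)))
  inv <- lapply(seq_len(M), function(i)
    xty_from_summary(records[i, ], pheno_moments$variance))
  sxx <- vapply(inv, `[[`, numeric(1), "sxx")
  gy <- vapply(inv, `[[`, numeric(1), "sxy")
  yy <- pheno_moments$variance * (n - 1)
  # panel LD, with orientation check against study MAF
  G <- matrix(NA_real_, 0, 0)
  R <- diag(1, M)
  if (M > 1) {
    cols <- lapply(records$snp_id, panel_genotype, ld = ld)
    for (i in seq_len(M)) {
      fp <- mean(cols[[i]]) / 2
      if (abs(fp - records$maf[i]) > abs((1 - fp) - records$maf[i]))
        cols[[i]] <- 2 - cols[[i]]
    }
    G <- do.call(cbind, cols)
    sds <- apply(G, 2, stats::sd)
    ok <- sds > 0
    R[ok, ok] <- stats::cor(G[, ok, drop = FALSE])
  }
  gg <- R * tcrossprod(sqrt(sxx))
  structure(list(n = n, gg = gg, gy = gy, yy = yy,
                 g_means = 2 * records$maf, y_mean = pheno_moments$mean,
                 n_covariates = 0L, df_null = n - 1L,
                 snp_ids = records$snp_id,
                 z = records$beta / records$se, R = R,
                 maf = records$maf, records = records),
            class = c("summary_stats", "suff_stats"))
}

#' Gene-based tests from summary-mode sufficient statistics
#'
#' Runs the requested methods on a [gene_stats_from_summary()] object.
#' Statistics are computed from the reconstructed sufficient statistics
#' (GWiS, BIMBAM) or directly from the z-scores (VEGAS, GATES, MinSNP);
#' p-values come from multivariate-normal null z-scores simulated with the
#' gene's LD matrix ([simulate_null_z()]) instead of phenotype
#' permutations.  Case-control summary data is handled with the linear
#' approximation throughout.
#'
#' @param sstats a [gene_stats_from_summary()] object.
#' @param methods subset of `c("gwis","bimbam","vegas","gates","minsnp",
#'   "minsnp_gene")`.
#' @param n_sims number of null z-score simulations.
#' @param seed RNG seed for the simulations.
#' @param bf a [bf_config()] for BIMBAM.
#' @param maf_switch MinSNP parametric/empirical threshold.
#' @param gate GWiS permutation gate (see [gwis_pvalue()]).
#' @return data frame of one-row gene results, one per method.
#' @export
summary_gene_tests <- function(sstats,
                               methods = c("gwis", "bimbam", "vegas",
                                           "gates", "minsnp", "minsnp_gene"),
                               n_sims = 1e4, seed = 1, bf = bf_config(),
                               maf_switch = 0.01, gate = TRUE) {
  M <- length(sstats$z)
  z2 <- sstats$z^2
  nz <- simulate_null_z(sstats$R, n_sims, seed)$z
  dg <- diag(sstats$gg)
  n <- sstats$n
  yy <- sstats$yy
  # null gy draws implied by simulated z-scores (null residual variance)
  gy_null <- function(zrow) zrow * sqrt(yy * dg / (n - 2))
  out <- list()
  for (m in methods) {
    res <- switch(m,
      vegas = {
        obs <- sum(z2)
        p <- empirical_p(obs, rowSums(nz^2))
        gene_result("vegas", obs, p, n_sims, M, M)
      },
      gates = {
        p_snp <- stats::pchisq(z2, 1, lower.tail = FALSE)
        gene_result("gates", gates_pvalue(p_snp, sstats$R),
                    gates_pvalue(p_snp, sstats$R), 0L, M, M)
      },
      minsnp = {
        p_snp <- stats::pchisq(z2, 1, lower.tail = FALSE)
        rare <- which(sstats$maf < maf_switch)
        for (j in rare) p_snp[j] <- empirical_p(z2[j], nz[, j]^2)
        best <- which.min(p_snp)
        gene_result("minsnp", z2[best], p_snp[best], n_sims, 1L, M)
      },
      minsnp_gene = {
        obs <- max(z2)
        p <- empirical_p(obs, apply(nz^2, 1, max))
        gene_result("minsnp_gene", obs, p, n_sims, 1L, M)
      },
      gwis = {
        eff <- effective_tests(sstats$R)
        kmax <- min(M, ceiling(eff))
        obs <- gwis_search_core(sstats$gg, dg, sstats$gy, yy, n, eff, kmax)
        if (gate && obs$score <= 0) {
          gene_result("gwis", obs$score, NA_real_, 0L, obs$k, M)
        } else {
          raws <- vapply(seq_len(nrow(nz)), function(b)
            gwis_search_core(sstats$gg, dg, gy_null(nz[b, ]), yy, n, eff,
                             kmax)$raw, numeric(1))
          gene_result("gwis", obs$score, empirical_p(obs$raw, raws),
                      n_sims, obs$k, M)
        }
      },
      bimbam = {
        sx <- n * sstats$g_means
        sxx_raw <- dg + sx^2 / n
        sy <- n * sstats$y_mean
        syy_raw <- yy + sy^2 / n
        sigma2 <- yy / n
        sxy <- sstats$gy + sx * sy / n
        mean_bf <- function(lbf) exp(logsumexp(lbf * log(10)) - log(M))
        lbf <- bf_linear_core(n, sx, sxx_raw, sy, syy_raw, sxy,
                              bf$sigma_a, bf$tau0, sigma2)
        obs <- mean_bf(lbf)
        nulls <- vapply(seq_len(nrow(nz)), function(b)
          mean_bf(bf_linear_core(n, sx, sxx_raw, sy, syy_raw,
                                 gy_null(nz[b, ]) + sx * sy / n,
                                 bf$sigma_a, bf$tau0, sigma2)),
          numeric(1))
        r <- gene_result("bimbam", obs, empirical_p(obs, nulls), n_sims, M, M)
        attr(r, "log10_bf") <- lbf
        r
      },
      stop("unknown method: ", m))
    out[[m]] <- res
  }
  do.call(rbind, out)
}
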