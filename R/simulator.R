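#' @keywords internal
#' Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

#' Construct a genotype block
#'
#' A genotype block couples an `N x P` dosage matrix (fractional minor-allele
#' dosages in \[0,2\], as produced by imputation) with its SNP annotation and
#' sample identifiers.  It is the unit every gene-based test consumes.
#'
#' @param dosages numeric `N x P` matrix, finite values in \[0,2\].
#' @param snps data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf` (one row per dosage column).  `maf` may be `NA` and is then
#'   computed from the dosages (folded to \[0, 0.5\]).
#' @param sample_ids character vector of length `N`.
#' @return an object of class `"genotype_block"`: a list with elements
#'   `dosages`, `snps`, `sample_ids`.
#' @export
genotype_block <- function(dosages, snps, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosages)))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(nrow(snps) == ncol(dosages), length(sample_ids) == nrow(dosages))
  bad <- which(!is.finite(dosages) | dosages < 0 | dosages > 2)
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(dosages)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(dosages)) + 1L
    stop(sprintf("dosage out of [0,2] at sample %d (%s), SNP %d (%s): %g",
                 i, sample_ids[i], j, snps$id[j], dosages[bad[1]]))
  }
  for (ch in unique(snps$chrom)) {
    ids <- snps$id[snps$chrom == ch]
    if (anyDuplicated(ids))
      stop("duplicate SNP id within chromosome ", ch, ": ",
           ids[duplicated(ids)][1])
  }
  if (is.null(snps$maf) || anyNA(snps$maf)) {
    f <- colMeans(dosages) / 2
    snps$maf <- pmin(f, 1 - f)
  }
  dimnames(dosages) <- list(sample_ids, snps$id)
  structure(list(dosages = dosages, snps = snps, sample_ids = sample_ids),
            class = "genotype_block")
}

#' @export
print.genotype_block <- function(x, ...) {
  cat(sprintf("genotype block: %d samples x %d SNPs (%s..%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              x$snps$id[1], x$snps$id[nrow(x$snps)]))
  invisible(x)
}

#' Construct a phenotype vector
#'
#' @param values numeric vector; for a dichotomous trait every value must be
#'   0 or 1.
#' @param trait_type `"continuous"` or `"dichotomous"`; guessed from the
#'   values when missing.
#' @return class `"phenotype"`: list with `values`, `trait_type`, `mean`,
#'   `variance`.
#' @export
phenotype_vector <- function(values, trait_type = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("phenotype contains missing values")
  if (is.null(trait_type))
    trait_type <- if (all(values %in% c(0, 1))) "dichotomous" else "continuous"
  trait_type <- match.arg(trait_type, c("continuous", "dichotomous"))
  if (trait_type == "dichotomous" && !all(values %in% c(0, 1)))
    stop("dichotomous phenotype must be coded 0/1")
  v <- stats::var(values)
  if (!is.finite(v) || v <= 0) stop("phenotype variance must be positive")
  structure(list(values = values, trait_type = trait_type,
                 mean = mean(values), variance = v),
            class = "phenotype")
}

as_phenotype <- function(y) {
  if (inherits(y, "phenotype")) y else phenotype_vector(y)
}

#' Simulation design for case-control data
#'
#' The defaults reproduce the package's standard evaluation design: 500
#' cases and 5500 controls genotyped at 10,000 independent SNPs, of which 10
#' are disease-associated with a multiplicative homozygote risk of 1.5.
#'
#' @param n_cases,n_controls sample sizes per group.
#' @param n_snps total SNP count (independent, Hardy-Weinberg).
#' @param n_causal number of disease-associated SNPs.
#' @param hom_risk multiplicative relative risk for minor-allele homozygotes
#'   (per-allele relative risk is `sqrt(hom_risk)` under the default
#'   `risk_model = "homozygote"`).
#' @param maf_range minor-allele-frequency range, drawn uniformly.
#' @param gene_len_range gene lengths in SNPs (uniform integer draw).
#' @param prevalence baseline disease prevalence for the penetrance model.
#' @param risk_model `"homozygote"` (per-allele RR `sqrt(hom_risk)`) or
#'   `"per_allele"` (per-allele RR `hom_risk`, homozygote `hom_risk^2`).
#' @param seed RNG seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_cases = 500, n_controls = 5500, n_snps = 10000,
                       n_causal = 10, hom_risk = 1.5,
                       maf_range = c(0.05, 0.45),
                       gene_len_range = c(10, 100),
                       prevalence = 0.01,
                       risk_model = c("homozygote", "per_allele"),
                       seed = 1) {
  risk_model <- match.arg(risk_model)
  stopifnot(n_causal <= n_snps, hom_risk > 0,
            maf_range[1] > 0, maf_range[1] <= maf_range[2],
            maf_range[2] < 0.5)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_snps = n_snps, n_causal = n_causal, hom_risk = hom_risk,
                 maf_range = maf_range, gene_len_range = gene_len_range,
                 prevalence = prevalence, risk_model = risk_model,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a case-control GWAS dataset
#'
#' SNPs are independent with Hardy-Weinberg genotype frequencies at MAFs
#' drawn uniformly from `cfg$maf_range`.  Causal SNPs act multiplicatively
#' on disease risk per minor-allele copy; with the default reading the
#' homozygote relative risk equals `cfg$hom_risk`.  Genotypes for cases and
#' controls are drawn from the exact conditional genotype distributions
#' implied by the penetrance model and baseline prevalence, which yields the
#' same joint law as prospective sampling continued until the two group
#' sizes are reached.
#'
#' @param cfg a [sim_config()].
#' @return list with `block` (a [genotype_block()], cases first), `phenotype`
#'   (a dichotomous [phenotype_vector()]), and `causal` (character vector of
#'   causal SNP ids).
#' @export
simulate_case_control <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    P <- cfg$n_snps
    N <- cfg$n_cases + cfg$n_controls
    mafs <- runif(P, cfg$maf_range[1], cfg$maf_range[2])
    causal <- sort(sample.int(P, cfg$n_causal))
    rr <- switch(cfg$risk_model,
                 homozygote = sqrt(cfg$hom_risk),
                 per_allele = cfg$hom_risk)
    # all-null draw first (vectorized), then overwrite causal columns
    X <- matrix(rbinom(N * P, 2L, rep(mafs, each = N)), N, P)
    y <- c(rep(1, cfg$n_cases), rep(0, cfg$n_controls))
    for (j in causal) {
      f <- mafs[j]
      pg <- c((1 - f)^2, 2 * f * (1 - f), f^2)
      pen <- rr^(0:2)
      b <- cfg$prevalence / sum(pg * pen)       # baseline penetrance
      pen <- pmin(b * pen, 1)
      p_case <- pg * pen / sum(pg * pen)
      p_ctrl <- pg * (1 - pen) / sum(pg * (1 - pen))
      X[, j] <- c(sample(0:2, cfg$n_cases, TRUE, p_case),
                  sample(0:2, cfg$n_controls, TRUE, p_ctrl))
    }
    ids <- sprintf("snp%05d", seq_len(P))
    snps <- data.frame(id = ids, chrom = "1", pos = 1000L * (seq_len(P) + 1L),
                       ref = "A", alt = "G", maf = NA_real_,
                       stringsAsFactors = FALSE)
    block <- genotype_block(X, snps,
                            sample_ids = sprintf("ind%05d", seq_len(N)))
    list(block = block, phenotype = phenotype_vector(y, "dichotomous"),
         causal = ids[causal])
  })
}

#' Tile SNPs into non-overlapping simulated genes
#'
#' Genes cover all SNPs sequentially without overlap starting from the first
#' SNP; each gene's length (in SNPs) is uniform on
#' `{len_range[1], ..., len_range[2]}` and the final gene is truncated at the
#' last SNP.  Base-pair coordinates come from `positions` (default: SNP `i`
#' at `1000*(i+1)` bp); each gene spans its SNPs' bp range.
#'
#' @param n_snps number of SNPs to tile.
#' @param len_range integer 2-vector, inclusive gene-length range in SNPs.
#' @param seed RNG seed.
#' @param positions optional integer vector of SNP bp positions.
#' @param chrom chromosome label for all genes.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end` and a
#'   list column `snp_indices`; the indices partition `1:n_snps`.
#' @export
simulate_gene_structure <- function(n_snps, len_range = c(10, 100),
                                    seed = NULL, positions = NULL,
                                    chrom = "1") {
  stopifnot(n_snps >= 1, len_range[1] >= 1, len_range[1] <= len_range[2])
  if (is.null(positions)) positions <- 1000L * (seq_len(n_snps) + 1L)
  with_seed(seed, {
    starts <- integer(0); ends <- integer(0)
    at <- 1L
    lens <- seq.int(len_range[1], len_range[2])
    while (at <= n_snps) {
      len <- lens[sample.int(length(lens), 1L)]
      starts <- c(starts, at)
      ends <- c(ends, min(at + len - 1L, n_snps))
      at <- at + len
    }
    g <- length(starts)
    data.frame(gene_id = sprintf("gene%04d", seq_len(g)),
               chrom = chrom,
               start = positions[starts],
               end = positions[ends],
               snp_indices = I(mapply(seq.int, starts, ends,
                                      SIMPLIFY = FALSE)),
               stringsAsFactors = FALSE)
  })
}

# Bivariate standard-normal CDF by 1-D quadrature (used only to calibrate
# the latent copula correlation; small M, cached per pair).
pbinorm <- function(a, b, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  f <- function(z) dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2))
  integrate(f, -8, a, rel.tol = 1e-10)$value
}

# Latent correlation such that thresholded-indicator correlation hits target.
latent_rho <- function(target, f1, f2) {
  if (abs(target) < 1e-12) return(0)
  t1 <- qnorm(f1); t2 <- qnorm(f2)
  s <- sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  g <- function(r) (pbinorm(t1, t2, r) - f1 * f2) / s - target
  uniroot(g, c(-0.9999, 0.9999), tol = 1e-8)$root
}

#' Simulate genotype dosages with a target LD structure
#'
#' Haplotype alleles are generated by thresholding latent multivariate-normal
#' draws at the allele frequencies (a Gaussian copula); the latent
#' correlation for each SNP pair is calibrated numerically so that the
#' *observed dosage* correlation converges to the requested `R`, undoing the
#' attenuation that naive thresholding induces.
#'
#' @param N number of individuals (two independent haplotypes each).
#' @param R target SNP-SNP dosage correlation matrix (unit diagonal).
#' @param mafs minor-allele frequencies, length `ncol(R)`.
#' @param seed RNG seed.
#' @param chrom,pos0 annotation for the returned block.
#' @return a [genotype_block()] with integer dosages 0/1/2.
#' @export
simulate_ld_genotypes <- function(N, R, mafs, seed = NULL, chrom = "1",
                                  pos0 = 1000L) {
  M <- ncol(R)
  stopifnot(length(mafs) == M, all(mafs > 0), all(mafs < 1))
  L <- diag(1, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i != j) L[i, j] <- latent_rho(R[i, j], mafs[i], mafs[j])
  }
  # clamp to positive semi-definite, keep unit diagonal
  e <- eigen(L, symmetric = TRUE)
  if (any(e$values < 1e-8)) {
    L <- e$vectors %*% diag(pmax(e$values, 1e-8)) %*% t(e$vectors)
    s <- sqrt(diag(L)); L <- L / tcrossprod(s)
  }
  ch <- chol(L + diag(1e-10, M))
  thr <- qnorm(mafs)
  with_seed(seed, {
    a1 <- matrix(rnorm(N * M), N, M) %*% ch
    a2 <- matrix(rnorm(N * M), N, M) %*% ch
    X <- (sweep(a1, 2, thr, "<") + 0) + (sweep(a2, 2, thr, "<") + 0)
    snps <- data.frame(id = sprintf("ld%04d", seq_len(M)), chrom = chrom,
                       pos = pos0 * (seq_len(M) + 1L), ref = "A", alt = "G",
                       maf = NA_real_, stringsAsFactors = FALSE)
    genotype_block(X, snps)
  })
}

#' Simulate a quantitative phenotype with given heritability
#'
#' `y = X[, causal] %*% betas + e`, with the noise variance chosen so the
#' additive genetic values explain a fraction `h2` of the phenotypic
#' variance.  `h2 = 0` returns pure noise, independent of the genotypes.
#'
#' @param block a [genotype_block()].
#' @param betas named numeric vector (names = causal SNP ids) or numeric
#'   vector over all columns.
#' @param h2 target heritability in \[0, 1).
#' @param seed RNG seed.
#' @return a continuous [phenotype_vector()].
#' @export
simulate_quantitative <- function(block, betas = NULL, h2 = 0, seed = NULL) {
  N <- nrow(block$dosages)
  with_seed(seed, {
    if (is.null(betas) || h2 <= 0) return(phenotype_vector(rnorm(N)))
    if (!is.null(names(betas))) {
      j <- match(names(betas), block$snps$id)
      if (anyNA(j)) stop("unknown causal SNP id")
      g <- as.vector(block$dosages[, j, drop = FALSE] %*% betas)
    } else g <- as.vector(block$dosages %*% betas)
    vg <- stats::var(g)
    if (vg == 0) stop("causal SNPs are monomorphic; genetic variance is 0")
    ve <- vg * (1 - h2) / h2
    phenotype_vector(g + rnorm(N, sd = sqrt(ve)))
  })
}
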