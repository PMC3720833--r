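# Small in-code fixtures shared across test files.

# Independent-SNP dosage block: binomial(2, maf) draws.
make_block <- function(N, P, mafs = runif(P, 0.1, 0.4), seed = NULL,
                       chrom = "1") {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rbinom(N * P, 2L, rep(mafs, each = N)), N, P)
  # guard against monomorphic draws in tiny fixtures
  for (j in which(apply(X, 2, var) == 0)) X[1:2, j] <- c(0L, 1L)
  snps <- data.frame(id = sprintf("s%04d", seq_len(P)), chrom = chrom,
                     pos = 1000L * (seq_len(P) + 1L), ref = "A", alt = "G",
                     maf = NA_real_, stringsAsFactors = FALSE)
  genotype_block(X, snps)
}

# Quantitative phenotype independent of genotypes.
null_pheno <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phenotype_vector(rnorm(N))
}

# Exactly orthogonal (after centering) dosage columns from a Hadamard-type
# design, mapped to dosages {0, 2}.
orthogonal_block <- function() {
  H <- matrix(c(1, 1, 1, 1,  1, -1, 1, -1,  1, 1, -1, -1,  1, -1, -1, 1),
              4, 4)
  H8 <- rbind(cbind(H, H), cbind(H, -H))  # 8 x 8 Hadamard
  X <- (H8[, 2:5] + 1)                    # columns orthogonal, values 0/2
  snps <- data.frame(id = paste0("h", 1:4), chrom = "1",
                     pos = 1000L * (2:5), ref = "A", alt = "G",
                     maf = NA_real_, stringsAsFactors = FALSE)
  genotype_block(X, snps)
}

# OLS RSS on a raw-column subset, the refit oracle for Gram-Schmidt.
ols_rss <- function(X, y, cols) {
  fit <- lm(y ~ X[, cols, drop = FALSE])
  sum(resid(fit)^2)
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), tol)
}
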