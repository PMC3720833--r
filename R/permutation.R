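#' Permutation plan
#'
#' The contract every permutation-based test shares: the same `(seed,
#' n_perm)` always produces the identical sequence of Fisher-Yates shuffles,
#' independent of how many threads are requested and of which or how many
#' methods consume the stream.  Worker decomposition assigns disjoint
#' contiguous blocks of the one stream, so `n_threads` never changes
#' results.
#'
#' @param seed integer RNG seed.
#' @param n_perm number of permutations.
#' @param n_threads worker count (bookkeeping only; results are invariant).
#' @export
permutation_plan <- function(seed = 1, n_perm = 1000, n_threads = 1) {
  stopifnot(n_perm >= 1, n_threads >= 1)
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 n_threads = as.integer(n_threads)),
            class = "permutation_plan")
}

#' Fisher-Yates shuffle
#'
#' Unbiased in-place random permutation of `1..n`: for `i = n..2`, swap
#' position `i` with a uniformly drawn position in `1..i`.  Draws come from
#' the current RNG stream.
#'
#' @param n permutation length.
#' @return an integer permutation of `1..n`.
#' @export
fisher_yates <- function(n) {
  p <- seq_len(n)
  u <- runif(n - 1L)
  for (i in n:2) {
    j <- 1L + min(i - 1L, as.integer(u[n - i + 1L] * i))
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  }
  p
}

#' Generate the shared permutation stream
#'
#' @param plan a [permutation_plan()].
#' @param N number of samples to permute.
#' @return integer `N x n_perm` matrix; column `b` is the `b`-th
#'   Fisher-Yates shuffle of `1..N` from the seeded stream.
#' @export
shuffle_stream <- function(plan, N) {
  with_seed(plan$seed, {
    out <- matrix(0L, N, plan$n_perm)
    for (b in seq_len(plan$n_perm)) out[, b] <- fisher_yates(N)
    out
  })
}

#' Empirical p-value with the add-one correction
#'
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`; never exactly 0, with
#' granularity floor `1/(n_perm + 1)`.
#'
#' @param observed observed statistic (scalar).
#' @param null_values vector of null-draw statistics.
#' @export
empirical_p <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' LDL factorization of a correlation matrix
#'
#' `R = L D L'` with `L` unit lower triangular and `D` diagonal.  When a
#' pivot falls below `ridge_floor` the matrix is regularized as
#' `R + ridge * I` and refactored, with `ridge` escalating tenfold from
#' `ridge0` up to `1e-2` before giving up (a duplicated-SNP correlation
#' matrix succeeds after regularization; a note is emitted).
#'
#' @param R symmetric matrix with unit diagonal.
#' @param ridge0 starting ridge for degenerate pivots.
#' @param ridge_floor pivot threshold triggering regularization.
#' @return list `L` (unit lower triangular), `d` (diagonal of `D`),
#'   `ridge` (0 when no regularization was needed).
#' @export
ldl_factor <- function(R, ridge0 = 1e-8, ridge_floor = 1e-10) {
  M <- ncol(R)
  attempt <- function(A) {
    L <- diag(1, M)
    d <- numeric(M)
    for (j in seq_len(M)) {
      v <- if (j > 1) L[j, 1:(j - 1)] else numeric(0)
      d[j] <- A[j, j] - sum(v^2 * d[seq_along(v)])
      if (d[j] < ridge_floor) return(NULL)
      if (j < M) {
        for (i in (j + 1):M) {
          L[i, j] <- (A[i, j] -
                        sum(L[i, seq_len(j - 1)] * v * d[seq_len(j - 1)])) / d[j]
        }
      }
    }
    list(L = L, d = d)
  }
  res <- attempt(R)
  ridge <- 0
  if (is.null(res)) {
    ridge <- ridge0
    while (ridge <= 1e-2) {
      res <- attempt(R + diag(ridge, M))
      if (!is.null(res)) break
      ridge <- ridge * 10
    }
    if (is.null(res)) stop("LDL factorization failed even with ridge 1e-2")
    message("LDL: correlation matrix regularized with ridge ", ridge)
  }
  list(L = res$L, d = res$d, ridge = ridge)
}

#' Simulate null z-scores with a given LD correlation
#'
#' Under the null the single-SNP z-scores in a gene are multivariate normal
#' with mean 0 and correlation equal to the SNP LD matrix `R`.  Draws are
#' colored from iid standard normals via the LDL factorization:
#' `z = L sqrt(D) g`.
#'
#' @param R SNP correlation matrix.
#' @param n_sims number of simulated z-vectors (0 gives an empty matrix).
#' @param seed RNG seed.
#' @return class `"null_z"`: list with `z` (`n_sims x M`), `R`, `L`, `d`.
#' @export
simulate_null_z <- function(R, n_sims, seed = NULL) {
  M <- ncol(R)
  f <- ldl_factor(R)
  A <- f$L %*% diag(sqrt(f$d), M)
  z <- if (n_sims > 0) {
    with_seed(seed, matrix(rnorm(n_sims * M), n_sims, M) %*% t(A))
  } else matrix(0, 0, M)
  structure(list(z = z, R = R, L = f$L, d = f$d), class = "null_z")
}
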