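# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft-threshold operator
#'
#' Elementwise shrinkage `sign(x) * max(|x| - lambda, 0)`, the proximal
#' operator of the l1 norm. Used by the penalized CCA solvers.
#'
#' @param x numeric vector or matrix.
#' @param lambda threshold, scalar >= 0.
#' @return object of the same shape as `x`.
#' @keywords internal
soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}

# Symmetrize a nearly-symmetric matrix (guards numerical drift).
symmetrize <- function(m) (m + t(m)) / 2

# Inverse symmetric square root via eigendecomposition.
# Eigenvalues below `tol * max(ev)` are treated as zero and trigger an error
# unless `pseudo = TRUE`, in which case they are dropped (pseudo-inverse root).
inv_sqrtm <- function(m, tol = 1e-12, pseudo = FALSE) {
  m <- symmetrize(m)
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!all(keep) && !pseudo) {
    stop(sprintf(
      "matrix is rank deficient (rank %d of %d); increase shrinkage",
      sum(keep), length(keep)
    ))
  }
  v <- e$vectors[, keep, drop = FALSE]
  v %*% diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(v)
}

# Pearson correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Derive a child seed from a master seed
#'
#' Counter-based mixing so every cell of a benchmark sweep gets its own
#' reproducible seed that can be regenerated in isolation. Result is kept
#' in `[0, 2^31 - 1]`.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter (cell index).
#' @return integer seed.
#' @export
derive_seed <- function(master, index) {
  # splitmix-style mixing in double precision, folded into 31 bits
  z <- (as.numeric(master) * 2654435761 + as.numeric(index) * 40503 + 12345)
  as.integer(z %% 2147483647)
}

# Deterministic sign convention: flip each column of filters/patterns so the
# pattern coefficient with the largest magnitude is positive.
fix_signs <- function(w, a) {
  for (k in seq_len(ncol(a))) {
    i <- which.max(abs(a[, k]))
    if (a[i, k] < 0) {
      a[, k] <- -a[, k]
      w[, k] <- -w[, k]
    }
  }
  list(w = w, a = a)
}
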