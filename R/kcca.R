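# Kernel CCA: nonlinear cross-modal coupling via sample-space kernel
# matrices. Solved by eigendecomposing the centered kernels into implicit
# feature coordinates and running ridge-constrained CCA there; channel
# filters are replaced by dual coefficients over training samples.

#' Kernel configuration for kCCA
#'
#' @param kind `"linear"`, `"polynomial"`, or `"gaussian"`.
#' @param bandwidth gaussian bandwidth in data units; `NULL` uses the median
#'   pairwise distance heuristic at fit time.
#' @param degree polynomial degree.
#' @param ridge positive regularization weight (kCCA is ill-posed without
#'   it for flexible kernels).
#' @param centered whether to center the kernel in feature space.
#' @return list of class `kernel_config`.
#' @export
kernel_config <- function(kind = c("linear", "polynomial", "gaussian"),
                          bandwidth = NULL, degree = 2, ridge = 0.1,
                          centered = TRUE) {
  kind <- match.arg(kind)
  if (kind %in% c("gaussian", "polynomial") && ridge <= 0)
    stop("kernel_config: ridge must be > 0 for gaussian/polynomial kernels")
  if (!is.null(bandwidth) && bandwidth <= 0)
    stop("kernel_config: bandwidth must be positive")
  structure(list(kind = kind, bandwidth = bandwidth, degree = degree,
                 ridge = ridge, centered = centered),
            class = "kernel_config")
}

# Gram matrix between sample sets (columns of a, b are samples).
kernel_gram <- function(a, b, cfg, bandwidth = NULL) {
  switch(cfg$kind,
    linear = crossprod(a, b),
    polynomial = (crossprod(a, b) + 1)^cfg$degree,
    gaussian = {
      d2 <- outer(colSums(a^2), colSums(b^2), "+") - 2 * crossprod(a, b)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * bandwidth^2))
    }
  )
}

median_bandwidth <- function(a) {
  n <- ncol(a)
  idx <- if (n > 300) sort(sample.int(n, 300)) else seq_len(n)
  d <- stats::dist(t(a[, idx, drop = FALSE]))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

center_gram <- function(k) {
  n <- nrow(k)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% k %*% j
}

#' Kernel canonical correlation analysis
#'
#' Maximizes the correlation of implicit feature-space projections under
#' ridge-regularized unit-variance constraints. Returned models carry dual
#' coefficients (one per training sample) instead of channel filters;
#' out-of-sample projection goes through [project_kcca()].
#'
#' @param x,y `channel_timeseries` with equal sample counts.
#' @param k number of components.
#' @param kernel_x,kernel_y `kernel_config`s.
#' @return a `decomposition_model` with `wx`, `wy` holding dual coefficients
#'   and training data stored in `extras` for projection.
#' @export
fit_kcca <- function(x, y, k = 1,
                     kernel_x = kernel_config("gaussian"),
                     kernel_y = kernel_config("gaussian")) {
  xd <- x$data - rowMeans(x$data)
  yd <- y$data - rowMeans(y$data)
  t_n <- ncol(xd)
  if (ncol(yd) != t_n) stop("fit_kcca: sample counts differ")
  bx <- if (kernel_x$kind == "gaussian")
    kernel_x$bandwidth %||% median_bandwidth(xd) else NULL
  by <- if (kernel_y$kind == "gaussian")
    kernel_y$bandwidth %||% median_bandwidth(yd) else NULL
  kx <- kernel_gram(xd, xd, kernel_x, bx)
  ky <- kernel_gram(yd, yd, kernel_y, by)
  if (kernel_x$centered) kx <- center_gram(kx)
  if (kernel_y$centered) ky <- center_gram(ky)

  # implicit feature coordinates: K = Z Z' with Z = U L^{1/2}
  fx <- gram_features(kx)
  fy <- gram_features(ky)
  zx <- channel_timeseries(t(fx$z), x$rate, modality = x$modality)
  zy <- channel_timeseries(t(fy$z), y$rate, modality = y$modality)
  kk <- min(k, nrow(zx$data), nrow(zy$data))
  m <- fit_regularized_cca(zx, zy, kk,
                           penalty_config(l2_x = kernel_x$ridge,
                                          l2_y = kernel_y$ridge,
                                          constraint_mode = "covariance"))
  # dual coefficients: alpha = U L^{-1/2} w so that K alpha = Z w
  alpha <- fx$u %*% (m$wx / sqrt(fx$l))
  beta <- fy$u %*% (m$wy / sqrt(fy$l))
  new_decomposition_model("kcca", alpha, beta, m$correlations,
                          constraint_mode = "covariance",
                          input_space = c(x = x$modality, y = y$modality),
                          extras = list(
                            kernel_x = kernel_x, kernel_y = kernel_y,
                            bandwidth_x = bx, bandwidth_y = by,
                            train_x = xd, train_y = yd,
                            train_means = list(x = rowMeans(x$data),
                                               y = rowMeans(y$data)),
                            dual = TRUE))
}

gram_features <- function(k, tol = 1e-10) {
  e <- eigen(symmetrize(k), symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  list(u = e$vectors[, keep, drop = FALSE],
       l = e$values[keep],
       z = e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                    sum(keep)))
}

#' Project new samples through a fitted kCCA model
#'
#' @param model a `decomposition_model` from [fit_kcca()].
#' @param x a `channel_timeseries` of new samples.
#' @param side `"x"` or `"y"`.
#' @return a `channel_timeseries` of component scores.
#' @export
project_kcca <- function(model, x, side = c("x", "y")) {
  side <- match.arg(side)
  ex <- model$extras
  cfg <- if (side == "x") ex$kernel_x else ex$kernel_y
  bw <- if (side == "x") ex$bandwidth_x else ex$bandwidth_y
  train <- if (side == "x") ex$train_x else ex$train_y
  mu <- ex$train_means[[side]]
  dual <- if (side == "x") model$wx else model$wy
  newd <- x$data - mu
  kn <- kernel_gram(newd, train, cfg, bw)   # [n_new x n_train]
  if (cfg$centered) {
    n <- ncol(train)
    ktr <- kernel_gram(train, train, cfg, bw)
    kn <- kn - matrix(rowMeans(kn), nrow(kn), n) -
      matrix(colMeans(ktr), nrow(kn), n, byrow = TRUE) + mean(ktr)
  }
  channel_timeseries(t(kn %*% dual), x$rate,
                     paste0("comp", seq_len(ncol(dual))), x$modality, x$t0)
}
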