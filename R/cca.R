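# The CCA family. Standard CCA is solved as a whitened cross-covariance SVD
# (equivalent to the generalized eigenvalue formulation); regularized
# variants use alternating penalized power iterations with soft-thresholding
# and GraphNet/ridge normalization matrices.

#' Penalty configuration for regularized CCA
#'
#' Lagrangian penalty weights for the x- and y-side filters: l1 (sparsity),
#' l2 (ridge), and graph (GraphNet `w' L w`) terms.
#'
#' @param l1_x,l1_y,l2_x,l2_y,graph_x,graph_y non-negative scalars.
#' @param constraint_mode `"covariance"` (unit variance, `w' C w = 1`) or
#'   `"identity"` (unit norm). Default `NULL` picks `"identity"` whenever an
#'   l1 or graph penalty is active (the usual substitution in penalized CCA
#'   implementations) and `"covariance"` otherwise.
#' @return list of class `penalty_config`.
#' @export
penalty_config <- function(l1_x = 0, l1_y = 0, l2_x = 0, l2_y = 0,
                           graph_x = 0, graph_y = 0, constraint_mode = NULL) {
  vals <- c(l1_x, l1_y, l2_x, l2_y, graph_x, graph_y)
  stopifnot(all(is.finite(vals)), all(vals >= 0))
  if (is.null(constraint_mode)) {
    constraint_mode <- if (l1_x > 0 || l1_y > 0 || graph_x > 0 || graph_y > 0)
      "identity" else "covariance"
  }
  structure(list(l1_x = l1_x, l1_y = l1_y, l2_x = l2_x, l2_y = l2_y,
                 graph_x = graph_x, graph_y = graph_y,
                 constraint_mode = constraint_mode),
            class = "penalty_config")
}

# Correlations of paired variates, clamped into [0, 1]; sign-fixed upstream.
variate_correlations <- function(sx, sy) {
  sapply(seq_len(nrow(sx)), function(k) {
    r <- safe_cor(sx[k, ], sy[k, ])
    if (is.na(r)) 0 else abs(r)
  })
}

#' Canonical correlation analysis
#'
#' Finds filter pairs maximizing the correlation of the reconstructed
#' sources `wx' x(t)` and `wy' y(t)` under unit-variance constraints,
#' solved as the SVD of the whitened cross-covariance
#' `Cx^{-1/2} Cxy Cy^{-1/2}`.
#'
#' @param x,y `channel_timeseries` with equal sample counts.
#' @param k number of components, `k <= min(Nx, Ny)`.
#' @param shrinkage trace-scaled diagonal covariance shrinkage (see
#'   [compute_covariances()]); the small default guards invertibility.
#' @return a `decomposition_model` with filters, canonical correlations
#'   (sorted descending), and spatial patterns.
#' @export
fit_cca <- function(x, y, k = 1, shrinkage = 1e-9) {
  nx <- nrow(x$data); ny <- nrow(y$data)
  if (k > min(nx, ny))
    stop(sprintf("fit_cca: k = %d exceeds min(Nx, Ny) = %d", k, min(nx, ny)))
  cov <- compute_covariances(x, y, shrinkage)
  px <- inv_sqrtm(cov$cx)
  py <- inv_sqrtm(cov$cy)
  s <- svd(px %*% cov$cxy %*% py, nu = k, nv = k)
  wx <- px %*% s$u
  wy <- py %*% s$v
  corr <- pmin(pmax(s$d[seq_len(k)], 0), 1)
  ax <- estimate_patterns(wx, cov$cx)
  ay <- estimate_patterns(wy, cov$cy)
  sx <- fix_signs(wx, ax); wx <- sx$w; ax <- sx$a
  sy <- fix_signs(wy, ay); wy <- sy$w; ay <- sy$a
  new_decomposition_model("cca", wx, wy, corr, ax, ay,
                          constraint_mode = "covariance",
                          input_space = c(x = x$modality, y = y$modality),
                          extras = list(shrinkage = shrinkage))
}

#' Regularized CCA (Ridge / sparse / ElasticNet / GraphNet ssCCA)
#'
#' With only l2 penalties the problem keeps unit-variance constraints and is
#' solved in closed form (ridge-shrunk whitened SVD). Once an l1 or graph
#' penalty is active, constraints switch to unit filter norm and the solver
#' alternates penalized power iterations: each side's update soft-thresholds
#' the cross-covariance image of the other side's filter and applies the
#' normalization matrix `(1 + l2) I + graph * L`. Iterates are accepted only
#' while the penalized objective does not decrease, so the recorded objective
#' history is monotone.
#'
#' @param x,y `channel_timeseries` with equal sample counts.
#' @param k number of components (deflation via rank-one subtraction of the
#'   cross-covariance for the penalized path).
#' @param penalties a `penalty_config`.
#' @param graphs optional list with `channel_graph`s `x` and/or `y`
#'   (required when the corresponding graph penalty is positive).
#' @param shrinkage covariance shrinkage, as in [fit_cca()].
#' @param max_iter,tol alternating-solver controls.
#' @return a `decomposition_model`; `converged = FALSE` (with a warning) if
#'   the alternation hit `max_iter`.
#' @export
fit_regularized_cca <- function(x, y, k = 1, penalties = penalty_config(),
                                graphs = NULL, shrinkage = 1e-9,
                                max_iter = 500, tol = 1e-6) {
  p <- penalties
  nx <- nrow(x$data); ny <- nrow(y$data)
  if (k > min(nx, ny)) stop("fit_regularized_cca: k too large")
  if (p$graph_x > 0 && (is.null(graphs$x) ||
      nrow(graphs$x$laplacian) != nx))
    stop("fit_regularized_cca: graph_x penalty needs a matching x graph")
  if (p$graph_y > 0 && (is.null(graphs$y) ||
      nrow(graphs$y$laplacian) != ny))
    stop("fit_regularized_cca: graph_y penalty needs a matching y graph")

  if (p$constraint_mode == "covariance" && p$l1_x == 0 && p$l1_y == 0 &&
      p$graph_x == 0 && p$graph_y == 0) {
    return(ridge_cca_closed_form(x, y, k, p, shrinkage))
  }

  cov <- compute_covariances(x, y, shrinkage)
  lx <- if (p$graph_x > 0) graphs$x$laplacian else NULL
  ly <- if (p$graph_y > 0) graphs$y$laplacian else NULL
  mx <- (1 + p$l2_x) * diag(nx) + if (!is.null(lx)) p$graph_x * lx else 0
  my <- (1 + p$l2_y) * diag(ny) + if (!is.null(ly)) p$graph_y * ly else 0

  # penalty weights are defined on standardized (unit-variance) features, as
  # is usual for penalized CCA; filters are mapped back to raw units below.
  # CCA itself is invariant to per-channel scaling, so zero-penalty
  # reductions are unaffected.
  standardize <- (p$l1_x > 0 || p$l1_y > 0 || p$graph_x > 0 ||
                    p$graph_y > 0 || p$l2_x > 0 || p$l2_y > 0)
  sdx <- sqrt(pmax(diag(cov$cx), 1e-24))
  sdy <- sqrt(pmax(diag(cov$cy), 1e-24))
  cxy <- if (standardize) cov$cxy / (sdx %o% sdy) else cov$cxy
  wx_all <- matrix(0, nx, k); wy_all <- matrix(0, ny, k)
  histories <- list(); iters <- 0L; converged <- TRUE

  pen_obj <- function(wx, wy) {
    as.numeric(t(wx) %*% cxy %*% wy) -
      p$l1_x * sum(abs(wx)) - p$l1_y * sum(abs(wy)) -
      0.5 * (p$l2_x * sum(wx^2) + p$l2_y * sum(wy^2)) -
      0.5 * (if (!is.null(lx)) p$graph_x * as.numeric(t(wx) %*% lx %*% wx) else 0) -
      0.5 * (if (!is.null(ly)) p$graph_y * as.numeric(t(wy) %*% ly %*% wy) else 0)
  }

  for (comp in seq_len(k)) {
    sv <- svd(cxy, nu = 1, nv = 1)
    wx <- sv$u[, 1]; wy <- sv$v[, 1]
    obj <- pen_obj(wx, wy)
    hist_k <- obj
    conv_k <- FALSE
    for (it in seq_len(max_iter)) {
      wx_new <- solve(mx, soft_threshold(cxy %*% wy, p$l1_x))
      if (sum(abs(wx_new)) == 0) break  # penalty annihilated the filter
      wx_new <- wx_new / sqrt(sum(wx_new^2))
      wy_new <- solve(my, soft_threshold(t(cxy) %*% wx_new, p$l1_y))
      if (sum(abs(wy_new)) == 0) break
      wy_new <- wy_new / sqrt(sum(wy_new^2))
      obj_new <- pen_obj(wx_new, wy_new)
      if (obj_new < obj - 1e-12) break  # ascent stalled; keep best iterate
      wx <- as.numeric(wx_new); wy <- as.numeric(wy_new)
      hist_k <- c(hist_k, obj_new)
      if (abs(obj_new - obj) <= tol * (abs(obj) + 1e-12)) {
        obj <- obj_new; conv_k <- TRUE; break
      }
      obj <- obj_new
    }
    if (!conv_k && it >= max_iter) {
      converged <- FALSE
      warning("fit_regularized_cca: alternation did not converge within max_iter")
    }
    iters <- iters + length(hist_k) - 1L
    histories[[comp]] <- hist_k
    wx_all[, comp] <- wx; wy_all[, comp] <- wy
    # rank-one projection deflation of the cross-covariance
    cxy <- cxy - as.numeric(t(wx) %*% cxy %*% wy) * (wx %*% t(wy))
  }

  if (standardize) {
    wx_all <- wx_all / sdx
    wy_all <- wy_all / sdy
  }
  sx <- apply_filters(wx_all, cts_center(x))
  sy <- apply_filters(wy_all, cts_center(y))
  corr <- variate_correlations(sx$data, sy$data)
  ord <- order(corr, decreasing = TRUE)
  corr <- corr[ord]
  wx_all <- wx_all[, ord, drop = FALSE]; wy_all <- wy_all[, ord, drop = FALSE]
  ax <- estimate_patterns(wx_all, cov$cx)
  ay <- estimate_patterns(wy_all, cov$cy)
  fx <- fix_signs(wx_all, ax); wx_all <- fx$w; ax <- fx$a
  fy <- fix_signs(wy_all, ay); wy_all <- fy$w; ay <- fy$a
  new_decomposition_model("regularized_cca", wx_all, wy_all, corr, ax, ay,
                          constraint_mode = "identity",
                          converged = converged, iterations = iters,
                          objective_history = histories[[1]],
                          input_space = c(x = x$modality, y = y$modality),
                          extras = list(penalties = p,
                                        standardized = standardize))
}

# Closed-form path: l2-only penalties with covariance constraints reduce to
# CCA on ridge-shrunk covariances.
ridge_cca_closed_form <- function(x, y, k, p, shrinkage) {
  cov <- compute_covariances(x, y, shrinkage)
  standardize <- p$l2_x > 0 || p$l2_y > 0
  sdx <- sqrt(pmax(diag(cov$cx), 1e-24))
  sdy <- sqrt(pmax(diag(cov$cy), 1e-24))
  cx_s <- if (standardize) cov$cx / (sdx %o% sdx) else cov$cx
  cy_s <- if (standardize) cov$cy / (sdy %o% sdy) else cov$cy
  cxy_s <- if (standardize) cov$cxy / (sdx %o% sdy) else cov$cxy
  cx_r <- cx_s + p$l2_x * diag(nrow(cx_s))
  cy_r <- cy_s + p$l2_y * diag(nrow(cy_s))
  px <- inv_sqrtm(cx_r)
  py <- inv_sqrtm(cy_r)
  s <- svd(px %*% cxy_s %*% py, nu = k, nv = k)
  wx <- px %*% s$u; wy <- py %*% s$v
  if (standardize) {
    wx <- wx / sdx
    wy <- wy / sdy
  }
  # reported values are the ridge-constrained canonical correlations (the
  # objective under w'(C + l2 I)w = 1), which shrink to 0 as l2 grows
  corr <- pmin(pmax(s$d[seq_len(k)], 0), 1)
  ax <- estimate_patterns(wx, cov$cx)
  ay <- estimate_patterns(wy, cov$cy)
  fx <- fix_signs(wx, ax); wx <- fx$w; ax <- fx$a
  fy <- fix_signs(wy, ay); wy <- fy$w; ay <- fy$a
  new_decomposition_model("regularized_cca", wx, wy, corr, ax, ay,
                          constraint_mode = "covariance",
                          objective_history = s$d[1],
                          input_space = c(x = x$modality, y = y$modality),
                          extras = list(penalties = p))
}

#' Temporally embedded CCA (tCCA)
#'
#' Embeds the x-side series (EEG bandpower in the benchmark) with
#' time-shifted copies so that delayed cross-modal coupling — e.g. the
#' hemodynamic lag between an EEG bandpower change and the fNIRS response —
#' becomes accessible to an instantaneous CCA, then fits
#' [fit_regularized_cca()] on the embedded pair.
#'
#' @param x series to embed; `y` the delayed modality's counterpart.
#' @param y `channel_timeseries`.
#' @param k components.
#' @param lags an `embedding_config` (benchmark default: 1-4 s in 1-s steps).
#' @param penalties a `penalty_config`.
#' @param graphs optional graphs; an x-side graph is expanded blockwise over
#'   the lag copies.
#' @param ... passed to [fit_regularized_cca()].
#' @return a `decomposition_model`; `wx` is over embedded features, with the
#'   reshaped `[Nx x P]` filter and per-lag pattern blocks in `extras`
#'   (`wx_lags`, `ax_lags`), and `ax` reduced to channel space via the
#'   lag block with the largest pattern norm.
#' @export
fit_tcca <- function(x, y, k = 1, lags = embedding_config(1:4),
                     penalties = penalty_config(), graphs = NULL, ...) {
  xe <- temporal_embed(cts_center(x), lags)
  if (!is.null(graphs$x)) {
    p <- length(lags$lags)
    lx <- graphs$x$laplacian
    big <- kronecker(diag(p), lx)
    graphs$x <- structure(list(adjacency = kronecker(diag(p), graphs$x$adjacency),
                               degree = kronecker(diag(p), graphs$x$degree),
                               laplacian = big, rule = graphs$x$rule,
                               param = graphs$x$param),
                          class = "channel_graph")
  }
  m <- fit_regularized_cca(xe, y, k, penalties, graphs, ...)
  nx <- nrow(x$data); p <- length(lags$lags)
  wx_lags <- array(m$wx, dim = c(nx, p, m$k))
  ax_lags <- array(m$ax, dim = c(nx, p, m$k))
  # channel-space pattern: per component, the lag block with the largest norm
  ax_chan <- sapply(seq_len(m$k), function(kk) {
    norms <- apply(ax_lags[, , kk, drop = FALSE], 2, function(v) sqrt(sum(v^2)))
    ax_lags[, which.max(norms), kk]
  })
  m$method <- "tcca"
  m$embedding <- lags
  m$extras$wx_lags <- wx_lags
  m$extras$ax_lags <- ax_lags
  m$extras$ax_embedded <- m$ax
  m$ax <- as.matrix(ax_chan)
  m
}
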