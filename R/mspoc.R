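# Multimodal Source Power Co-modulation (mSPoC): finds an EEG spatial
# filter wx, an fNIRS spatial filter wy and an FIR lag filter wtau such
# that the temporally embedded bandpower of the latent EEG source,
# h(Phi)(e) = sum_i wtau_i * Phi(e - tau_i), Phi(e) = wx' Cx(e) wx,
# maximally covaries with the latent fNIRS source wy' y(e), under
# wx' Cx wx = wy' Cy wy = wtau' wtau = 1.

#' Per-window covariance stack
#'
#' Splits a band-pass-filtered series into non-overlapping windows and
#' returns the within-window covariance matrices; for any filter `w`,
#' `w' Cx(e) w` equals the per-window variance (bandpower) of the filtered
#' source.
#'
#' @param x a `channel_timeseries` (band-pass filtered, approximately
#'   mean-free).
#' @param window_s window length in seconds (at least 2 samples).
#' @return list of class `epoched_covariances`: `cov` is an
#'   `[Nx x Nx x E]` array, plus `window_s`, `epoch_rate`, `n_epochs`.
#' @export
epoch_covariances <- function(x, window_s) {
  w <- round(window_s * x$rate)
  if (w < 2) stop("epoch_covariances: window must span at least 2 samples")
  n <- ncol(x$data); e_n <- floor(n / w)
  if (e_n < 1) stop("epoch_covariances: window longer than series")
  nx <- nrow(x$data)
  cov <- array(0, dim = c(nx, nx, e_n))
  for (e in seq_len(e_n)) {
    seg <- x$data[, ((e - 1) * w + 1):(e * w), drop = FALSE]
    seg <- seg - rowMeans(seg)
    cov[, , e] <- tcrossprod(seg) / w
  }
  structure(list(cov = cov, window_s = window_s, epoch_rate = 1 / window_s,
                 n_epochs = e_n),
            class = "epoched_covariances")
}

#' mSPoC configuration
#'
#' @param n_lags number of FIR lags `Ntau` (in epochs, lags `0..Ntau-1`;
#'   bandpower precedes the hemodynamic response).
#' @param l2_x ridge weight added to the EEG-filter update matrix
#'   (benchmark default 0.8).
#' @param pca_explained_variance fraction of EEG variance kept by the PCA
#'   preprojection (1 disables it; benchmark default 0.99).
#' @param max_iter,tol outer-loop controls (relative objective change).
#' @param n_restarts random restarts on top of the SVD-based init.
#' @param seed integer seed for the restarts.
#' @return list of class `mspoc_config`.
#' @export
mspoc_config <- function(n_lags = 8, l2_x = 0.8, pca_explained_variance = 0.99,
                         max_iter = 200, tol = 1e-5, n_restarts = 10,
                         seed = 1) {
  stopifnot(n_lags >= 1, pca_explained_variance > 0,
            pca_explained_variance <= 1)
  structure(list(n_lags = as.integer(n_lags), l2_x = l2_x,
                 pca_explained_variance = pca_explained_variance,
                 max_iter = max_iter, tol = tol,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "mspoc_config")
}

# Lagged copies of a vector: column i holds v(e - (i-1)), zero-padded.
lag_matrix <- function(v, n_lags) {
  e_n <- length(v)
  out <- matrix(0, e_n, n_lags)
  for (i in seq_len(n_lags)) {
    k <- i - 1
    if (k == 0) out[, i] <- v
    else out[(k + 1):e_n, i] <- v[1:(e_n - k)]
  }
  out
}

#' Fit mSPoC
#'
#' Alternating optimization where each step is the exact maximizer given the
#' others: `wtau` from the covariance of the lagged bandpower with the fNIRS
#' source, `wx` from a generalized eigenproblem on the lag-combined
#' covariance stack, `wy` in closed form. Best objective over restarts is
#' kept; within a restart, the objective is non-decreasing per outer
#' iteration or the restart is cut at its best iterate.
#'
#' @param x EEG `channel_timeseries`, band-pass filtered (e.g. 8-12 Hz).
#' @param y fNIRS `channel_timeseries` sampled at one point per EEG window
#'   (`E` samples).
#' @param cfg an `mspoc_config`.
#' @param window_s EEG window length in seconds; must tile `x` into exactly
#'   `E = n_samples(y)` windows.
#' @return a `decomposition_model` with `wx`, `wy`, FIR filter
#'   `extras$wtau`, patterns in the original channel space, and the
#'   objective (covariance) history of the winning restart. The reported
#'   correlation is `|cor(h(Phi), s_hat_y)|`.
#' @export
fit_mspoc <- function(x, y, cfg = mspoc_config(), window_s = NULL) {
  e_n <- ncol(y$data)
  if (is.null(window_s)) window_s <- ncol(x$data) / x$rate / e_n
  ec <- epoch_covariances(x, window_s)
  if (ec$n_epochs != e_n)
    stop(sprintf("fit_mspoc: %d EEG windows but %d fNIRS samples",
                 ec$n_epochs, e_n))
  if (e_n <= cfg$n_lags)
    stop("fit_mspoc: need more epochs than FIR lags")

  # PCA preprojection of the EEG side
  cx_full <- symmetrize(apply(ec$cov, c(1, 2), mean))
  proj <- diag(nrow(cx_full)); expl <- 1
  if (cfg$pca_explained_variance < 1) {
    e <- eigen(cx_full, symmetric = TRUE)
    cum <- cumsum(e$values) / sum(e$values)
    keep <- seq_len(which(cum >= cfg$pca_explained_variance)[1])
    proj <- e$vectors[, keep, drop = FALSE]
    expl <- cum[max(keep)]
  }
  nxr <- ncol(proj)
  cov_r <- array(0, dim = c(nxr, nxr, e_n))
  for (e in seq_len(e_n)) cov_r[, , e] <- t(proj) %*% ec$cov[, , e] %*% proj
  cx <- symmetrize(apply(cov_r, c(1, 2), mean))
  cov_flat <- matrix(cov_r, nxr * nxr, e_n)  # column e = vec(Cx(e))

  yd <- y$data - rowMeans(y$data)
  cy <- symmetrize(tcrossprod(yd) / e_n)
  cy <- cy + 1e-9 * (sum(diag(cy)) / nrow(cy)) * diag(nrow(cy))
  cy_inv <- solve(cy)
  mx_con <- cx + cfg$l2_x * diag(nxr)  # wx-step constraint matrix (ridge)
  px <- inv_sqrtm(mx_con)

  run_restart <- function(wx0) {
    wx <- normalize_w(wx0, cx, "covariance")
    wtau <- c(1, rep(0, cfg$n_lags - 1))
    wy <- NULL
    best <- list(obj = -Inf)
    obj_prev <- -Inf
    conv <- FALSE
    hist <- numeric(0)
    for (it in seq_len(cfg$max_iter)) {
      phi <- colSums((as.numeric(wx %*% t(wx))) * cov_flat)  # wx' Cx(e) wx
      phi_c <- phi - mean(phi)
      lp <- lag_matrix(phi_c, cfg$n_lags)
      # wy step: closed form given h(Phi)
      h <- as.numeric(lp %*% wtau)
      h_c <- h - mean(h)
      wy <- cy_inv %*% (yd %*% h_c / e_n)
      wy <- normalize_w(as.numeric(wy), cy, "covariance")
      sy <- as.numeric(t(wy) %*% yd)
      sy_c <- sy - mean(sy)
      # wtau step: cov(lagged Phi, sy), unit norm
      ct <- as.numeric(t(lag_matrix(phi_c, cfg$n_lags)) %*% sy_c / e_n)
      if (sqrt(sum(ct^2)) > 0) wtau <- ct / sqrt(sum(ct^2))
      # wx step: maximize wx' M wx with M = sum_i wtau_i sum_e sy(e) Cx(e - tau_i)
      m <- matrix(0, nxr, nxr)
      for (i in seq_len(cfg$n_lags)) {
        k <- i - 1
        wts <- rep(0, e_n)
        if (k == 0) wts <- sy_c
        else wts[1:(e_n - k)] <- sy_c[(k + 1):e_n]  # weight on Cx(e') from sy(e' + k)
        m <- m + wtau[i] * matrix(cov_flat %*% wts, nxr, nxr)
      }
      m <- symmetrize(m) / e_n
      ev <- eigen(symmetrize(px %*% m %*% px), symmetric = TRUE)
      # covariance can be maximized at either spectrum end; take the larger |.|
      cand <- if (abs(ev$values[1]) >= abs(ev$values[nxr]))
        ev$vectors[, 1] else ev$vectors[, nxr]
      wx <- normalize_w(as.numeric(px %*% cand), cx, "covariance")
      # objective after the sweep
      phi <- colSums((as.numeric(wx %*% t(wx))) * cov_flat)
      phi_c <- phi - mean(phi)
      h <- as.numeric(lag_matrix(phi_c, cfg$n_lags) %*% wtau)
      obj <- abs(stats::cov(h, sy))
      if (obj > best$obj)
        best <- list(obj = obj, wx = wx, wy = wy, wtau = wtau,
                     hist = c(hist, obj))
      if (obj < obj_prev - 1e-9) break  # objective regressed: stop restart
      hist <- c(hist, obj)
      if (is.finite(obj_prev) &&
          abs(obj - obj_prev) <= cfg$tol * (abs(obj_prev) + 1e-12)) {
        conv <- TRUE
        break
      }
      obj_prev <- obj
    }
    best$converged <- conv
    best$iterations <- length(best$hist)
    best
  }

  # restarts: deterministic spectral init + random draws
  set.seed(cfg$seed)
  inits <- list(as.numeric(eigen(cx, symmetric = TRUE)$vectors[, 1]))
  for (r in seq_len(cfg$n_restarts)) inits[[r + 1]] <- stats::rnorm(nxr)
  results <- lapply(inits, run_restart)
  best <- results[[which.max(vapply(results, function(r) r$obj, 1))]]
  if (!best$converged)
    warning("fit_mspoc: best restart did not meet the convergence tolerance")

  wx_full <- as.numeric(proj %*% best$wx)
  # renormalize in the full space: wx' Cx_full wx = 1 (PCA projection keeps it)
  wx_full <- normalize_w(wx_full, cx_full, "covariance")
  ax <- estimate_patterns(matrix(wx_full, ncol = 1), cx_full)
  ay <- estimate_patterns(matrix(best$wy, ncol = 1), cy)
  # reported correlation: |cor(h(Phi), s_hat_y)| on the training data
  phi <- colSums((as.numeric(best$wx %*% t(best$wx))) * cov_flat)
  phi_c <- phi - mean(phi)
  h <- as.numeric(lag_matrix(phi_c, cfg$n_lags) %*% best$wtau)
  sy <- as.numeric(t(best$wy) %*% yd)
  corr <- abs(safe_cor(h, sy))
  new_decomposition_model("mspoc", matrix(wx_full, ncol = 1),
                          matrix(best$wy, ncol = 1), corr, ax, ay,
                          constraint_mode = "covariance",
                          converged = best$converged,
                          iterations = best$iterations,
                          objective_history = best$hist,
                          input_space = c(x = x$modality, y = y$modality),
                          extras = list(wtau = best$wtau, config = cfg,
                                        window_s = window_s,
                                        pca_projection = proj,
                                        pca_explained = expl,
                                        wx_reduced = best$wx,
                                        objective = best$obj))
}
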