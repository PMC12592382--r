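# Linear forward/backward source model machinery shared by every
# decomposition method: covariances, temporal embedding, filter application,
# spatial-pattern estimation (A = C W (W' C W)^-1), whitening, bandpower.

#' Covariance set for a modality pair
#'
#' Computes within-modality covariances `Cx`, `Cy` and the cross-modality
#' covariance `Cxy` from mean-centered data, with optional trace-scaled
#' diagonal shrinkage. The `1/T` estimator is used throughout.
#'
#' @param x,y `channel_timeseries` with equal sample counts (resample
#'   upstream if needed); centered internally.
#' @param shrinkage non-negative scalar; `Cx` becomes
#'   `XX'/T + shrinkage * (tr(XX'/T)/Nx) * I` (same for `Cy`).
#' @return list of class `covariance_set` with elements `cx`, `cy`, `cxy`,
#'   `shrinkage`.
#' @export
compute_covariances <- function(x, y, shrinkage = 0) {
  stopifnot(inherits(x, "channel_timeseries"), inherits(y, "channel_timeseries"))
  tx <- ncol(x$data); ty <- ncol(y$data)
  if (tx != ty)
    stop(sprintf("compute_covariances: sample counts differ (x: %d, y: %d)", tx, ty))
  if (tx < 2) stop("compute_covariances: need at least 2 samples")
  xd <- x$data - rowMeans(x$data)
  yd <- y$data - rowMeans(y$data)
  cx <- symmetrize(tcrossprod(xd) / tx)
  cy <- symmetrize(tcrossprod(yd) / ty)
  if (shrinkage > 0) {
    cx <- cx + shrinkage * (sum(diag(cx)) / nrow(cx)) * diag(nrow(cx))
    cy <- cy + shrinkage * (sum(diag(cy)) / nrow(cy)) * diag(nrow(cy))
  }
  cxy <- tcrossprod(xd, yd) / tx
  structure(list(cx = cx, cy = cy, cxy = cxy, shrinkage = shrinkage),
            class = "covariance_set")
}

#' Temporal embedding configuration
#'
#' @param lags strictly increasing lags in seconds (each must land on a
#'   sample of the series it embeds).
#' @param padding `"zero"` or `"edge"` fill for samples shifted past the
#'   start of the recording.
#' @param direction which modality is the delayed one (metadata only).
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(lags, padding = c("zero", "edge"),
                             direction = "y") {
  padding <- match.arg(padding)
  stopifnot(length(lags) >= 1, all(diff(lags) > 0))
  structure(list(lags = as.numeric(lags), padding = padding,
                 direction = direction),
            class = "embedding_config")
}

#' Temporally embed a channel time series
#'
#' Concatenates time-shifted copies of `x` along the channel dimension:
#' the block for lag `tau` holds `x(t - tau)`, so embedded features at time
#' `t` expose past samples to an instantaneous method. Sample count is
#' preserved via the padding policy; a lag of 0 reproduces the input exactly.
#'
#' @param x a `channel_timeseries`.
#' @param cfg an `embedding_config`.
#' @return a `channel_timeseries` with `length(lags) * n_channels` channels;
#'   labels are `"<channel>@<lag>s"`.
#' @export
temporal_embed <- function(x, cfg) {
  stopifnot(inherits(x, "channel_timeseries"), inherits(cfg, "embedding_config"))
  n <- ncol(x$data)
  blocks <- vector("list", length(cfg$lags))
  labels <- character(0)
  for (i in seq_along(cfg$lags)) {
    lag_samp_real <- cfg$lags[i] * x$rate
    k <- round(lag_samp_real)
    if (abs(lag_samp_real - k) > 1e-6)
      stop(sprintf("temporal_embed: lag %g s is not representable at %g Hz",
                   cfg$lags[i], x$rate))
    if (k >= n)
      stop(sprintf("temporal_embed: lag %g s (%d samples) >= series length %d",
                   cfg$lags[i], k, n))
    if (k == 0) {
      blocks[[i]] <- x$data
    } else {
      pad <- switch(cfg$padding,
        zero = matrix(0, nrow(x$data), k),
        edge = x$data[, rep(1, k), drop = FALSE]
      )
      blocks[[i]] <- cbind(pad, x$data[, seq_len(n - k), drop = FALSE])
    }
    labels <- c(labels, paste0(x$channel_ids, "@", cfg$lags[i], "s"))
  }
  out <- do.call(rbind, blocks)
  channel_timeseries(out, x$rate, labels, x$modality, x$t0)
}

#' Set of spatial filters (backward model)
#'
#' @param wx,wy numeric matrices `[Nx x K]`, `[Ny x K]`.
#' @param constraint_mode `"covariance"` (unit source variance) or
#'   `"identity"` (unit filter norm).
#' @return list of class `filter_set`.
#' @export
filter_set <- function(wx, wy, constraint_mode = c("covariance", "identity")) {
  constraint_mode <- match.arg(constraint_mode)
  wx <- as.matrix(wx); wy <- as.matrix(wy)
  stopifnot(ncol(wx) == ncol(wy), ncol(wx) >= 1)
  if (any(colSums(abs(wx)) == 0) || any(colSums(abs(wy)) == 0))
    stop("filter_set: all-zero filter column")
  structure(list(wx = wx, wy = wy, k = ncol(wx),
                 constraint_mode = constraint_mode),
            class = "filter_set")
}

#' Apply spatial filters to data (backward model)
#'
#' Reconstructed sources `s_hat(t) = W' x(t)`.
#'
#' @param w numeric filter matrix `[N x K]` (or a `filter_set`, with `side`
#'   selecting `wx`/`wy`).
#' @param x a `channel_timeseries` with `N` channels.
#' @param side `"x"` or `"y"`, used when `w` is a `filter_set`.
#' @return a `channel_timeseries` with `K` component channels.
#' @export
apply_filters <- function(w, x, side = c("x", "y")) {
  side <- match.arg(side)
  if (inherits(w, "filter_set")) w <- if (side == "x") w$wx else w$wy
  w <- as.matrix(w)
  if (nrow(w) != nrow(x$data))
    stop(sprintf("apply_filters: filter expects %d channels, data has %d",
                 nrow(w), nrow(x$data)))
  channel_timeseries(t(w) %*% x$data, x$rate,
                     paste0("comp", seq_len(ncol(w))), x$modality, x$t0)
}

#' Estimate spatial patterns from filters (forward model)
#'
#' Converts backward-model filters into forward-model activation patterns via
#' `A = C W (W' C W)^-1`. The product `A s_hat` is invariant to filter
#' rescaling.
#'
#' @param w filter matrix `[N x K]`.
#' @param c_mat covariance matrix `[N x N]` of the same data the filters act
#'   on.
#' @return pattern matrix `[N x K]`.
#' @export
estimate_patterns <- function(w, c_mat) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == nrow(c_mat))
  gram <- t(w) %*% c_mat %*% w
  inv <- tryCatch(solve(symmetrize(gram)), error = function(e) {
    stop("estimate_patterns: W'CW is singular; add covariance shrinkage")
  })
  c_mat %*% w %*% inv
}

#' Estimate patterns for both sides of a filter set
#'
#' @param f a `filter_set`.
#' @param cov a `covariance_set`.
#' @return list with pattern matrices `ax`, `ay`.
#' @export
estimate_pattern_set <- function(f, cov) {
  list(ax = estimate_patterns(f$wx, cov$cx),
       ay = estimate_patterns(f$wy, cov$cy))
}

#' Whiten a channel time series
#'
#' Symmetric (ZCA-flavoured) whitening: the returned transform `P` satisfies
#' `P C P' = I`; output data are `P (x - mean)`.
#'
#' @param x a `channel_timeseries`.
#' @param shrinkage optional diagonal shrinkage before inversion.
#' @return list with `series` (whitened `channel_timeseries`) and
#'   `transform` (`[N x N]`).
#' @export
whiten <- function(x, shrinkage = 0) {
  xd <- x$data - rowMeans(x$data)
  cx <- symmetrize(tcrossprod(xd) / ncol(xd))
  if (shrinkage > 0)
    cx <- cx + shrinkage * (sum(diag(cx)) / nrow(cx)) * diag(nrow(cx))
  p <- inv_sqrtm(cx)
  list(series = cts_with_data(x, p %*% xd), transform = p)
}

#' Per-window bandpower (variance) time course
#'
#' Splits the series into non-overlapping windows of `window_s` seconds and
#' returns the per-window variance of each channel, i.e. the slow bandpower
#' envelope of a band-limited signal. One output sample per complete window;
#' a trailing partial window is dropped.
#'
#' @param x a `channel_timeseries` (typically band-pass-filtered EEG).
#' @param window_s window length in seconds (at least 2 samples).
#' @param demean `"window"` removes the mean per window before squaring
#'   (default); `"global"` uses the channel's global mean.
#' @return a `channel_timeseries` at rate `1/window_s` with modality
#'   `"eeg-bandpower"`.
#' @export
bandpower_series <- function(x, window_s, demean = c("window", "global")) {
  demean <- match.arg(demean)
  w <- round(window_s * x$rate)
  if (abs(window_s * x$rate - w) > 1e-6)
    stop("bandpower_series: window must be an integer number of samples")
  if (w < 2) stop("bandpower_series: window must span at least 2 samples")
  n <- ncol(x$data)
  if (w > n) stop("bandpower_series: window longer than series")
  e <- floor(n / w)
  gm <- rowMeans(x$data)
  out <- matrix(0, nrow(x$data), e)
  for (j in seq_len(e)) {
    seg <- x$data[, ((j - 1) * w + 1):(j * w), drop = FALSE]
    mu <- if (demean == "window") rowMeans(seg) else gm
    out[, j] <- rowMeans((seg - mu)^2)
  }
  channel_timeseries(out, 1 / window_s, x$channel_ids, "eeg-bandpower", x$t0)
}
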