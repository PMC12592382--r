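# ChannelTimeSeries: the in-memory container for multichannel, uniformly
# sampled signals. Rows are channels, columns are samples (the convention of
# the linear forward model x(t) = A s(t) + eps, where x(t) is a column).

MODALITIES <- c("eeg", "eeg-bandpower", "fnirs-hbo", "fnirs-hbr", "fnirs-od")

#' Multichannel uniformly sampled time series
#'
#' Container for EEG/fNIRS channel-space data. Rows are channels, columns are
#' samples; sampling is uniform at `rate` Hz starting at time `t0`.
#'
#' @param data numeric matrix `[n_channels x n_samples]`, all finite.
#' @param rate sampling rate in Hz, positive.
#' @param channel_ids character vector of channel labels (defaults to
#'   `ch1...chN`).
#' @param modality one of `"eeg"`, `"eeg-bandpower"`, `"fnirs-hbo"`,
#'   `"fnirs-hbr"`, `"fnirs-od"`.
#' @param t0 time of the first sample in seconds.
#' @return object of class `channel_timeseries`.
#' @export
channel_timeseries <- function(data, rate, channel_ids = NULL,
                               modality = "eeg", t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("channel_timeseries: data must be finite")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("channel_timeseries: rate must be a positive scalar (Hz)")
  modality <- match.arg(modality, MODALITIES)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop(sprintf("channel_timeseries: %d channel ids for %d channels",
                 length(channel_ids), nrow(data)))
  structure(
    list(data = data, rate = rate, channel_ids = as.character(channel_ids),
         modality = modality, t0 = t0),
    class = "channel_timeseries"
  )
}

#' @export
print.channel_timeseries <- function(x, ...) {
  cat(sprintf("<channel_timeseries> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate))
  invisible(x)
}

#' @export
dim.channel_timeseries <- function(x) dim(x$data)

n_channels <- function(x) nrow(x$data)
n_samples <- function(x) ncol(x$data)

#' Sample times of a channel time series
#' @param x a `channel_timeseries`.
#' @return numeric vector of times in seconds.
#' @export
cts_times <- function(x) x$t0 + (seq_len(ncol(x$data)) - 1) / x$rate

# Replace the data matrix, keeping metadata (internal).
cts_with_data <- function(x, data, rate = x$rate, channel_ids = x$channel_ids,
                          modality = x$modality, t0 = x$t0) {
  channel_timeseries(data, rate, channel_ids, modality, t0)
}

#' Extract a time window from a channel time series
#'
#' @param x a `channel_timeseries`.
#' @param from,to window bounds in seconds (absolute, i.e. on the `t0` axis);
#'   samples with `from <= t < to` are kept.
#' @return a `channel_timeseries` covering the window.
#' @export
cts_window <- function(x, from, to) {
  t <- cts_times(x)
  idx <- which(t >= from - 1e-9 & t < to - 1e-9)
  if (length(idx) == 0) stop("cts_window: empty window")
  cts_with_data(x, x$data[, idx, drop = FALSE], t0 = t[idx[1]])
}

#' Resample a channel time series to a new rate
#'
#' Linear interpolation onto a uniform grid at `target_rate`. Intended for
#' downsampling already low-pass-filtered data (the fNIRS preprocessing path);
#' no anti-alias filter is applied here.
#'
#' @param x a `channel_timeseries`.
#' @param target_rate new sampling rate in Hz.
#' @return a `channel_timeseries` at `target_rate`.
#' @export
cts_resample <- function(x, target_rate) {
  t_old <- cts_times(x)
  duration <- ncol(x$data) / x$rate
  n_new <- floor(duration * target_rate)
  t_new <- x$t0 + (seq_len(n_new) - 1) / target_rate
  out <- t(apply(x$data, 1, function(ch) {
    stats::approx(t_old, ch, xout = t_new, rule = 2)$y
  }))
  if (n_new == 1) out <- matrix(out, nrow = nrow(x$data))
  cts_with_data(x, out, rate = target_rate)
}

#' Center each channel to zero mean
#' @param x a `channel_timeseries`.
#' @return centered `channel_timeseries`.
#' @export
cts_center <- function(x) {
  cts_with_data(x, x$data - rowMeans(x$data))
}

# Concatenate several cts along time (rates/channels must match).
cts_concat <- function(lst) {
  stopifnot(length(lst) >= 1)
  r <- lst[[1]]$rate
  for (s in lst) stopifnot(abs(s$rate - r) < 1e-9,
                           nrow(s$data) == nrow(lst[[1]]$data))
  cts_with_data(lst[[1]], do.call(cbind, lapply(lst, function(s) s$data)),
                t0 = 0)
}
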