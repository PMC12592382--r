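# Benchmark pipeline: modality-specific preprocessing, trial epoching,
# train/test splitting, evaluation against ground truth, and Fisher-z
# aggregation of correlation metrics.

#' Preprocess fNIRS data
#'
#' Zero-phase band-pass 0.01-0.6 Hz, linear detrend, then resampling to
#' `target_rate` (in that order).
#'
#' @param y fNIRS `channel_timeseries` (rate > 1.2 Hz).
#' @param band passband in Hz.
#' @param target_rate output rate (default 2 Hz).
#' @return preprocessed `channel_timeseries`.
#' @export
preprocess_fnirs <- function(y, band = c(0.01, 0.6), target_rate = 2) {
  if (y$rate <= 1.2) stop("preprocess_fnirs: rate must exceed 1.2 Hz")
  if (ncol(y$data) < 3 * y$rate)
    stop("preprocess_fnirs: series too short to filter")
  bf <- signal::butter(2, band / (y$rate / 2), type = "pass")
  # odd-reflection padding lets the very low high-pass corner settle
  pad <- min(ncol(y$data) - 1, round(60 * y$rate))
  filt <- t(apply(y$data, 1, function(ch) {
    n <- length(ch)
    ext <- c(2 * ch[1] - rev(ch[2:(pad + 1)]), ch,
             2 * ch[n] - rev(ch[(n - pad):(n - 1)]))
    as.numeric(signal::filtfilt(bf, ext))[(pad + 1):(pad + n)]
  }))
  t_idx <- seq_len(ncol(filt))
  detr <- t(apply(filt, 1, function(ch) stats::resid(stats::lm(ch ~ t_idx))))
  out <- cts_with_data(y, detr)
  cts_resample(out, target_rate)
}

#' Preprocess EEG data
#'
#' Zero-phase band-pass in the alpha band plus a per-window bandpower time
#' course (variance of non-overlapping windows), the slow feature consumed
#' by the CCA family. With the default 0.5-s window the bandpower series is
#' sampled at 2 Hz.
#'
#' @param x EEG `channel_timeseries` (rate >= 50 Hz).
#' @param alpha_band passband in Hz (default 8-12).
#' @param bp_window_s bandpower window in seconds (default 0.5).
#' @return list with `x_alpha` (filtered, original rate) and `x_bandpower`
#'   (rate `1/bp_window_s`).
#' @export
preprocess_eeg <- function(x, alpha_band = c(8, 12), bp_window_s = 0.5) {
  if (x$rate < 50) stop("preprocess_eeg: rate must be >= 50 Hz")
  bf <- signal::butter(4, alpha_band / (x$rate / 2), type = "pass")
  filt <- t(apply(x$data, 1, function(ch)
    as.numeric(signal::filtfilt(bf, ch))))
  x_alpha <- cts_with_data(x, filt)
  list(x_alpha = x_alpha,
       x_bandpower = bandpower_series(x_alpha, bp_window_s))
}

#' Segment series into trial epochs
#'
#' Each epoch spans the stimulus period plus constant pre- and post-stimulus
#' windows. Trials whose epoch exceeds the recording are dropped with a
#' warning.
#'
#' @param series named list of `channel_timeseries` (e.g. `fnirs`,
#'   `eeg_alpha`, `eeg_bandpower`, and ground-truth series) — all segmented
#'   identically on their own sampling grids.
#' @param schedule a `trial_schedule`.
#' @param pre_s,post_s padding around the stimulus in seconds (default 8).
#' @return list of class `trial_epochs`: `trials` (list; each a named list
#'   of `channel_timeseries`), `schedule`, `pre_s`, `post_s`,
#'   `n_dropped`.
#' @export
epoch_trials <- function(series, schedule, pre_s = 8, post_s = 8) {
  trials <- list()
  dropped <- 0L
  # fixed sample count per series so every trial epoch has the same length
  cut_epoch <- function(s, from, dur) {
    n <- round(dur * s$rate)
    i0 <- ceiling((from - s$t0) * s$rate - 1e-9) + 1
    if (i0 < 1 || i0 + n - 1 > ncol(s$data)) return(NULL)
    cts_with_data(s, s$data[, i0:(i0 + n - 1), drop = FALSE],
                  t0 = s$t0 + (i0 - 1) / s$rate)
  }
  for (tr in seq_len(schedule$n_trials)) {
    from <- schedule$onset[tr] - pre_s
    dur <- pre_s + schedule$stim_s[tr] + post_s
    cut <- lapply(series, cut_epoch, from = from, dur = dur)
    if (any(vapply(cut, is.null, TRUE))) { dropped <- dropped + 1L; next }
    trials[[length(trials) + 1]] <- cut
  }
  if (dropped > 0)
    warning(sprintf("epoch_trials: dropped %d out-of-bounds trial(s)", dropped))
  structure(list(trials = trials, schedule = schedule, pre_s = pre_s,
                 post_s = post_s, n_dropped = dropped),
            class = "trial_epochs")
}

#' Split trial epochs into train and test sets
#'
#' `n_train = round-half-up(train_fraction * n)`, clamped so at least one
#' trial remains in each set; trials are drawn without replacement under the
#' seed. Train trials are concatenated along time per series; test trials
#' stay separate.
#'
#' @param epochs a `trial_epochs`.
#' @param train_fraction fraction of trials used for fitting (default 0.8).
#' @param seed integer seed.
#' @return list with `train` (named list of concatenated
#'   `channel_timeseries`), `test` (list of per-trial named lists),
#'   `train_idx`, `test_idx`.
#' @export
split_trials <- function(epochs, train_fraction = 0.8, seed = 1) {
  n <- length(epochs$trials)
  if (n < 2) stop("split_trials: need at least 2 trials")
  n_train <- floor(train_fraction * n + 0.5)
  n_train <- min(max(n_train, 1), n - 1)
  set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  nm <- names(epochs$trials[[1]])
  train <- lapply(nm, function(s)
    cts_concat(lapply(epochs$trials[train_idx], `[[`, s)))
  names(train) <- nm
  list(train = train, test = epochs$trials[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Fisher-z average of correlations
#'
#' `mean = tanh(mean(atanh(r)))`; the error is the standard error of the
#' mean in z-space, back-transformed. Values at `|r| = 1` are clipped to
#' `1 - 1e-12` with a warning.
#'
#' @param values correlations in `[-1, 1]`, non-empty.
#' @return list with `mean` and `error`.
#' @export
fisher_average <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("fisher_average: no values")
  if (any(abs(values) >= 1)) {
    warning("fisher_average: |r| = 1 clipped")
    values <- pmin(pmax(values, -1 + 1e-12), 1 - 1e-12)
  }
  z <- atanh(values)
  m <- mean(z)
  err <- if (length(z) > 1) tanh(stats::sd(z) / sqrt(length(z))) else 0
  list(mean = tanh(m), error = err)
}

#' Evaluate a fitted model on held-out trials
#'
#' Per test trial: the absolute Pearson correlation between the
#' reconstructed first-component sources and the ground-truth sources, and
#' between estimated and true spatial patterns (pattern metrics are
#' trial-independent and repeated per trial for table uniformity). All
#' metrics are sign-invariant.
#'
#' The comparator for the EEG side depends on the model's input space:
#' models fitted on bandpower (the CCA family) are scored against the
#' ground-truth source's bandpower envelope; models fitted on the
#' band-passed EEG itself (mSPoC) are scored against the raw source.
#'
#' @param model a `decomposition_model` fitted on the training split.
#' @param test list of per-trial named series lists (from
#'   [split_trials()]); each trial must carry the model's input series and
#'   ground-truth series `truth_sx_bp` or `truth_sx`, and `truth_sy`.
#' @param truth a `ground_truth` (for the pattern references, via
#'   `attr(truth, "patterns")` or passed `patterns`).
#' @param patterns list with true `ax`, `ay`.
#' @return data.frame with columns `trial`, `metric`, `value`.
#' @export
evaluate_model <- function(model, test, truth = NULL, patterns = NULL) {
  stopifnot(!is.null(patterns))
  bp_input <- identical(unname(model$input_space["x"]), "eeg-bandpower")
  ax_true <- as.numeric(patterns$ax[, 1])
  ay_true <- as.numeric(patterns$ay[, 1])
  corr_ax <- abs(safe_cor(as.numeric(model$ax[, 1]), ax_true))
  corr_ay <- abs(safe_cor(as.numeric(model$ay[, 1]), ay_true))
  out <- NULL
  for (tr in seq_along(test)) {
    trial <- test[[tr]]
    x_in <- if (bp_input) trial$eeg_bandpower else trial$eeg_alpha
    sx_ref <- if (bp_input) trial$truth_sx_bp else trial$truth_sx
    sx_hat <- project_model(model, x_in, "x")
    sy_hat <- project_model(model, trial$fnirs, "y")
    n_sy <- min(ncol(sy_hat$data), ncol(trial$truth_sy$data))
    n_sx <- min(ncol(sx_hat$data), ncol(sx_ref$data))
    vals <- c(
      corr_sx = abs(safe_cor(sx_hat$data[1, seq_len(n_sx)],
                             sx_ref$data[1, seq_len(n_sx)])),
      corr_sy = abs(safe_cor(sy_hat$data[1, seq_len(n_sy)],
                             trial$truth_sy$data[1, seq_len(n_sy)])),
      corr_ax = corr_ax, corr_ay = corr_ay
    )
    if (anyNA(vals))
      warning("evaluate_model: zero-variance reconstruction; metric missing")
    out <- rbind(out, data.frame(trial = tr, metric = names(vals),
                                 value = unname(vals)))
  }
  out
}
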