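# Semi-synthetic motor-task session generator: a single cortical source
# expressed in both modalities — alpha-band (8-12 Hz) event-related
# desynchronization (ERD) in EEG and a canonical double-gamma hemodynamic
# response in fNIRS HbO, with per-trial HRF amplitude proportional to the
# trial's bandpower decrease — mixed into synthetic physiological
# background at a controlled SNR.

#' Trial schedule for the simulated motor task
#'
#' Trials follow a fixed 10-s stimulus period and a recovery period drawn
#' uniformly from 8-16 s.
#'
#' @param n_trials number of trials (default 12).
#' @param stim_s stimulus duration in seconds.
#' @param recovery_range two-element range of the uniform recovery draw.
#' @param seed integer seed.
#' @param lead_in_s quiet period before the first trial (default 10, long
#'   enough for an 8-s pre-stimulus epoch window).
#' @return list of class `trial_schedule` with `onset`, `stim_s`,
#'   `recovery_s` vectors, `duration` (total, including a trailing
#'   `lead_in_s` tail), and `seed`.
#' @export
make_trial_schedule <- function(n_trials = 12, stim_s = 10,
                                recovery_range = c(8, 16), seed = 1,
                                lead_in_s = 10) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  recovery <- stats::runif(n_trials, recovery_range[1], recovery_range[2])
  onset <- lead_in_s + c(0, cumsum(stim_s + recovery[-n_trials]))
  structure(list(onset = onset, stim_s = rep(stim_s, n_trials),
                 recovery_s = recovery,
                 duration = lead_in_s + sum(stim_s + recovery) + lead_in_s,
                 n_trials = n_trials, seed = seed),
            class = "trial_schedule")
}

#' Canonical double-gamma HRF model
#'
#' `h(t) = g(t; peak) - ratio * g(t; undershoot)` with unit-rate gamma
#' densities whose modes sit at the configured times; the kernel is
#' normalized to unit peak and truncated to `duration_s`.
#'
#' @param peak_s time-to-peak of the positive lobe (default 6).
#' @param undershoot_s time of the undershoot trough (default 16).
#' @param ratio undershoot amplitude ratio (default 1/6).
#' @param onset_delay_s hemodynamic delay relative to ERD onset (default 1).
#' @param duration_s kernel support (default 32).
#' @return list of class `hrf_model`.
#' @export
hrf_model <- function(peak_s = 6, undershoot_s = 16, ratio = 1 / 6,
                      onset_delay_s = 1, duration_s = 32) {
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s, ratio = ratio,
                 onset_delay_s = onset_delay_s, duration_s = duration_s),
            class = "hrf_model")
}

#' Evaluate an HRF kernel on a time grid
#'
#' @param hrf an `hrf_model`.
#' @param rate sampling rate in Hz.
#' @return numeric kernel sampled at `0, 1/rate, ..., duration_s`.
#' @export
hrf_kernel <- function(hrf, rate) {
  t <- seq(0, hrf$duration_s, by = 1 / rate)
  h <- stats::dgamma(t, shape = hrf$peak_s + 1, rate = 1) -
    hrf$ratio * stats::dgamma(t, shape = hrf$undershoot_s + 1, rate = 1)
  h / max(h)
}

#' Neurovascular coupling specification
#'
#' @param erd_depth_range uniform range of per-trial ERD depth (fractional
#'   alpha-power drop during stimulus), default `[0.4, 0.8]`.
#' @param gain proportionality constant linking HRF amplitude to the trial's
#'   bandpower decrease (default 1).
#' @param alpha_band alpha band in Hz (default 8-12).
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(erd_depth_range = c(0.4, 0.8), gain = 1,
                          alpha_band = c(8, 12)) {
  stopifnot(all(erd_depth_range >= 0), all(erd_depth_range <= 1), gain > 0)
  structure(list(erd_depth_range = erd_depth_range, gain = gain,
                 alpha_band = alpha_band),
            class = "coupling_spec")
}

# Band-pass white noise via zero-phase Butterworth filtering.
bandlimited_noise <- function(n, rate, band, order = 4) {
  w <- stats::rnorm(n)
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, w))
}

# Raised-cosine transition from `from` to `to` over `ramp_s`.
raised_cosine_ramp <- function(t, t0, ramp_s, from, to) {
  u <- (t - t0) / ramp_s
  u <- pmin(pmax(u, 0), 1)
  from + (to - from) * (1 - cos(pi * u)) / 2
}

#' Simulate the coupled EEG/fNIRS source time courses
#'
#' EEG source: unit-variance 8-12 Hz noise whose envelope drops by the
#' trial's ERD depth during stimulation (1-s raised-cosine ramps). fNIRS
#' source: a sum of HRF kernels time-locked to each ERD onset (plus the
#' hemodynamic delay), with amplitude `c *` (the trial's measured bandpower
#' decrease), so over trials amplitude and bandpower decrease correlate
#' perfectly by construction.
#'
#' @param schedule a `trial_schedule`.
#' @param hrf an `hrf_model`.
#' @param coupling a `coupling_spec`.
#' @param eeg_rate,fnirs_rate sampling rates (defaults 250, 12.6 Hz).
#' @param seed integer seed.
#' @return list of class `ground_truth`: `sx` and `sy`
#'   (`channel_timeseries`), per-trial `erd_depth`, `bandpower_decrease`,
#'   `amplitude`, plus the generating objects.
#' @export
simulate_sources <- function(schedule, hrf = hrf_model(),
                             coupling = coupling_spec(),
                             eeg_rate = 250, fnirs_rate = 12.6, seed = 1) {
  set.seed(seed)
  n_e <- round(schedule$duration * eeg_rate)
  t_e <- (seq_len(n_e) - 1) / eeg_rate
  alpha <- bandlimited_noise(n_e, eeg_rate, coupling$alpha_band)
  alpha <- alpha / stats::sd(alpha)
  depths <- stats::runif(schedule$n_trials,
                         coupling$erd_depth_range[1],
                         coupling$erd_depth_range[2])
  env <- rep(1, n_e)
  for (tr in seq_len(schedule$n_trials)) {
    on <- schedule$onset[tr]; off <- on + schedule$stim_s[tr]
    lo <- sqrt(1 - depths[tr])   # amplitude factor for a power drop by depth
    span <- t_e >= on - 1e-9 & t_e < off + 1
    env[span] <- pmin(env[span],
                      raised_cosine_ramp(t_e[span], on, 1, 1, lo))
    env[span] <- pmax(env[span],
                      raised_cosine_ramp(t_e[span], off, 1, lo, 1))
  }
  sx <- alpha * env

  # per-trial bandpower decrease attributable to the ERD: variance of the
  # unmodulated alpha minus variance of the modulated signal over the
  # stimulus core (past the onset ramp). Exactly zero when depth = 0.
  decrease <- numeric(schedule$n_trials)
  for (tr in seq_len(schedule$n_trials)) {
    on <- schedule$onset[tr]; off <- on + schedule$stim_s[tr]
    core <- t_e >= on + 1 & t_e < off
    decrease[tr] <- stats::var(alpha[core]) - stats::var(sx[core])
  }
  amplitude <- coupling$gain * decrease

  n_f <- round(schedule$duration * fnirs_rate)
  t_f <- (seq_len(n_f) - 1) / fnirs_rate
  kern <- hrf_kernel(hrf, fnirs_rate)
  sy <- numeric(n_f)
  for (tr in seq_len(schedule$n_trials)) {
    t0 <- schedule$onset[tr] + hrf$onset_delay_s
    i0 <- which(t_f >= t0)[1]
    if (is.na(i0)) next
    idx <- i0:min(n_f, i0 + length(kern) - 1)
    sy[idx] <- sy[idx] + amplitude[tr] * kern[seq_along(idx)]
  }

  structure(list(
    sx = channel_timeseries(matrix(sx, 1), eeg_rate, "sx", "eeg"),
    sy = channel_timeseries(matrix(sy, 1), fnirs_rate, "sy", "fnirs-hbo"),
    schedule = schedule, hrf = hrf, coupling = coupling,
    erd_depth = depths, bandpower_decrease = decrease,
    amplitude = amplitude, seed = seed),
    class = "ground_truth")
}

#' Physiological background model
#'
#' Surrogate resting-state background: spatially smoothed 1/f noise per
#' modality, an alpha-band component for EEG, and global systemic
#' oscillations for fNIRS (cardiac ~1.1 Hz, respiration ~0.25 Hz, Mayer
#' waves ~0.1 Hz) whose channel weights follow a spatial distance kernel.
#'
#' @param exponent_eeg,exponent_fnirs 1/f exponents in `[0, 2]`.
#' @param eeg_alpha_amp relative amplitude of the background alpha
#'   component.
#' @param fnirs_oscillations data.frame with columns `freq`, `amp`,
#'   `bandwidth` (Hz) for the systemic components.
#' @param global_share fraction of fNIRS variance from the shared systemic
#'   components.
#' @param smooth_mm spatial smoothness scale of the noise (mm).
#' @param seed integer seed.
#' @return list of class `background_model`.
#' @export
background_model <- function(exponent_eeg = 1, exponent_fnirs = 1,
                             eeg_alpha_amp = 1,
                             fnirs_oscillations = data.frame(
                               freq = c(1.1, 0.25, 0.1),
                               amp = c(0.6, 0.8, 1.0),
                               bandwidth = c(0.05, 0.03, 0.01)),
                             global_share = 0.5, smooth_mm = 25, seed = 1) {
  stopifnot(exponent_eeg >= 0, exponent_eeg <= 2,
            exponent_fnirs >= 0, exponent_fnirs <= 2,
            all(fnirs_oscillations$amp >= 0),
            global_share >= 0, global_share <= 1)
  structure(list(exponent_eeg = exponent_eeg,
                 exponent_fnirs = exponent_fnirs,
                 eeg_alpha_amp = eeg_alpha_amp,
                 fnirs_oscillations = fnirs_oscillations,
                 global_share = global_share, smooth_mm = smooth_mm,
                 seed = seed),
            class = "background_model")
}

# 1/f^exponent noise via spectral shaping; unit variance. Generated at a
# highly composite length (fast FFT) and truncated to n.
oneoverf_noise <- function(n, rate, exponent) {
  if (exponent == 0) return(stats::rnorm(n))
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  f <- seq(0, rate / 2, length.out = floor(m / 2) + 1)
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  full <- c(shape, rev(shape[2:(m - length(shape) + 1)]))
  x <- Re(stats::fft(stats::fft(w) * full, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Narrow-band oscillation: sinusoid with random-walk phase jitter whose
# spread matches the requested bandwidth; unit variance.
narrowband_osc <- function(n, rate, freq, bandwidth) {
  jitter <- cumsum(stats::rnorm(n, 0, 2 * pi * bandwidth / sqrt(rate)))
  x <- cos(2 * pi * freq * (seq_len(n) - 1) / rate + jitter)
  x / stats::sd(x)
}

# Row-normalized spatial smoothing kernel over channel positions.
smoothing_kernel <- function(positions, scale_mm) {
  d <- as.matrix(stats::dist(positions))
  k <- exp(-d^2 / (2 * scale_mm^2))
  k / sqrt(rowSums(k^2))
}

#' Simulate resting-state background for both modalities
#'
#' @param geom a `montage_geometry`.
#' @param model a `background_model`.
#' @param duration_s recording length (>= 60 s).
#' @param eeg_rate,fnirs_rate sampling rates.
#' @return list with `channel_timeseries` `x0` (EEG) and `y0` (fNIRS HbO).
#' @export
simulate_background <- function(geom, model = background_model(),
                                duration_s, eeg_rate = 250,
                                fnirs_rate = 12.6) {
  if (duration_s < 60) stop("simulate_background: duration must be >= 60 s")
  set.seed(model$seed)
  n_e <- round(duration_s * eeg_rate)
  n_eeg_ch <- nrow(geom$eeg_positions)
  xe <- matrix(0, n_eeg_ch, n_e)
  for (i in seq_len(n_eeg_ch))
    xe[i, ] <- oneoverf_noise(n_e, eeg_rate, model$exponent_eeg)
  ke <- smoothing_kernel(geom$eeg_positions, model$smooth_mm)
  xe <- ke %*% xe
  if (model$eeg_alpha_amp > 0) {
    n_osc <- 4  # a few spatially smooth alpha generators
    for (o in seq_len(n_osc)) {
      src <- bandlimited_noise(n_e, eeg_rate, c(8, 12))
      ctr <- geom$eeg_positions[sample.int(n_eeg_ch, 1), ]
      d <- sqrt(rowSums((geom$eeg_positions -
                           matrix(ctr, n_eeg_ch, 3, byrow = TRUE))^2))
      wgt <- exp(-d^2 / (2 * (2 * model$smooth_mm)^2))
      xe <- xe + model$eeg_alpha_amp * (wgt %*% t(src / stats::sd(src)))
    }
  }
  xe <- xe / apply(xe, 1, stats::sd) * stats::runif(n_eeg_ch, 0.85, 1.15)

  n_f <- round(duration_s * fnirs_rate)
  mid <- montage_channel_midpoints(geom)
  n_ch <- nrow(mid)
  yf <- matrix(0, n_ch, n_f)
  for (i in seq_len(n_ch))
    yf[i, ] <- oneoverf_noise(n_f, fnirs_rate, model$exponent_fnirs)
  kf <- smoothing_kernel(mid, model$smooth_mm)
  yf <- kf %*% yf
  yf <- yf / apply(yf, 1, stats::sd)
  osc <- model$fnirs_oscillations
  if (nrow(osc) > 0 && any(osc$amp > 0) && model$global_share > 0) {
    glob <- matrix(0, n_ch, n_f)
    for (o in seq_len(nrow(osc))) {
      if (osc$amp[o] == 0) next
      g <- narrowband_osc(n_f, fnirs_rate, osc$freq[o], osc$bandwidth[o])
      ctr <- mid[sample.int(n_ch, 1), ]
      d <- sqrt(rowSums((mid - matrix(ctr, n_ch, 3, byrow = TRUE))^2))
      wgt <- 0.5 + exp(-d^2 / (2 * (3 * model$smooth_mm)^2))
      glob <- glob + osc$amp[o] * (wgt %*% t(g))
    }
    glob <- glob / max(apply(glob, 1, stats::sd), 1e-12)
    a <- sqrt(model$global_share); b <- sqrt(1 - model$global_share)
    yf <- b * yf + a * glob
  }
  yf <- yf / apply(yf, 1, stats::sd) * stats::runif(n_ch, 0.85, 1.15)

  list(
    x0 = channel_timeseries(xe, eeg_rate, rownames(geom$eeg_positions), "eeg"),
    y0 = channel_timeseries(yf, fnirs_rate,
                            paste0("S", geom$channels$source, "-D",
                                   geom$channels$detector), "fnirs-hbo")
  )
}

#' Mix clean source activity into background at an exact SNR
#'
#' Channel-space signal `pattern %*% source` is normalized to unit mean
#' power over channels and scaled by `gamma` so that
#' `10 log10(P(gamma signal) / P(background))` equals `snr_db` exactly;
#' both modalities are scaled to the same nominal SNR. `snr_db = -Inf`
#' yields the background unchanged.
#'
#' @param truth a `ground_truth` from [simulate_sources()].
#' @param patterns list with `ax`, `ay` (see [make_spatial_patterns()]).
#' @param background list with `x0`, `y0` (see [simulate_background()]);
#'   truncated to the source duration.
#' @param snr_db target SNR in dB (scalar, finite or `-Inf`).
#' @return list of class `simulated_session`: `x`, `y`
#'   (`channel_timeseries`), `truth`, `patterns`, `snr_db`, `gamma`
#'   (per modality).
#' @export
assemble_dataset <- function(truth, patterns, background, snr_db) {
  if (is.nan(snr_db)) stop("assemble_dataset: snr_db must not be NaN")
  mix_one <- function(src, pat, bg) {
    n <- min(ncol(src$data), ncol(bg$data))
    clean <- pat %*% src$data[, seq_len(n), drop = FALSE]
    p_sig <- mean(clean^2)
    if (p_sig > 0) clean <- clean / sqrt(p_sig)
    bgd <- bg$data[, seq_len(n), drop = FALSE]
    p_bg <- mean(bgd^2)
    gamma <- if (is.infinite(snr_db) && snr_db < 0) 0
             else sqrt(p_bg * 10^(snr_db / 10))
    list(series = cts_with_data(bg, gamma * clean + bgd),
         gamma = gamma)
  }
  mx <- mix_one(truth$sx, patterns$ax, background$x0)
  my <- mix_one(truth$sy, patterns$ay, background$y0)
  structure(list(x = mx$series, y = my$series, truth = truth,
                 patterns = patterns, snr_db = snr_db,
                 gamma = c(x = mx$gamma, y = my$gamma)),
            class = "simulated_session")
}

#' Simulate a full fNIRS-EEG session from a manifest
#'
#' Convenience wrapper running montage, patterns, schedule, sources,
#' background, and SNR mixing from a single parameter list. The returned
#' session embeds the fully resolved manifest; calling
#' `simulate_session(manifest = session$manifest)` reproduces the session
#' bit-exactly.
#'
#' @param n_trials,snr_db,seed headline parameters (ignored when
#'   `manifest` is supplied).
#' @param eeg_rate,fnirs_rate sampling rates.
#' @param manifest optional fully resolved parameter list from a previous
#'   run.
#' @return a `simulated_session` with elements as in [assemble_dataset()]
#'   plus `geometry` and `manifest`.
#' @export
simulate_session <- function(n_trials = 12, snr_db = 0, seed = 1,
                             eeg_rate = 250, fnirs_rate = 12.6,
                             manifest = NULL) {
  if (is.null(manifest)) {
    manifest <- list(
      n_trials = n_trials, snr_db = snr_db, seed = seed,
      eeg_rate = eeg_rate, fnirs_rate = fnirs_rate,
      schedule_seed = derive_seed(seed, 1),
      source_seed = derive_seed(seed, 2),
      background_seed = derive_seed(seed, 3),
      hrf = unclass(hrf_model()),
      coupling = unclass(coupling_spec()),
      background = NULL
    )
  }
  geom <- make_montage()
  patterns <- make_spatial_patterns(geom)
  schedule <- make_trial_schedule(manifest$n_trials,
                                  seed = manifest$schedule_seed)
  hrf <- do.call(hrf_model, manifest$hrf[c("peak_s", "undershoot_s", "ratio",
                                           "onset_delay_s", "duration_s")])
  cpl <- do.call(coupling_spec, manifest$coupling[c("erd_depth_range", "gain",
                                                    "alpha_band")])
  truth <- simulate_sources(schedule, hrf, cpl, manifest$eeg_rate,
                            manifest$fnirs_rate, manifest$source_seed)
  bgm <- background_model(seed = manifest$background_seed)
  bg <- simulate_background(geom, bgm, max(schedule$duration, 60),
                            manifest$eeg_rate, manifest$fnirs_rate)
  sess <- assemble_dataset(truth, patterns, bg, manifest$snr_db)
  sess$geometry <- geom
  sess$manifest <- manifest
  sess
}
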