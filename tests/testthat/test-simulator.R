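test_that("default montage reproduces the reference counts and separations", {
  g <- make_montage()
  expect_equal(nrow(g$fnirs_sources), 14)
  expect_equal(nrow(g$fnirs_detectors), 32)
  expect_equal(nrow(g$channels), 100)
  expect_true(all(abs(g$channels$separation_mm - 19) <= 2 |
                    abs(g$channels$separation_mm - 33) <= 2))
  expect_equal(nrow(g$eeg_positions), 32)
  expect_true(all(c("C3", "C4") %in% rownames(g$eeg_positions)))
  # ground-truth source sits at the C3 landmark
  expect_equal(g$source_location, unname(g$eeg_positions["C3", ]))
})

test_that("surrogate spatial patterns follow their closed forms", {
  g <- make_montage()
  p <- make_spatial_patterns(g)
  # fNIRS mask maximal at the channel midpoint nearest the source
  mid <- montage_channel_midpoints(g)
  d <- sqrt(rowSums((mid - matrix(g$source_location, nrow(mid), 3,
                                  byrow = TRUE))^2))
  expect_equal(which.max(p$ay[, 1]), which.min(d))
  expect_true(all(p$ay >= 0))
  # Gaussian mask closed form: value at 30 mm with sigma 15 mm
  expect_equal(exp(-30^2 / (2 * 15^2)), 0.1353, tolerance = 1e-3)
  ratio <- p$ay[, 1] / max(p$ay[, 1])
  expect_equal(unname(ratio), exp(-(d^2 - min(d)^2) / (2 * 15^2)),
               tolerance = 1e-10)
  # EEG topography is bipolar and peaks at the electrode nearest the source
  expect_true(any(p$ax > 0) && any(p$ax < 0))
  de <- sqrt(rowSums((g$eeg_positions -
                        matrix(g$source_location, 32, 3, byrow = TRUE))^2))
  expect_equal(which.max(abs(p$ax[, 1])), unname(which.min(de)))
  expect_equal(sqrt(sum(p$ax^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(p$ay^2)), 1, tolerance = 1e-12)
})

test_that("trial schedules follow the stimulus/recovery design", {
  s <- make_trial_schedule(seed = 80)
  expect_equal(s$n_trials, 12)
  expect_true(all(s$stim_s == 10))
  expect_true(all(s$recovery_s >= 8 & s$recovery_s <= 16))
  expect_true(all(diff(s$onset) >= 18))  # strictly ordered, non-overlapping

  # expected trial length: stimulus 10 s + mean recovery 12 s
  tot <- vapply(1:100, function(i) {
    sc <- make_trial_schedule(seed = i)
    sum(sc$stim_s + sc$recovery_s)
  }, 1)
  expect_lt(abs(mean(tot) - 12 * 22) / (12 * 22), 0.05)
  expect_identical(make_trial_schedule(seed = 3)$onset,
                   make_trial_schedule(seed = 3)$onset)
})

test_that("coupled sources express the ERD and proportional HRF amplitudes", {
  sch <- make_trial_schedule(seed = 81)
  tr <- simulate_sources(sch, seed = 82)

  # alpha power drops during stimulation in every trial
  t_e <- cts_times(tr$sx)
  for (k in seq_len(sch$n_trials)) {
    on <- sch$onset[k]; off <- on + sch$stim_s[k]
    p_stim <- stats::var(tr$sx$data[1, t_e >= on + 1 & t_e < off])
    p_pre <- stats::var(tr$sx$data[1, t_e >= on - 7 & t_e < on - 1])
    expect_lt(p_stim, p_pre)
  }

  # amplitude proportional to bandpower decrease, exactly
  expect_equal(stats::cor(tr$amplitude, tr$bandpower_decrease), 1,
               tolerance = 1e-10)

  # zero ERD depth forces a flat fNIRS source
  tr0 <- simulate_sources(sch, coupling = coupling_spec(c(0, 0)), seed = 82)
  expect_true(all(tr0$sy$data == 0))

  # HRF kernel peaks at the configured time-to-peak
  k2 <- hrf_kernel(hrf_model(), 12.6)
  expect_equal((which.max(k2) - 1) / 12.6, 6, tolerance = 1 / 12.6 + 1e-9)
})

test_that("hemodynamic response lags the bandpower drop by the coupling latency", {
  sch <- make_trial_schedule(seed = 83)
  tr <- simulate_sources(sch, seed = 84)
  bp <- bandpower_series(tr$sx, 0.5)
  sy2 <- cts_resample(tr$sy, 2)
  n <- min(ncol(bp$data), ncol(sy2$data))
  cc <- stats::ccf(as.numeric(sy2$data[1, 1:n]), -as.numeric(bp$data[1, 1:n]),
                   lag.max = 40, plot = FALSE)
  pk <- cc$lag[which.max(cc$acf)] / 2
  # between the onset delay and the delay + HRF time-to-peak
  expect_gte(pk, hrf_model()$onset_delay_s)
  expect_lte(pk, hrf_model()$onset_delay_s + hrf_model()$peak_s)
})

test_that("background noise carries the systemic signatures", {
  g <- make_montage()
  bg <- simulate_background(g, background_model(seed = 85), 120)

  # Mayer-wave spectral bump within 0.08-0.12 Hz on most channels
  pks <- vapply(seq(1, 91, by = 10), function(i) {
    sp <- stats::spec.pgram(stats::ts(bg$y0$data[i, ], frequency = 12.6),
                            spans = 5, plot = FALSE)
    band <- sp$freq >= 0.06 & sp$freq <= 0.15
    sp$freq[band][which.max(sp$spec[band])]
  }, 1)
  expect_gte(mean(pks >= 0.08 & pks <= 0.12), 0.7)

  # close channel pairs correlate more than distant ones
  mid <- montage_channel_midpoints(g)
  dd <- as.matrix(stats::dist(mid))
  near <- which(dd > 0 & dd < 12, arr.ind = TRUE)[1, ]
  far <- which(dd > 60, arr.ind = TRUE)[1, ]
  expect_gt(stats::cor(bg$y0$data[near[1], ], bg$y0$data[near[2], ]),
            stats::cor(bg$y0$data[far[1], ], bg$y0$data[far[2], ]))

  # channel variances within a factor 3
  v <- apply(bg$y0$data, 1, stats::var)
  expect_lt(max(v) / min(v), 3)
  ve <- apply(bg$x0$data, 1, stats::var)
  expect_lt(max(ve) / min(ve), 3)

  # degenerate config: no oscillations, exponent 0 -> white noise
  bm <- background_model(exponent_eeg = 0, exponent_fnirs = 0,
                         eeg_alpha_amp = 0,
                         fnirs_oscillations = data.frame(freq = 1, amp = 0,
                                                         bandwidth = 0.1),
                         global_share = 0, smooth_mm = 1e-6, seed = 86)
  bg0 <- simulate_background(g, bm, 60)
  ac <- stats::acf(bg0$x0$data[1, ], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 0.05)
})

test_that("SNR mixing is exact and reproducible from the manifest", {
  sess <- simulate_session(snr_db = -10, seed = 87)
  clean <- sess$patterns$ax %*% sess$truth$sx$data[, 1:ncol(sess$x$data)]
  clean <- clean / sqrt(mean(clean^2))
  bg <- sess$x$data - sess$gamma[["x"]] * clean
  snr_meas <- 10 * log10(mean((sess$gamma[["x"]] * clean)^2) / mean(bg^2))
  expect_equal(snr_meas, -10, tolerance = 1e-6)

  # gamma = 0 guard: -Inf SNR returns the background bit-exactly
  s0 <- assemble_dataset(sess$truth, sess$patterns,
                         list(x0 = cts_with_data(sess$x, bg),
                              y0 = sess$y), -Inf)
  expect_identical(s0$x$data, bg)

  # bit-exact reproduction from the manifest
  sess2 <- simulate_session(manifest = sess$manifest)
  expect_identical(sess$x$data, sess2$x$data)
  expect_identical(sess$y$data, sess2$y$data)

  # ground-truth self-consistency: regressing clean channels on the source
  # recovers the pattern
  a_rec <- clean %*% sess$truth$sx$data[1, 1:ncol(clean)] /
    sum(sess$truth$sx$data[1, 1:ncol(clean)]^2)
  expect_gte(abs(stats::cor(a_rec, sess$patterns$ax[, 1])), 0.999)
})
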