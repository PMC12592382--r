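# Shared fixture generators; everything is built in code under fixed seeds.

white_cts <- function(n_ch, t_n, rate = 1, seed = NULL, modality = "eeg") {
  if (!is.null(seed)) set.seed(seed)
  channel_timeseries(matrix(rnorm(n_ch * t_n), n_ch), rate,
                     modality = modality)
}

# A pair of datasets sharing a latent source in channel 1 at a given SNR (dB).
shared_pair <- function(n_x = 2, n_y = 2, t_n = 5000, snr_db = 10,
                        seed = 1) {
  set.seed(seed)
  s <- rnorm(t_n)
  sig <- 10^(-snr_db / 20)
  x <- rbind(s + sig * rnorm(t_n),
             matrix(rnorm((n_x - 1) * t_n), n_x - 1))
  y <- rbind(s + sig * rnorm(t_n),
             matrix(rnorm((n_y - 1) * t_n), n_y - 1))
  list(x = channel_timeseries(x, 1), y = channel_timeseries(y, 1), s = s)
}

# Exhaustive first canonical correlation over unit-norm filter angles for
# 2-channel problems; the brute-force oracle for fit_cca.
brute_force_cca_2x2 <- function(x, y, step_deg = 0.5) {
  cov <- compute_covariances(x, y, 0)
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  wx <- rbind(cos(ang), sin(ang))
  wy <- wx
  qx <- colSums(wx * (cov$cx %*% wx))    # wx' Cx wx per angle
  qy <- colSums(wy * (cov$cy %*% wy))
  num <- t(wx) %*% cov$cxy %*% wy
  corr <- abs(num) / sqrt(qx %o% qy)
  max(corr)
}

# planted mSPoC problem: EEG source whose exact per-window variance (possibly
# lagged by whole epochs) is the latent fNIRS source
planted_mspoc <- function(e_n = 150, w_samp = 50, nx = 4, ny = 3,
                          lag = 0, snr_db = 20, seed = 1) {
  set.seed(seed)
  rate <- 50
  profile <- 1 + 0.8 * sin(2 * pi * seq_len(e_n) / 20)
  sx <- unlist(lapply(seq_len(e_n), function(e)
    sqrt(profile[e]) * rnorm(w_samp)))
  # realized per-window variance of the source (mean-free, 1/n)
  segs <- matrix(sx, w_samp, e_n)
  varprof <- colMeans((t(t(segs) - colMeans(segs)))^2)
  ax <- rnorm(nx); ax <- ax / sqrt(sum(ax^2))
  noise <- matrix(rnorm(nx * e_n * w_samp), nx) * 10^(-snr_db / 20)
  x <- channel_timeseries(ax %*% t(sx) + noise, rate)
  sy <- c(rep(varprof[1], lag), varprof[seq_len(e_n - lag)])
  ay <- rnorm(ny); ay <- ay / sqrt(sum(ay^2))
  ynoise <- matrix(rnorm(ny * e_n), ny) * 0.001
  y <- channel_timeseries(ay %*% t(sy) + ynoise, rate / w_samp)
  list(x = cts_center(x), y = y, ax = ax, ay = ay, profile = varprof,
       window_s = w_samp / rate)
}

planted_jica <- function(ns = 40, nx = 120, ny = 100, k = 2, noise = 0.002,
                         seed = 70) {
  set.seed(seed)
  nf <- nx + ny
  v <- matrix(rexp(nf * k) * sign(rnorm(nf * k)), nf, k)  # heavy-tailed
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  g <- matrix(rnorm(ns * k), ns, k)
  d <- g %*% t(v) + noise * matrix(rnorm(ns * nf), ns)
  list(data = subject_feature_matrix(d[, 1:nx], d[, (nx + 1):nf]),
       v = v, g = g)
}
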