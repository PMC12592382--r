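test_that("epoched covariances reproduce windowed variance for any filter", {
  set.seed(60)
  x <- channel_timeseries(matrix(rnorm(3 * 1000), 3), 10)
  x <- cts_center(x)
  ec <- epoch_covariances(x, 1)
  expect_equal(ec$n_epochs, 100)

  # quadratic-form route equals the bandpower of the filtered source
  w <- rnorm(3)
  sx <- apply_filters(matrix(w, 3, 1), x)
  bp <- bandpower_series(sx, 1)
  qf <- vapply(seq_len(ec$n_epochs), function(e)
    as.numeric(t(w) %*% ec$cov[, , e] %*% w), 1)
  expect_equal(qf, as.numeric(bp$data), tolerance = 1e-10)
  expect_true(all(qf >= 0))

  # unit-variance white noise -> mean windowed variance about 1
  one <- channel_timeseries(matrix(rnorm(5000), 1), 50)
  ec1 <- epoch_covariances(one, 1)
  expect_equal(ec1$n_epochs, 100)
  expect_lt(abs(mean(ec1$cov) - 1), 0.1)

  # constant zero channel -> all-zero covariances
  z <- channel_timeseries(matrix(0 * rnorm(200), 1), 10)
  expect_true(all(epoch_covariances(z, 1)$cov == 0))

  expect_error(epoch_covariances(x, 0.1), "at least 2 samples")
})

test_that("instantaneous mSPoC recovers a planted variance comodulation", {
  pl <- planted_mspoc(seed = 61)
  m <- fit_mspoc(pl$x, pl$y,
                 mspoc_config(n_lags = 1, pca_explained_variance = 1,
                              l2_x = 0, n_restarts = 3, seed = 62),
                 window_s = pl$window_s)
  expect_gte(m$correlations[1], 0.99)
  expect_gte(abs(stats::cor(m$ax[, 1], pl$ax)), 0.9)
  expect_gte(abs(stats::cor(m$ay[, 1], pl$ay)), 0.9)
})

test_that("mSPoC localizes a planted epoch delay in the FIR filter", {
  pl <- planted_mspoc(lag = 2, seed = 63)
  m <- fit_mspoc(pl$x, pl$y,
                 mspoc_config(n_lags = 4, pca_explained_variance = 1,
                              l2_x = 0, n_restarts = 3, seed = 64),
                 window_s = pl$window_s)
  expect_equal(which.max(abs(m$extras$wtau)), 3L)  # lags 0..3 -> index 3 = 2
  expect_gte(m$correlations[1], 0.95)
})

test_that("mSPoC honours its unit constraints and ascends its objective", {
  pl <- planted_mspoc(seed = 65)
  cfg <- mspoc_config(n_lags = 3, pca_explained_variance = 1, l2_x = 0,
                      n_restarts = 2, seed = 66)
  m <- fit_mspoc(pl$x, pl$y, cfg, window_s = pl$window_s)
  # Cx as the method defines it: the mean of the within-window covariances
  ec <- epoch_covariances(pl$x, pl$window_s)
  cx <- apply(ec$cov, c(1, 2), mean)
  expect_lt(abs(as.numeric(t(m$wx) %*% cx %*% m$wx) - 1), 1e-6)
  yd <- pl$y$data - rowMeans(pl$y$data)
  cy <- tcrossprod(yd) / ncol(yd)
  expect_lt(abs(as.numeric(t(m$wy) %*% cy %*% m$wy) - 1), 2e-6)
  expect_lt(abs(sum(m$extras$wtau^2) - 1), 1e-6)
  expect_true(all(diff(m$objective_history) >= -1e-9))

  # scale invariance of the achieved objective
  m2 <- fit_mspoc(cts_with_data(pl$x, 3 * pl$x$data),
                  cts_with_data(pl$y, 0.5 * pl$y$data),
                  cfg, window_s = pl$window_s)
  expect_lt(abs(m$correlations[1] - m2$correlations[1]), 1e-6)

  expect_error(fit_mspoc(pl$x, cts_with_data(pl$y, pl$y$data[, 1:10]),
                         cfg, window_s = pl$window_s),
               "windows but")
})

test_that("the mSPoC objective on true pairings beats an epoch-permutation null", {
  pl <- planted_mspoc(seed = 67)
  cfg <- mspoc_config(n_lags = 1, pca_explained_variance = 1, l2_x = 0,
                      n_restarts = 1, seed = 68, max_iter = 50)
  m <- fit_mspoc(pl$x, pl$y, cfg, window_s = pl$window_s)
  set.seed(69)
  null_obj <- vapply(1:100, function(i) {
    perm <- sample.int(ncol(pl$y$data))
    yp <- cts_with_data(pl$y, pl$y$data[, perm, drop = FALSE])
    suppressWarnings(
      fit_mspoc(pl$x, yp, cfg, window_s = pl$window_s))$extras$objective
  }, 1)
  expect_gt(m$extras$objective, stats::quantile(null_obj, 0.95))
})
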