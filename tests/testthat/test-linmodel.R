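test_that("covariances match hand values, obey shrinkage, and vanish for independent noise", {
  # identical single-channel pair with unit variance
  set.seed(1)
  v <- rnorm(1000)
  v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- channel_timeseries(matrix(v, 1), 1)
  cov <- compute_covariances(x, x, 0)
  expect_equal(cov$cx, matrix(1), tolerance = 1e-12)
  expect_equal(cov$cxy, matrix(1), tolerance = 1e-12)

  # law of large numbers: independent channels decorrelate
  xb <- white_cts(2, 1e5, seed = 2)
  yb <- white_cts(2, 1e5, seed = 3)
  cov2 <- compute_covariances(xb, yb, 0)
  expect_lt(max(abs(cov2$cxy)), 0.05)
  expect_true(isSymmetric(cov2$cx, tol = 1e-10))

  # shrinkage adds exactly shrinkage * (tr/N) to the diagonal
  cov3 <- compute_covariances(xb, yb, 0)
  cov4 <- compute_covariances(xb, yb, 0.1)
  expect_equal(diag(cov4$cx) - diag(cov3$cx),
               rep(0.1 * sum(diag(cov3$cx)) / 2, 2), tolerance = 1e-12)

  expect_error(compute_covariances(xb, white_cts(2, 99, seed = 4)),
               "sample counts differ")
  expect_error(compute_covariances(white_cts(1, 1), white_cts(1, 1)),
               "at least 2 samples")
})

test_that("temporal embedding shifts blocks by whole samples and preserves identity", {
  x <- white_cts(3, 50, rate = 2, seed = 5)

  expect_identical(temporal_embed(x, embedding_config(0))$data, x$data)

  e <- temporal_embed(x, embedding_config(c(0, 1, 2)))
  expect_equal(nrow(e$data), 9)
  expect_identical(e$data[1:3, ], x$data)  # lag-0 block bit-exact

  # impulse at sample 10, lag 1 s at 2 Hz -> impulse at sample 12
  imp <- channel_timeseries(matrix(c(rep(0, 9), 1, rep(0, 10)), 1), 2)
  le <- temporal_embed(imp, embedding_config(c(0, 1)))
  expect_equal(which(le$data[2, ] != 0), 12)

  # zero vs edge padding at the series start
  ee <- temporal_embed(x, embedding_config(1, padding = "edge"))
  expect_equal(ee$data[1:3, 1], x$data[, 1])
  ze <- temporal_embed(x, embedding_config(1, padding = "zero"))
  expect_equal(ze$data[1:3, 1], rep(0, 3))

  expect_error(temporal_embed(x, embedding_config(0.7)), "not representable")
  expect_error(temporal_embed(x, embedding_config(30)), ">= series length")
})

test_that("filter application is the linear backward model", {
  x <- white_cts(2, 200, seed = 6)
  expect_equal(apply_filters(diag(2), x)$data, x$data)

  # [1, -1] cancels a common additive noise channel
  set.seed(7)
  s <- rnorm(300); n <- rnorm(300)
  xc <- channel_timeseries(rbind(s + n, n), 1)
  out <- apply_filters(matrix(c(1, -1), 2, 1), xc)
  expect_equal(as.numeric(out$data), s, tolerance = 1e-12)

  w <- matrix(rnorm(4), 2, 2)
  x3 <- cts_with_data(x, 3 * x$data)
  expect_equal(apply_filters(w, x3)$data, 3 * apply_filters(w, x)$data,
               tolerance = 1e-12)
  expect_error(apply_filters(matrix(1, 3, 1), x), "expects 3 channels")
})

test_that("pattern estimation inverts the backward model", {
  # identity covariance with orthonormal filters returns the filters
  w <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(estimate_patterns(w, diag(3)), w, tolerance = 1e-12)

  # rescaling filters rescales patterns inversely; A s_hat is invariant
  set.seed(8)
  x <- white_cts(3, 500, seed = 8)
  cov <- compute_covariances(x, x, 1e-9)
  w1 <- matrix(rnorm(3), 3, 1)
  a1 <- estimate_patterns(w1, cov$cx)
  a2 <- estimate_patterns(2 * w1, cov$cx)
  expect_equal(a2, a1 / 2, tolerance = 1e-12)
  s1 <- t(w1) %*% x$data
  expect_equal(a1 %*% s1, a2 %*% (t(2 * w1) %*% x$data), tolerance = 1e-10)

  # planted forward model: pattern recovered from any source-recovering filter
  set.seed(9)
  a_true <- c(1, 0.5, -0.3); a_true <- a_true / sqrt(sum(a_true^2))
  s <- rnorm(20000)
  eps <- matrix(rnorm(3 * 20000), 3) * 10^(-20 / 20)
  xd <- channel_timeseries(a_true %*% t(s) + eps, 1)
  covp <- compute_covariances(xd, xd, 1e-9)
  w_rec <- matrix(a_true, 3, 1)       # unit filter aligned with the source
  a_hat <- estimate_patterns(w_rec, covp$cx)
  expect_gte(abs(cor(a_hat[, 1], a_true)), 0.95)

  expect_error(estimate_patterns(matrix(0, 3, 1), cov$cx), "singular")
})

test_that("whitening yields identity covariance and is idempotent", {
  set.seed(10)
  mix <- matrix(c(2, 0.5, 0.3, 1), 2)
  x <- channel_timeseries(mix %*% matrix(rnorm(2 * 4000), 2), 1)
  w1 <- whiten(x)
  cw <- tcrossprod(w1$series$data - rowMeans(w1$series$data)) /
    ncol(w1$series$data)
  expect_equal(cw, diag(2), tolerance = 1e-6)

  # diag(4, 1) input
  xd <- channel_timeseries(rbind(2 * rnorm(4000), rnorm(4000)), 1)
  cw2 <- with(whiten(xd), tcrossprod(series$data - rowMeans(series$data))) / 4000
  expect_equal(cw2, diag(2), tolerance = 1e-6)

  # idempotent up to rotation
  w2 <- whiten(w1$series)
  cw3 <- tcrossprod(w2$series$data - rowMeans(w2$series$data)) / 4000
  expect_equal(cw3, diag(2), tolerance = 1e-6)

  rank_def <- channel_timeseries(rbind(rnorm(100), rnorm(100)) [c(1, 1), ], 1)
  expect_error(whiten(rank_def), "rank deficient")
})

test_that("bandpower is the per-window variance at the window rate", {
  const <- channel_timeseries(matrix(5, 1, 40), 4)
  expect_true(all(bandpower_series(const, 1)$data == 0))

  # unit sine, integer cycles per window -> 0.5
  t <- (0:799) / 100
  sine <- channel_timeseries(matrix(sin(2 * pi * 5 * t), 1), 100)
  bp <- bandpower_series(sine, 1)
  expect_equal(as.numeric(bp$data), rep(0.5, 8), tolerance = 1e-3)
  expect_equal(bp$rate, 1)
  expect_identical(bp$modality, "eeg-bandpower")

  # white noise sigma^2 = 4 -> mean bandpower about 4
  set.seed(11)
  wn <- channel_timeseries(matrix(2 * rnorm(5000), 1), 10)
  bpw <- bandpower_series(wn, 5)
  expect_equal(ncol(bpw$data), 100)
  expect_lt(abs(mean(bpw$data) - 4), 0.4)

  # length = floor(n / window); trailing partial window dropped
  odd <- white_cts(1, 107, rate = 10, seed = 12)
  expect_equal(ncol(bandpower_series(odd, 1)$data), 10)
  expect_error(bandpower_series(odd, 20), "longer than series")
})
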