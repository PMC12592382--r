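test_that("linear-kernel kCCA approximates CCA", {
  p <- shared_pair(n_x = 3, n_y = 2, t_n = 400, snr_db = 5, seed = 40)
  kc <- kernel_config("linear", ridge = 1e-6)
  mk <- fit_kcca(p$x, p$y, k = 1, kernel_x = kc, kernel_y = kc)
  mc <- fit_cca(p$x, p$y)
  expect_lt(abs(mk$correlations[1] - mc$correlations[1]), 0.02)
})

test_that("gaussian kCCA uncovers a quadratic relation invisible to linear CCA", {
  set.seed(41)
  n <- 400
  x <- channel_timeseries(matrix(rnorm(n), 1), 1)
  y <- channel_timeseries(matrix(x$data[1, ]^2 - mean(x$data[1, ]^2), 1), 1)
  lin <- fit_cca(x, y)
  expect_lte(lin$correlations[1], 0.3)
  kg <- kernel_config("gaussian", ridge = 0.01)  # median-heuristic bandwidth
  mk <- fit_kcca(x, y, k = 1, kernel_x = kg, kernel_y = kg)
  expect_gte(mk$correlations[1], 0.8)
})

test_that("kCCA correlations shrink to zero monotonically with ridge", {
  p <- shared_pair(t_n = 300, snr_db = 10, seed = 42)
  cors <- vapply(c(0.01, 0.1, 1, 10, 100), function(r) {
    kc <- kernel_config("linear", ridge = r)
    fit_kcca(p$x, p$y, k = 1, kernel_x = kc, kernel_y = kc)$correlations[1]
  }, 1)
  expect_true(all(diff(cors) < 1e-9))
  expect_lt(cors[length(cors)], 0.05)
})

test_that("kCCA projects new samples through the dual coefficients", {
  p <- shared_pair(t_n = 300, snr_db = 10, seed = 43)
  kc <- kernel_config("gaussian", ridge = 1e-6)
  m <- fit_kcca(p$x, p$y, k = 1, kernel_x = kc, kernel_y = kc)
  # training-set projections reproduce the fitted correlation (at
  # negligible ridge the constrained objective equals the score Pearson)
  sx <- project_kcca(m, p$x, "x")
  sy <- project_kcca(m, p$y, "y")
  expect_equal(abs(stats::cor(sx$data[1, ], sy$data[1, ])),
               m$correlations[1], tolerance = 0.02)
  # projecting a sample subset is consistent with the full projection
  sub <- cts_with_data(p$x, p$x$data[, 1:50, drop = FALSE])
  sxs <- project_kcca(m, sub, "x")
  expect_equal(sxs$data[1, ], sx$data[1, 1:50], tolerance = 1e-8)
  expect_error(kernel_config("gaussian", ridge = 0), "ridge")
  expect_error(kernel_config("gaussian", bandwidth = 0), "bandwidth")
})
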