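test_that("CCA recovers perfect and planted correlations and matches oracles", {
  # identical pair -> correlation 1
  x <- white_cts(1, 500, seed = 30)
  m <- fit_cca(x, x, shrinkage = 0)
  expect_equal(m$correlations[1], 1, tolerance = 1e-10)

  # planted shared source: matches the brute-force angle search and cancor
  p <- shared_pair(snr_db = 10, seed = 31)
  m2 <- fit_cca(p$x, p$y)
  expect_gte(m2$correlations[1], 0.9)
  expect_equal(m2$correlations[1], brute_force_cca_2x2(p$x, p$y, 1),
               tolerance = 1e-3)
  oracle <- stats::cancor(t(p$x$data), t(p$y$data))$cor[1]
  expect_equal(m2$correlations[1], oracle, tolerance = 1e-8)

  # unit-variance constraint and sorted correlations
  cov <- compute_covariances(p$x, p$y)
  expect_equal(as.numeric(t(m2$wx[, 1]) %*% cov$cx %*% m2$wx[, 1]), 1,
               tolerance = 1e-8)
  mk <- fit_cca(p$x, p$y, k = 2)
  expect_true(all(diff(mk$correlations) <= 1e-12))
  expect_true(all(mk$correlations >= 0 & mk$correlations <= 1 + 1e-8))

  expect_error(fit_cca(p$x, p$y, k = 3), "exceeds")
})

test_that("null data gives small canonical correlations", {
  vals <- vapply(1:200, function(i) {
    fit_cca(white_cts(2, 2000, seed = 1000 + i),
            white_cts(2, 2000, seed = 5000 + i))$correlations[1]
  }, 1)
  expect_lt(mean(vals), 0.15)
})

test_that("CCA is invariant to invertible channel mixing and bounded below by channel Pearson", {
  p <- shared_pair(n_x = 3, n_y = 3, snr_db = 5, seed = 32)
  m <- fit_cca(p$x, p$y)
  set.seed(33)
  mix <- matrix(rnorm(9), 3); while (abs(det(mix)) < 0.1) mix <- matrix(rnorm(9), 3)
  xm <- cts_with_data(p$x, mix %*% p$x$data)
  m_mix <- fit_cca(xm, p$y)
  expect_lt(abs(m$correlations[1] - m_mix$correlations[1]), 1e-8)

  best_pair <- max(abs(stats::cor(t(p$x$data), t(p$y$data))))
  expect_gte(m$correlations[1], best_pair - 1e-8)
})

test_that("zero-penalty regularized CCA reduces to CCA; identity mode to PLS", {
  p <- shared_pair(snr_db = 10, seed = 34)
  m0 <- fit_cca(p$x, p$y)
  mr <- fit_regularized_cca(p$x, p$y)
  expect_lt(abs(m0$correlations[1] - mr$correlations[1]), 1e-6)

  # whitened CCA equals PLS: direct SVD of the whitened cross-covariance
  wx <- whiten(p$x); wy <- whiten(p$y)
  mw <- fit_cca(wx$series, wy$series)
  cxy <- compute_covariances(wx$series, wy$series)$cxy
  sv <- svd(cxy, nu = 1, nv = 1)
  pls <- abs(stats::cor(as.numeric(t(sv$u) %*% wx$series$data),
                        as.numeric(t(sv$v) %*% wy$series$data)))
  expect_lt(abs(mw$correlations[1] - pls), 1e-6)
})

test_that("l1 penalties produce exact sparsity concentrated on the informative channel", {
  set.seed(35)
  t_n <- 4000
  s <- rnorm(t_n)
  x <- channel_timeseries(rbind(s + 0.2 * rnorm(t_n),
                                matrix(rnorm(5 * t_n), 5)), 1)
  y <- channel_timeseries(rbind(s + 0.2 * rnorm(t_n),
                                matrix(rnorm(5 * t_n), 5)), 1)
  m <- fit_regularized_cca(x, y, penalties = penalty_config(l1_x = 0.2,
                                                            l1_y = 0.2))
  expect_identical(m$constraint_mode, "identity")
  expect_equal(which.max(abs(m$wx[, 1])), 1L)
  expect_equal(which.max(abs(m$wy[, 1])), 1L)
  expect_gte(sum(m$wx[2:6, 1] == 0), 3)
  expect_gte(sum(m$wy[2:6, 1] == 0), 3)

  # support size is non-increasing along an l1 ladder
  nnz <- vapply(c(0.05, 0.2, 0.5), function(l1) {
    mm <- fit_regularized_cca(x, y, penalties = penalty_config(l1_x = l1,
                                                               l1_y = l1))
    sum(mm$wx[, 1] != 0)
  }, 1)
  expect_true(all(diff(nnz) <= 0))

  # objective history is monotone non-decreasing
  expect_true(all(diff(m$objective_history) >= -1e-9))
})

test_that("GraphNet penalty pulls connected channels together", {
  set.seed(36)
  t_n <- 3000
  s <- rnorm(t_n)
  # channels 1 and 2 carry the same signal and are strongly connected
  x <- channel_timeseries(rbind(s + 0.5 * rnorm(t_n), s + 0.5 * rnorm(t_n),
                                rnorm(t_n)), 1)
  y <- channel_timeseries(matrix(s + 0.5 * rnorm(t_n), 1), 1)
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0))
  g <- suppressMessages(
    build_channel_graph(pos, rule = "distance_threshold", param = 25))
  m_pen <- fit_regularized_cca(x, y,
                               penalties = penalty_config(graph_x = 5),
                               graphs = list(x = g))
  m_ref <- fit_regularized_cca(x, y,
                               penalties = penalty_config(
                                 constraint_mode = "identity"))
  gap <- function(w) abs(w[1, 1] - w[2, 1]) / max(abs(w[1:2, 1]))
  expect_lt(gap(m_pen$wx), gap(m_ref$wx))
})

test_that("temporal embedding lets CCA capture a pure delay", {
  set.seed(37)
  n <- 1000
  xs <- rnorm(n)
  x <- channel_timeseries(matrix(xs, 1), 2)
  y <- channel_timeseries(matrix(c(rep(0, 4), xs[1:(n - 4)]), 1), 2)  # 2 s lag
  m <- fit_tcca(x, y, lags = embedding_config(1:4))
  expect_gte(m$correlations[1], 0.99)
  lag_norms <- apply(m$extras$wx_lags[, , 1, drop = FALSE], 2, function(v)
    sqrt(sum(v^2)))
  expect_equal(which.max(lag_norms), 2L)  # lag grid 1..4 s -> block 2 = 2 s

  m0 <- fit_tcca(x, y, lags = embedding_config(0))
  expect_lt(m0$correlations[1], m$correlations[1])

  # 4 lags on 24 channels -> 96 embedded features
  x24 <- white_cts(24, 200, rate = 2, seed = 38)
  e <- temporal_embed(x24, embedding_config(1:4))
  expect_equal(nrow(e$data), 96)
})
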