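test_that("two-set mCCA reduces to CCA", {
  p <- shared_pair(n_x = 3, n_y = 2, t_n = 2000, snr_db = 5, seed = 50)
  mc <- fit_mcca(list(p$x, p$y))
  cc <- fit_cca(p$x, p$y)
  expect_lt(abs(mc$correlations[1] - cc$correlations[1]), 1e-6)
})

test_that("mCCA aligns a source shared by three datasets", {
  set.seed(51)
  n <- 2000
  s <- rnorm(n)
  mk <- function(extra) channel_timeseries(
    rbind(s + 0.2 * rnorm(n), matrix(rnorm(extra * n), extra)), 1)
  ds <- list(mk(2), mk(1), mk(3))
  m <- fit_mcca(ds, multiset_config(k = 2))
  pw <- abs(m$extras$pairwise[upper.tri(m$extras$pairwise)])
  expect_true(all(pw >= 0.9))

  # deflation: second filters orthogonal to the first in every dataset
  for (w in m$extras$w)
    expect_lt(abs(sum(w[, 1] * w[, 2])), 1e-8)

  # SSQCOR objective also converges with monotone history
  m2 <- fit_mcca(ds, multiset_config(objective = "SSQCOR"))
  expect_true(all(diff(m2$objective_history) >= -1e-9))
  expect_gte(mean(abs(m2$extras$pairwise[upper.tri(m2$extras$pairwise)])), 0.9)

  expect_error(fit_mcca(ds, multiset_config(k = 3)), "exceeds")
  expect_error(fit_mcca(ds[1]), "at least two")
})

test_that("ssmCCA reduces to identity-constrained mCCA and recovers sparse supports", {
  p <- shared_pair(n_x = 3, n_y = 2, t_n = 2000, snr_db = 5, seed = 52)
  s0 <- fit_ssmcca(list(p$x, p$y))
  mi <- fit_mcca(list(p$x, p$y),
                 multiset_config(constraint_mode = "identity"))
  expect_lt(abs(s0$correlations[1] - mi$correlations[1]), 1e-6)

  # sparse shared source among 8 channels per dataset, 3 datasets
  set.seed(53)
  n <- 3000
  s <- rnorm(n)
  mk <- function() channel_timeseries(
    rbind(s + 0.3 * rnorm(n), matrix(rnorm(7 * n), 7)), 1)
  ds <- list(mk(), mk(), mk())
  m <- fit_ssmcca(ds, penalties = list(penalty_config(l1_x = 0.2)))
  for (w in m$extras$w)
    expect_equal(which.max(abs(w[, 1])), 1L)

  # absolute-value objective: flipping one dataset's sign leaves it unchanged
  ds_flip <- ds
  ds_flip[[2]] <- cts_with_data(ds[[2]], -ds[[2]]$data)
  m_flip <- fit_ssmcca(ds_flip, penalties = list(penalty_config(l1_x = 0.2)))
  expect_lt(abs(utils::tail(m$objective_history, 1) -
                  utils::tail(m_flip$objective_history, 1)), 1e-9)
})
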