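test_that("rank-one data identifies its single profile exactly", {
  pl <- planted_jica(k = 1, noise = 0)
  m <- fit_jica(pl$data, k = 1, seed = 71, normalize = FALSE)
  expect_gte(abs(stats::cor(m$v[, 1], pl$v[, 1])), 0.999)
})

test_that("planted heavy-tailed profiles are recovered up to sign and permutation", {
  pl <- planted_jica(k = 2)
  m <- fit_jica(pl$data, k = 2, seed = 72, normalize = FALSE)
  match <- match_components(m$v, pl$v)
  expect_true(all(match$abs_cor >= 0.95))
  expect_lte(m$reconstruction_error, 0.05)  # k = true rank

  # per-modality splits carry the right feature counts; one loading vector
  # per component shared across modalities (structural shape)
  expect_equal(nrow(m$vx) + nrow(m$vy), nrow(m$v))
  expect_equal(dim(m$g), c(40, 2))
  expect_equal(sqrt(colSums(m$v^2)), c(1, 1), tolerance = 1e-12)
})

test_that("jICA is deterministic under a seed and validates inputs", {
  pl <- planted_jica(k = 2, seed = 73)
  m1 <- fit_jica(pl$data, 2, seed = 5)
  m2 <- fit_jica(pl$data, 2, seed = 5)
  expect_identical(m1$v, m2$v)
  expect_error(fit_jica(pl$data, k = 60), "exceeds")
  expect_error(subject_feature_matrix(matrix(1, 3, 2), matrix(1, 4, 2)),
               "subject counts differ")
})

test_that("subject-by-feature tables round-trip through the CSV reader", {
  pl <- planted_jica(ns = 10, nx = 4, ny = 3, k = 1)
  dir <- withr::local_tempdir()
  d <- as.data.frame(pl$data$d)
  names(d) <- pl$data$feature_labels
  utils::write.csv(cbind(subject = paste0("s", 1:10), d),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = pl$data$feature_labels,
                              modality = pl$data$modality),
                   file.path(dir, "modality.csv"), row.names = FALSE)
  rt <- read_subject_features(file.path(dir, "features.csv"),
                              file.path(dir, "modality.csv"))
  expect_equal(unname(rt$dx), unname(pl$data$dx), tolerance = 1e-12)
  expect_equal(unname(rt$dy), unname(pl$data$dy), tolerance = 1e-12)
})
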