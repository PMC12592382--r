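# Multiset CCA: joint decomposition of D >= 2 datasets maximizing overall
# pairwise correlation (SUMCOR) or squared correlation (SSQCOR), with
# filter-orthogonal deflation for further components; plus the structured
# sparse multiset variant (ssmCCA) with l1/GraphNet penalties under
# unit-norm constraints.

#' Multiset CCA configuration
#'
#' @param objective `"SUMCOR"` (sum of pairwise correlations) or `"SSQCOR"`
#'   (sum of squared pairwise correlations).
#' @param k number of components (limited by the smallest dataset).
#' @param max_iter,tol alternating-update controls.
#' @param constraint_mode `"covariance"` (`wi' Ci wi = 1`) or `"identity"`
#'   (`||wi|| = 1`, the PLS-flavoured variant used by the penalized method).
#' @return list of class `multiset_config`.
#' @export
multiset_config <- function(objective = c("SUMCOR", "SSQCOR"), k = 1,
                            max_iter = 200, tol = 1e-10,
                            constraint_mode = c("covariance", "identity")) {
  structure(list(objective = match.arg(objective), k = k,
                 max_iter = max_iter, tol = tol,
                 constraint_mode = match.arg(constraint_mode)),
            class = "multiset_config")
}

# Covariance blocks for a dataset list (centered, 1/T).
multiset_covariances <- function(datasets, shrinkage = 1e-9) {
  t_n <- unique(vapply(datasets, function(d) ncol(d$data), 1L))
  if (length(t_n) != 1) stop("multiset: datasets must share the sample count")
  xs <- lapply(datasets, function(d) d$data - rowMeans(d$data))
  d <- length(xs)
  ci <- lapply(xs, function(x) {
    c0 <- symmetrize(tcrossprod(x) / t_n)
    c0 + shrinkage * (sum(diag(c0)) / nrow(c0)) * diag(nrow(c0))
  })
  cij <- vector("list", d)
  for (i in seq_len(d)) {
    cij[[i]] <- vector("list", d)
    for (j in seq_len(d)) if (i != j)
      cij[[i]][[j]] <- tcrossprod(xs[[i]], xs[[j]]) / t_n
  }
  list(ci = ci, cij = cij, xs = xs, t_n = t_n)
}

#' Multiset canonical correlation analysis (mCCA)
#'
#' Alternating per-dataset updates: each filter `wi` is set to the exact
#' maximizer of the objective given all other filters, under its unit
#' constraint, so the objective is non-decreasing. For `D = 2` with the
#' SUMCOR objective this converges to standard CCA's leading pair. Higher
#' components are obtained by deflation with plain filter orthogonality
#' (`wi,l` orthogonal to the dataset's earlier filters).
#'
#' @param datasets list of `channel_timeseries` (equal sample counts).
#' @param cfg a `multiset_config`.
#' @param shrinkage covariance shrinkage.
#' @return a `decomposition_model`; `extras$w` holds the per-dataset filter
#'   list, `extras$pairwise` the pairwise variate correlation matrix of the
#'   first component. For `D = 2`, `wx`/`wy` mirror the two filter sets.
#' @export
fit_mcca <- function(datasets, cfg = multiset_config(), shrinkage = 1e-9) {
  d <- length(datasets)
  if (d < 2) stop("fit_mcca: need at least two datasets")
  ni <- vapply(datasets, function(x) nrow(x$data), 1L)
  if (cfg$k > min(ni))
    stop(sprintf("fit_mcca: k = %d exceeds smallest dataset size %d",
                 cfg$k, min(ni)))
  cc <- multiset_covariances(datasets, shrinkage)
  w_all <- lapply(ni, function(n) matrix(0, n, cfg$k))
  hist1 <- NULL; iters <- 0L; converged <- TRUE

  for (comp in seq_len(cfg$k)) {
    # orthonormal bases of the orthogonal complement of earlier filters
    basis <- lapply(seq_len(d), function(i) {
      if (comp == 1) diag(ni[i])
      else {
        prev <- w_all[[i]][, seq_len(comp - 1), drop = FALSE]
        qr.Q(qr(cbind(prev, diag(ni[i]))))[, comp:ni[i], drop = FALSE]
      }
    })
    red <- lapply(seq_len(d), function(i) {
      q <- basis[[i]]
      list(ci = symmetrize(t(q) %*% cc$ci[[i]] %*% q),
           q = q)
    })
    # SVD-based init from the (1,2) pair; remaining datasets start flat
    c12 <- t(red[[1]]$q) %*% cc$cij[[1]][[2]] %*% red[[2]]$q
    w <- lapply(seq_len(d), function(i) rep(1, ncol(red[[i]]$q)))
    if (cfg$constraint_mode == "covariance") {
      p1 <- inv_sqrtm(red[[1]]$ci); p2 <- inv_sqrtm(red[[2]]$ci)
      sv <- svd(p1 %*% c12 %*% p2, nu = 1, nv = 1)
      w[[1]] <- as.numeric(p1 %*% sv$u); w[[2]] <- as.numeric(p2 %*% sv$v)
    } else {
      sv <- svd(c12, nu = 1, nv = 1)
      w[[1]] <- as.numeric(sv$u); w[[2]] <- as.numeric(sv$v)
    }
    w <- lapply(seq_len(d), function(i)
      normalize_w(w[[i]], red[[i]]$ci, cfg$constraint_mode))
    obj <- msc_objective(w, red, cc, cfg)
    hist_k <- obj
    conv_k <- FALSE
    for (it in seq_len(cfg$max_iter)) {
      for (i in seq_len(d)) {
        qi <- red[[i]]$q
        if (cfg$objective == "SUMCOR") {
          b <- numeric(ncol(qi))
          for (j in seq_len(d)) if (j != i) {
            b <- b + as.numeric(t(qi) %*% cc$cij[[i]][[j]] %*%
                                  (red[[j]]$q %*% w[[j]]))
          }
          wi <- if (cfg$constraint_mode == "covariance")
            solve(red[[i]]$ci, b) else b
        } else {
          m <- matrix(0, ncol(qi), ncol(qi))
          for (j in seq_len(d)) if (j != i) {
            v <- as.numeric(t(qi) %*% cc$cij[[i]][[j]] %*%
                              (red[[j]]$q %*% w[[j]]))
            m <- m + tcrossprod(v)
          }
          wi <- leading_gev(m, red[[i]]$ci, cfg$constraint_mode)
        }
        w[[i]] <- normalize_w(wi, red[[i]]$ci, cfg$constraint_mode)
      }
      obj_new <- msc_objective(w, red, cc, cfg)
      hist_k <- c(hist_k, obj_new)
      if (abs(obj_new - obj) <= cfg$tol * (abs(obj) + 1e-12)) {
        conv_k <- TRUE; obj <- obj_new; break
      }
      obj <- obj_new
    }
    if (!conv_k) {
      converged <- FALSE
      warning("fit_mcca: alternation did not converge within max_iter")
    }
    iters <- iters + length(hist_k) - 1L
    if (comp == 1) hist1 <- hist_k
    for (i in seq_len(d)) w_all[[i]][, comp] <- red[[i]]$q %*% w[[i]]
  }

  variates <- lapply(seq_len(d), function(i) t(w_all[[i]]) %*% cc$xs[[i]])
  pairwise <- matrix(1, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) if (i != j)
    pairwise[i, j] <- safe_cor(variates[[i]][1, ], variates[[j]][1, ])
  corr <- sapply(seq_len(cfg$k), function(kk) {
    vals <- c()
    for (i in seq_len(d)) for (j in seq_len(d)) if (i < j)
      vals <- c(vals, abs(safe_cor(variates[[i]][kk, ], variates[[j]][kk, ])))
    mean(vals, na.rm = TRUE)
  })
  patterns <- lapply(seq_len(d), function(i)
    estimate_patterns(w_all[[i]], cc$ci[[i]]))
  new_decomposition_model("mcca", w_all[[1]], w_all[[2]], corr,
                          patterns[[1]], patterns[[2]],
                          constraint_mode = cfg$constraint_mode,
                          converged = converged, iterations = iters,
                          objective_history = hist1,
                          input_space = vapply(datasets, function(s) s$modality, ""),
                          extras = list(w = w_all, patterns = patterns,
                                        pairwise = pairwise, d = d,
                                        objective = cfg$objective))
}

normalize_w <- function(w, ci, mode) {
  s <- if (mode == "covariance") sqrt(as.numeric(t(w) %*% ci %*% w))
       else sqrt(sum(w^2))
  if (s == 0) stop("multiset: degenerate (zero-norm) filter update")
  w / s
}

msc_objective <- function(w, red, cc, cfg) {
  d <- length(w)
  total <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) if (i < j) {
    v <- as.numeric(t(red[[i]]$q %*% w[[i]]) %*% cc$cij[[i]][[j]] %*%
                      (red[[j]]$q %*% w[[j]]))
    total <- total + if (cfg$objective == "SUMCOR") v else v^2
  }
  total
}

leading_gev <- function(m, ci, mode) {
  if (mode == "covariance") {
    p <- inv_sqrtm(ci)
    e <- eigen(symmetrize(p %*% m %*% p), symmetric = TRUE)
    as.numeric(p %*% e$vectors[, 1])
  } else {
    eigen(symmetrize(m), symmetric = TRUE)$vectors[, 1]
  }
}

#' Structured sparse multiset CCA (ssmCCA)
#'
#' Maximizes the sum of absolute pairwise cross-covariances under unit-norm
#' constraints with l1 (sparsity) and GraphNet (`wi' Li wi`) penalties in
#' Lagrangian form — the covariance constraints are replaced by identity,
#' as is standard for penalized CCA. Alternating soft-thresholded updates;
#' iterates are accepted while the penalized objective does not decrease.
#'
#' @param datasets list of `channel_timeseries`.
#' @param cfg a `multiset_config` (objective fixed to the absolute-value
#'   SUMCOR form).
#' @param penalties list (length 1 or D) of `penalty_config`s; the x-side
#'   fields (`l1_x`, `l2_x`, `graph_x`) of each apply to the corresponding
#'   dataset.
#' @param graphs optional list (length D) of `channel_graph`s.
#' @param shrinkage covariance shrinkage.
#' @return a `decomposition_model` (see [fit_mcca()] for the multiset
#'   conventions).
#' @export
fit_ssmcca <- function(datasets, cfg = multiset_config(constraint_mode = "identity"),
                       penalties = list(penalty_config()), graphs = NULL,
                       shrinkage = 1e-9) {
  d <- length(datasets)
  if (d < 2) stop("fit_ssmcca: need at least two datasets")
  if (length(penalties) == 1) penalties <- rep(penalties, d)
  stopifnot(length(penalties) == d)
  ni <- vapply(datasets, function(x) nrow(x$data), 1L)
  for (i in seq_len(d)) {
    if (penalties[[i]]$graph_x > 0 &&
        (is.null(graphs[[i]]) || nrow(graphs[[i]]$laplacian) != ni[i]))
      stop(sprintf("fit_ssmcca: dataset %d needs a matching graph", i))
  }
  cc <- multiset_covariances(datasets, shrinkage)
  # penalties act on standardized features (see fit_regularized_cca)
  standardize <- any(vapply(penalties, function(p)
    p$l1_x > 0 || p$l2_x > 0 || p$graph_x > 0, TRUE))
  sdi <- lapply(cc$ci, function(ci) sqrt(pmax(diag(ci), 1e-24)))
  if (standardize) {
    for (i in seq_len(d)) for (j in seq_len(d)) if (i != j)
      cc$cij[[i]][[j]] <- cc$cij[[i]][[j]] / (sdi[[i]] %o% sdi[[j]])
  }
  mi <- lapply(seq_len(d), function(i) {
    p <- penalties[[i]]
    (1 + p$l2_x) * diag(ni[i]) +
      if (p$graph_x > 0) p$graph_x * graphs[[i]]$laplacian else 0
  })
  # init from pairwise SVD against dataset 1
  s1 <- svd(cc$cij[[1]][[2]], nu = 1, nv = 1)
  w <- vector("list", d)
  w[[1]] <- s1$u[, 1]; w[[2]] <- s1$v[, 1]
  if (d > 2) for (i in 3:d) {
    w[[i]] <- as.numeric(cc$cij[[i]][[1]] %*% w[[1]])
    w[[i]] <- w[[i]] / sqrt(sum(w[[i]]^2))
  }

  obj_fun <- function(w) {
    total <- 0
    for (i in seq_len(d)) for (j in seq_len(d)) if (i < j)
      total <- total + abs(as.numeric(t(w[[i]]) %*% cc$cij[[i]][[j]] %*% w[[j]]))
    for (i in seq_len(d)) {
      p <- penalties[[i]]
      total <- total - p$l1_x * sum(abs(w[[i]])) -
        0.5 * p$l2_x * sum(w[[i]]^2) -
        0.5 * (if (p$graph_x > 0)
          p$graph_x * as.numeric(t(w[[i]]) %*% graphs[[i]]$laplacian %*% w[[i]])
          else 0)
    }
    total
  }

  obj <- obj_fun(w)
  hist <- obj
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    w_new <- w
    for (i in seq_len(d)) {
      b <- numeric(ni[i])
      for (j in seq_len(d)) if (j != i) {
        cij <- cc$cij[[i]][[j]]
        sgn <- sign(as.numeric(t(w_new[[i]]) %*% cij %*% w_new[[j]]))
        if (sgn == 0) sgn <- 1
        b <- b + sgn * as.numeric(cij %*% w_new[[j]])
      }
      wi <- solve(mi[[i]], soft_threshold(b, penalties[[i]]$l1_x))
      if (sum(abs(wi)) == 0) next  # keep previous filter if annihilated
      w_new[[i]] <- as.numeric(wi / sqrt(sum(wi^2)))
    }
    obj_new <- obj_fun(w_new)
    if (obj_new < obj - 1e-12) break
    w <- w_new
    hist <- c(hist, obj_new)
    if (abs(obj_new - obj) <= cfg$tol * (abs(obj) + 1e-12)) {
      converged <- TRUE; obj <- obj_new; break
    }
    obj <- obj_new
  }
  if (!converged && it >= cfg$max_iter)
    warning("fit_ssmcca: alternation did not converge within max_iter")

  if (standardize) for (i in seq_len(d)) w[[i]] <- w[[i]] / sdi[[i]]
  variates <- lapply(seq_len(d), function(i) as.numeric(t(w[[i]]) %*% cc$xs[[i]]))
  corr <- {
    vals <- c()
    for (i in seq_len(d)) for (j in seq_len(d)) if (i < j)
      vals <- c(vals, abs(safe_cor(variates[[i]], variates[[j]])))
    mean(vals, na.rm = TRUE)
  }
  patterns <- lapply(seq_len(d), function(i)
    estimate_patterns(matrix(w[[i]], ncol = 1), cc$ci[[i]]))
  w_mats <- lapply(w, function(v) matrix(v, ncol = 1))
  new_decomposition_model("ssmcca", w_mats[[1]], w_mats[[2]], corr,
                          patterns[[1]], patterns[[2]],
                          constraint_mode = "identity",
                          converged = converged || it < cfg$max_iter,
                          iterations = length(hist) - 1L,
                          objective_history = hist,
                          input_space = vapply(datasets, function(s) s$modality, ""),
                          extras = list(w = w_mats, patterns = patterns,
                                        d = d, penalties = penalties))
}
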