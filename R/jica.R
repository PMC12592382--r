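# Joint ICA: concatenate subject-by-feature matrices of both modalities
# along the feature axis and run ICA treating the multimodal feature
# profiles as the independent directions; each component shares a single
# subject-loading vector across modalities.

#' Subject-by-feature matrix pair
#'
#' @param dx,dy numeric matrices `[Ns x Nx]`, `[Ns x Ny]` (subjects in
#'   rows, features in columns), finite, same `Ns`.
#' @param feature_labels optional labels for the concatenated features.
#' @return list of class `subject_feature_matrix` with `dx`, `dy`, the
#'   concatenation `d`, `modality` provenance per feature, and labels.
#' @export
subject_feature_matrix <- function(dx, dy, feature_labels = NULL) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (nrow(dx) != nrow(dy))
    stop("subject_feature_matrix: subject counts differ across modalities")
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    stop("subject_feature_matrix: data must be finite")
  modality <- c(rep("x", ncol(dx)), rep("y", ncol(dy)))
  if (is.null(feature_labels))
    feature_labels <- c(paste0("x", seq_len(ncol(dx))),
                        paste0("y", seq_len(ncol(dy))))
  structure(list(dx = dx, dy = dy, d = cbind(dx, dy), modality = modality,
                 feature_labels = feature_labels),
            class = "subject_feature_matrix")
}

#' Read a subject-by-feature table with a modality sidecar
#'
#' Expects a CSV/TSV with subjects in rows and features in columns, and a
#' two-column sidecar (`feature`, `modality` with values `x`/`y`) mapping
#' each feature column to its modality.
#'
#' @param data_path path to the data table (first column = subject id).
#' @param sidecar_path path to the modality map.
#' @param sep field separator (default `,`).
#' @return a `subject_feature_matrix`.
#' @export
read_subject_features <- function(data_path, sidecar_path, sep = ",") {
  tab <- utils::read.table(data_path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  map <- utils::read.table(sidecar_path, header = TRUE, sep = sep,
                           check.names = FALSE)
  stopifnot(all(c("feature", "modality") %in% names(map)))
  m <- as.matrix(tab)
  mod <- map$modality[match(colnames(m), map$feature)]
  if (anyNA(mod)) stop("read_subject_features: unmapped feature columns")
  subject_feature_matrix(m[, mod == "x", drop = FALSE],
                         m[, mod == "y", drop = FALSE],
                         feature_labels = colnames(m)[order(mod != "x")])
}

#' Joint independent component analysis
#'
#' Fits `D = G V'` where the columns of `V` are statistically independent
#' multimodal feature profiles and `G` holds per-subject loadings shared by
#' both modality blocks. The ICA core is a seeded fixed-point iteration with
#' tanh contrast and symmetric decorrelation after PCA-whitening of the
#' subject dimension to `k` components.
#'
#' @param data a `subject_feature_matrix`.
#' @param k number of components, `k <= min(Ns, Nx + Ny)`.
#' @param seed integer seed (initial rotation).
#' @param normalize z-score each feature before decomposition so neither
#'   modality dominates by scale (default TRUE).
#' @param max_iter,tol fixed-point controls.
#' @return list of class `jica_model`: mixing `g` `[Ns x K]`, unit-norm
#'   profiles `v` `[(Nx+Ny) x K]`, per-modality splits `vx`, `vy`,
#'   reconstruction error, and convergence metadata.
#' @export
fit_jica <- function(data, k, seed = 1, normalize = TRUE,
                     max_iter = 1000, tol = 1e-7) {
  stopifnot(inherits(data, "subject_feature_matrix"))
  d <- data$d
  ns <- nrow(d); nf <- ncol(d)
  if (k > min(ns, nf))
    stop(sprintf("fit_jica: k = %d exceeds min(Ns, Nx+Ny) = %d",
                 k, min(ns, nf)))
  mu <- colMeans(d)
  dc <- sweep(d, 2, mu)
  if (normalize) {
    sds <- apply(dc, 2, stats::sd)
    sds[sds == 0] <- 1
    dc <- sweep(dc, 2, sds, "/")
  }
  # PCA-whiten the subject dimension: rows of z are k whitened "channels",
  # columns are the Nf feature observations
  cs <- tcrossprod(dc) / nf
  e <- eigen(symmetrize(cs), symmetric = TRUE)
  if (e$values[k] <= 1e-12 * e$values[1])
    stop("fit_jica: k exceeds the numerical rank of the data")
  wh <- diag(1 / sqrt(e$values[seq_len(k)]), k) %*%
    t(e$vectors[, seq_len(k), drop = FALSE])
  z <- wh %*% dc  # [k x Nf]

  set.seed(seed)
  w <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  sym_decorrelate <- function(w) {
    s <- w %*% t(w)
    inv_sqrtm(symmetrize(s)) %*% w
  }
  w <- sym_decorrelate(w)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    wz <- w %*% z                    # current source estimates
    g <- tanh(wz)
    g_prime <- 1 - g^2
    w_new <- (g %*% t(z)) / nf - diag(rowMeans(g_prime), k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- 1 - abs(diag(w_new %*% t(w)))
    w <- w_new
    if (max(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_jica: fixed-point iteration did not converge")

  v <- t(w %*% z)                    # [Nf x K] independent profiles
  scale_v <- sqrt(colSums(v^2))
  v <- sweep(v, 2, scale_v, "/")
  g_mix <- dc %*% v %*% solve(crossprod(v))  # least-squares loadings
  recon <- g_mix %*% t(v)
  rel_err <- norm(dc - recon, "F") / norm(dc, "F")
  structure(
    list(g = g_mix, v = v,
         vx = v[data$modality == "x", , drop = FALSE],
         vy = v[data$modality == "y", , drop = FALSE],
         k = k, seed = seed, iterations = it, converged = converged,
         reconstruction_error = rel_err,
         feature_labels = data$feature_labels, modality = data$modality),
    class = "jica_model"
  )
}

#' @export
print.jica_model <- function(x, ...) {
  cat(sprintf("<jica_model> K = %d, Ns = %d, Nf = %d; rel. recon. error %.3f; %s\n",
              x$k, nrow(x$g), nrow(x$v), x$reconstruction_error,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Match estimated profiles to references up to sign and permutation
#'
#' Greedy assignment on absolute correlation, largest first. Used to score
#' planted-model recovery.
#'
#' @param est,ref matrices with components in columns.
#' @return data.frame with `est` index, `ref` index, and `abs_cor`.
#' @export
match_components <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  cm <- abs(stats::cor(est, ref))
  out <- data.frame(est = integer(0), ref = integer(0), abs_cor = numeric(0))
  for (i in seq_len(min(ncol(est), ncol(ref)))) {
    idx <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(est = idx[1], ref = idx[2],
                                 abs_cor = cm[idx[1], idx[2]]))
    cm[idx[1], ] <- -Inf
    cm[, idx[2]] <- -Inf
  }
  out
}
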