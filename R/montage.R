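# Surrogate montage geometry: a 32-channel 10-20 EEG cap and a bilateral
# high-density fNIRS grid (two triangular-lattice patches tangent to the
# scalp at C3/C4) whose source-detector pairings reproduce the reference
# counts: 14 sources, 32 detectors, 100 channels at 19/33 mm separations.

# 10-20/10-10 spherical angles (theta: polar from vertex; phi: azimuth,
# right ear = 0 deg, nasion = 90 deg), 32-channel actiCAP-style set.
EEG_ANGLES <- data.frame(
  label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1",
            "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
            "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1",
            "Oz", "O2"),
  theta = c(90, 90, 90, 60, 45, 60, 90, 108, 69, 32,
            32, 69, 108, 90, 45, 0, 45, 90, 108, 69,
            32, 32, 69, 108, 90, 60, 45, 60, 90, 90,
            90, 90),
  phi = c(108, 72, 144, 129, 90, 51, 36, 158, 160, 135,
          45, 20, 22, 180, 180, 0, 0, 0, 202, 200,
          225, 315, 340, 338, 216, 231, 270, 309, 324, 252,
          270, 288)
)

# Frozen per-patch optode lattice: triangular lattice (spacing 19 mm),
# 23 sites, 7 sources + 16 detectors; yields 50 channels per patch with
# separations 19.0 and 32.9 mm.
PATCH_SITES <- data.frame(
  i = c(0L, -1L, 0L, -1L, 1L, -1L, 0L, 0L, -2L, 1L, -2L, 1L, 0L, -1L,
        1L, -2L, 2L, -1L, 1L, -1L, 0L, -1L, 0L),
  j = c(0L, -1L, -1L, 0L, 0L, 1L, 1L, -2L, -1L, -1L, 1L, 1L, 2L, -2L,
        -2L, 0L, 0L, 2L, 2L, -3L, -3L, 3L, 3L),
  role = c("D", "S", "S", "S", "D", "S", "D", "S", "D", "D", "D", "S",
           "S", "D", "D", "D", "D", "D", "D", "D", "D", "D", "D")
)

sph_to_cart <- function(theta_deg, phi_deg, radius) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  radius * cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

# Orthonormal tangent basis at a scalp point: e1 ~ local anterior,
# e2 ~ normal x e1 (local superior-ish).
tangent_basis <- function(p) {
  n <- p / sqrt(sum(p^2))
  ant <- c(0, 1, 0)
  e1 <- ant - sum(ant * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2, n = n)
}

#' Build the surrogate fNIRS-EEG montage
#'
#' EEG electrodes on a spherical 10-20 layout; fNIRS optodes on two planar
#' triangular-lattice patches tangent to the scalp at C3 and C4. fNIRS
#' channels are all source-detector pairs whose separation falls in the
#' 19 +/- 2 mm or 33 +/- 2 mm bands. The default configuration yields 14
#' sources, 32 detectors, and 100 channels. The ground-truth source sits at
#' the C3 scalp landmark.
#'
#' @param head_radius_mm scalp sphere radius (default 87.5).
#' @param lattice_mm fNIRS lattice spacing = short separation (default 19).
#' @param separation_bands list of `c(center, tol)` pairs defining valid
#'   channels (default `19 +/- 2`, `33 +/- 2`).
#' @return list of class `montage_geometry`: `eeg_positions` (`[32 x 3]`,
#'   mm, rownames = labels), `fnirs_sources` (`[14 x 3]`),
#'   `fnirs_detectors` (`[32 x 3]`), `channels` (data.frame: `source`,
#'   `detector`, `separation_mm`), `source_location` (3-vector).
#' @export
make_montage <- function(head_radius_mm = 87.5, lattice_mm = 19,
                         separation_bands = list(c(19, 2), c(33, 2))) {
  eeg <- sph_to_cart(EEG_ANGLES$theta, EEG_ANGLES$phi, head_radius_mm)
  rownames(eeg) <- EEG_ANGLES$label

  patch_xy <- cbind(
    (PATCH_SITES$i + 0.5 * (PATCH_SITES$j %% 2)) * lattice_mm,
    PATCH_SITES$j * lattice_mm * sqrt(3) / 2
  )
  centers <- list(left = eeg["C3", ], right = eeg["C4", ])
  src <- NULL; det <- NULL
  for (side in c("left", "right")) {
    ctr <- centers[[side]]
    tb <- tangent_basis(ctr)
    pts <- t(apply(patch_xy, 1, function(uv)
      ctr + uv[1] * tb$e1 + uv[2] * tb$e2))
    src <- rbind(src, pts[PATCH_SITES$role == "S", , drop = FALSE])
    det <- rbind(det, pts[PATCH_SITES$role == "D", , drop = FALSE])
  }
  rownames(src) <- paste0("S", seq_len(nrow(src)))
  rownames(det) <- paste0("D", seq_len(nrow(det)))

  ch <- NULL
  for (s in seq_len(nrow(src))) for (d in seq_len(nrow(det))) {
    sep <- sqrt(sum((src[s, ] - det[d, ])^2))
    ok <- any(vapply(separation_bands,
                     function(b) abs(sep - b[1]) <= b[2], TRUE))
    if (ok) ch <- rbind(ch, data.frame(source = s, detector = d,
                                       separation_mm = sep))
  }
  if (is.null(ch)) stop("make_montage: separation constraints admit no channels")
  structure(list(eeg_positions = eeg, fnirs_sources = src,
                 fnirs_detectors = det, channels = ch,
                 source_location = unname(eeg["C3", ]),
                 head_radius_mm = head_radius_mm),
            class = "montage_geometry")
}

#' @export
print.montage_geometry <- function(x, ...) {
  cat(sprintf("<montage_geometry> %d EEG electrodes; %d fNIRS sources x %d detectors -> %d channels\n",
              nrow(x$eeg_positions), nrow(x$fnirs_sources),
              nrow(x$fnirs_detectors), nrow(x$channels)))
  invisible(x)
}

#' fNIRS channel midpoints
#'
#' A channel's position is the source-detector midpoint (used for distance
#' rules and spatial masks).
#'
#' @param geom a `montage_geometry`.
#' @return numeric matrix `[n_channels x 3]` in mm.
#' @export
montage_channel_midpoints <- function(geom) {
  t(apply(geom$channels, 1, function(row) {
    (geom$fnirs_sources[row[["source"]], ] +
       geom$fnirs_detectors[row[["detector"]], ]) / 2
  }))
}

#' Surrogate spatial patterns for the simulated source
#'
#' EEG: a signed, bipolar "Mexican hat" topography
#' `(1 - d^2/(2 sigma^2)) exp(-d^2/(2 sigma^2))` of electrode distance `d`
#' to the source — positive peak at the electrode nearest the source,
#' negative surround. fNIRS: a non-negative Gaussian activity mask
#' `exp(-d^2/(2 sigma^2))` over channel midpoints. Both unit-norm.
#'
#' @param geom a `montage_geometry`.
#' @param sigma_eeg_mm EEG topography scale (default 30).
#' @param sigma_fnirs_mm fNIRS mask scale (default 15).
#' @return list with unit-norm columns `ax` (`[32 x 1]`) and `ay`
#'   (`[n_channels x 1]`).
#' @export
make_spatial_patterns <- function(geom, sigma_eeg_mm = 30,
                                  sigma_fnirs_mm = 15) {
  src <- geom$source_location
  d_e <- sqrt(rowSums((geom$eeg_positions -
                         matrix(src, nrow(geom$eeg_positions), 3,
                                byrow = TRUE))^2))
  ax <- (1 - d_e^2 / (2 * sigma_eeg_mm^2)) * exp(-d_e^2 / (2 * sigma_eeg_mm^2))
  ax <- ax / sqrt(sum(ax^2))
  mid <- montage_channel_midpoints(geom)
  d_f <- sqrt(rowSums((mid - matrix(src, nrow(mid), 3, byrow = TRUE))^2))
  ay <- exp(-d_f^2 / (2 * sigma_fnirs_mm^2))
  ay <- ay / sqrt(sum(ay^2))
  list(ax = matrix(ax, ncol = 1), ay = matrix(ay, ncol = 1))
}
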