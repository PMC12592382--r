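# Channel graphs for structured-sparse (GraphNet) penalties: nodes are
# channels, edges connect spatially close channels, and the graph Laplacian
# L = D - B enters the penalty w' L w, pulling weights of connected channels
# together.

#' Build a channel adjacency graph and its Laplacian
#'
#' @param positions numeric matrix `[N x 3]` of channel positions in mm (for
#'   fNIRS, source-detector midpoints), or a `montage_geometry` with `side`.
#' @param side when a montage is given: `"eeg"` or `"fnirs"`.
#' @param rule `"distance_threshold"` (binary edges below `param` mm, the
#'   benchmark default), `"knn"` (symmetrized k-nearest-neighbour, `param` =
#'   k), or `"gaussian"` (weights `exp(-d^2 / (2 param^2))`).
#' @param param rule parameter (mm for the distance rules, a count for knn).
#' @return list of class `channel_graph` with `adjacency`, `degree`,
#'   `laplacian`, `rule`, `param`.
#' @export
build_channel_graph <- function(positions, side = c("eeg", "fnirs"),
                                rule = c("distance_threshold", "knn", "gaussian"),
                                param = 60) {
  rule <- match.arg(rule)
  if (inherits(positions, "montage_geometry")) {
    side <- match.arg(side)
    positions <- if (side == "eeg") positions$eeg_positions
                 else montage_channel_midpoints(positions)
  }
  positions <- as.matrix(positions)
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  b <- switch(rule,
    distance_threshold = (d < param) * 1,
    gaussian = exp(-d^2 / (2 * param^2)),
    knn = {
      k <- as.integer(param)
      b0 <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(k + 1)]
        b0[i, nb] <- 1
      }
      pmax(b0, t(b0))  # symmetrize: an edge if either is a neighbour
    }
  )
  diag(b) <- 0
  b <- symmetrize(b)
  dimnames(b) <- NULL
  deg <- diag(rowSums(b), n)
  l <- deg - b
  if (any(rowSums(b) == 0))
    message(sprintf("build_channel_graph: %d isolated channel(s)",
                    sum(rowSums(b) == 0)))
  structure(list(adjacency = b, degree = deg, laplacian = l,
                 rule = rule, param = param),
            class = "channel_graph")
}
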