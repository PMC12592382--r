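# DecompositionModel: the common return type of every fusion method.

new_decomposition_model <- function(method, wx, wy, correlations,
                                    ax = NULL, ay = NULL,
                                    constraint_mode = "covariance",
                                    converged = TRUE, iterations = 1L,
                                    objective_history = numeric(0),
                                    input_space = c(x = "eeg-bandpower",
                                                    y = "fnirs-hbo"),
                                    embedding = NULL, extras = list()) {
  wx <- as.matrix(wx); wy <- as.matrix(wy)
  structure(
    list(method = method, wx = wx, wy = wy, k = ncol(wx),
         correlations = correlations, ax = ax, ay = ay,
         constraint_mode = constraint_mode, converged = converged,
         iterations = as.integer(iterations),
         objective_history = objective_history,
         input_space = input_space, embedding = embedding,
         extras = extras),
    class = "decomposition_model"
  )
}

#' @export
print.decomposition_model <- function(x, ...) {
  cat(sprintf("<decomposition_model> %s: k = %d, Nx = %d, Ny = %d\n",
              x$method, x$k, nrow(x$wx), nrow(x$wy)))
  cat("  correlations:", paste(sprintf("%.4f", x$correlations), collapse = ", "),
      "\n")
  cat(sprintf("  constraint: %s; converged: %s (%d iterations)\n",
              x$constraint_mode, x$converged, x$iterations))
  invisible(x)
}

# Canonical variates on new data; side = "x"/"y".
#' Project new data through a fitted model
#'
#' Applies the learned backward-model filters to (centered) data, returning
#' the reconstructed source time courses.
#'
#' @param model a `decomposition_model`.
#' @param x a `channel_timeseries` in the same input space the model was
#'   fitted on (for temporally embedded models, the unembedded series; the
#'   embedding stored in the model is re-applied).
#' @param side `"x"` or `"y"`.
#' @return a `channel_timeseries` of component scores.
#' @export
project_model <- function(model, x, side = c("x", "y")) {
  side <- match.arg(side)
  if (side == "x" && !is.null(model$embedding))
    x <- temporal_embed(cts_center(x), model$embedding)
  w <- if (side == "x") model$wx else model$wy
  apply_filters(w, cts_center(x), side)
}
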