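# Plain-text interchange: JSON model serialization, CSV + JSON session
# container, YAML run configuration. Every artifact embeds a config hash
# and the package version so no run is unattributable.

nf_version <- function() {
  as.character(utils::packageVersion("neurofuse"))
}

config_hash <- function(obj) {
  # dependency-free polynomial rolling hash of the serialized representation
  s <- paste(utils::capture.output(dput(obj)), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize a decomposition model to JSON
#'
#' Writes filters, correlations, patterns, convergence metadata, and
#' provenance (package version, config hash, seed) in a schema-versioned
#' JSON file; numeric arrays are stored at full precision.
#'
#' @param model a `decomposition_model`.
#' @param path output file path.
#' @param seed optional seed recorded as provenance.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, seed = NULL) {
  ser <- list(
    schema = "neurofuse-model/1",
    version = nf_version(),
    method = model$method,
    k = model$k,
    wx = model$wx, wy = model$wy,
    correlations = model$correlations,
    ax = model$ax, ay = model$ay,
    constraint_mode = model$constraint_mode,
    converged = model$converged,
    iterations = model$iterations,
    objective_history = model$objective_history,
    input_space = as.list(model$input_space),
    embedding = if (!is.null(model$embedding)) unclass(model$embedding),
    wtau = model$extras$wtau,
    seed = seed
  )
  ser$hash <- config_hash(ser[c("method", "k", "wx", "wy")])
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized decomposition model
#'
#' @param path JSON file from [write_model()].
#' @return a `decomposition_model`.
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$schema, "neurofuse-model/1"))
    stop("read_model: unrecognized schema")
  emb <- NULL
  if (!is.null(ser$embedding))
    emb <- embedding_config(ser$embedding$lags, ser$embedding$padding,
                            ser$embedding$direction)
  new_decomposition_model(ser$method, as.matrix(ser$wx), as.matrix(ser$wy),
                          ser$correlations,
                          if (!is.null(ser$ax)) as.matrix(ser$ax),
                          if (!is.null(ser$ay)) as.matrix(ser$ay),
                          constraint_mode = ser$constraint_mode,
                          converged = ser$converged,
                          iterations = ser$iterations,
                          objective_history = ser$objective_history %||% numeric(0),
                          input_space = unlist(ser$input_space),
                          embedding = emb,
                          extras = list(wtau = ser$wtau))
}

#' Write a simulated session to a plain-text container
#'
#' One CSV per modality (channels in columns, samples in rows), a CSV with
#' the ground-truth source time courses, and a JSON manifest carrying the
#' trial schedule, spatial patterns, per-trial amplitudes, all seeds, and
#' the reproduction parameters.
#'
#' @param sess a `simulated_session` from [simulate_session()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(sess, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(cts, name) {
    d <- as.data.frame(t(cts$data))
    names(d) <- cts$channel_ids
    utils::write.csv(d, file.path(dir, name), row.names = FALSE)
  }
  wr(sess$x, "eeg.csv")
  wr(sess$y, "fnirs.csv")
  utils::write.csv(
    data.frame(sx_t = c(cts_times(sess$truth$sx)),
               sx = sess$truth$sx$data[1, ]),
    file.path(dir, "truth_sx.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sy_t = c(cts_times(sess$truth$sy)),
               sy = sess$truth$sy$data[1, ]),
    file.path(dir, "truth_sy.csv"), row.names = FALSE)
  manifest <- list(
    schema = "neurofuse-session/1",
    version = nf_version(),
    manifest = sess$manifest,
    snr_db = sess$snr_db,
    gamma = as.list(sess$gamma),
    rates = list(eeg = sess$x$rate, fnirs = sess$y$rate),
    n_channels = list(eeg = nrow(sess$x$data), fnirs = nrow(sess$y$data)),
    schedule = list(onset = sess$truth$schedule$onset,
                    stim_s = sess$truth$schedule$stim_s,
                    recovery_s = sess$truth$schedule$recovery_s),
    erd_depth = sess$truth$erd_depth,
    amplitude = sess$truth$amplitude,
    patterns = list(ax = as.numeric(sess$patterns$ax),
                    ay = as.numeric(sess$patterns$ay))
  )
  manifest$hash <- config_hash(manifest$manifest)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Validates against the known schema: unknown top-level keys are rejected
#' before any compute.
#'
#' @param path YAML file.
#' @param command one of `"simulate"`, `"fit"`, `"benchmark"`.
#' @return named list of parameters with defaults filled in.
#' @export
read_run_config <- function(path, command = c("simulate", "fit", "benchmark")) {
  command <- match.arg(command)
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  schema <- switch(command,
    simulate = list(n_trials = 12, snr_db = 0, seed = 1, eeg_rate = 250,
                    fnirs_rate = 12.6),
    fit = list(method = "elasticnet-tcca", seed = 1, l1 = 0.2, l2 = 0.8,
               lags_s = 1:4, snr_db = 0, n_trials = 12),
    benchmark = list(methods = BENCH_METHODS,
                     snr_grid_db = default_snr_grid(),
                     n_simulations = 50, seed = 1, l1 = 0.2, l2 = 0.8,
                     lags_s = 1:4, eeg_rate = 250, train_fraction = 0.8)
  )
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop(sprintf("read_run_config: unknown key(s): %s",
                 paste(unknown, collapse = ", ")))
  utils::modifyList(schema, raw)
}
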