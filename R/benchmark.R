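# The benchmark loop: simulate -> preprocess -> epoch -> split -> fit each
# method on the train concatenation -> evaluate on held-out trials ->
# Fisher-aggregate per (method, SNR, metric).

BENCH_METHODS <- c("cca", "tcca", "ridge-tcca", "sparse-tcca",
                   "elasticnet-tcca", "ss-tcca", "mspoc")

#' Benchmark configuration
#'
#' Defaults mirror the reference evaluation protocol: l1 = 0.2, l2 = 0.8,
#' embedding lags 1-4 s in 1-s steps, channel-graph distance thresholds
#' 25 mm (fNIRS) / 60 mm (EEG), mSPoC with l2 = 0.8 and PCA keeping 0.99
#' of the variance; 12 trials per simulation, 80/20 split, 20 SNR levels
#' spanning -25..10 dB.
#'
#' @param methods subset of
#'   `c("cca","tcca","ridge-tcca","sparse-tcca","elasticnet-tcca","ss-tcca","mspoc")`.
#' @param snr_grid_db SNR levels in dB.
#' @param n_simulations simulations per SNR.
#' @param seed master seed; every (simulation, SNR, method) cell derives
#'   its own seed.
#' @param l1,l2 penalty weights for the regularized variants.
#' @param lags_s embedding lag grid in seconds.
#' @param graph_mm named distance thresholds `c(eeg = 60, fnirs = 25)`.
#' @param mspoc mSPoC settings (an `mspoc_config`).
#' @param eeg_rate EEG simulation rate.
#' @param train_fraction train share of trials.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(methods = BENCH_METHODS,
                             snr_grid_db = default_snr_grid(),
                             n_simulations = 50, seed = 1,
                             l1 = 0.2, l2 = 0.8, lags_s = 1:4,
                             graph_mm = c(eeg = 60, fnirs = 25),
                             mspoc = mspoc_config(),
                             eeg_rate = 250, train_fraction = 0.8) {
  bad <- setdiff(methods, BENCH_METHODS)
  if (length(bad))
    stop(sprintf("benchmark_config: unknown method(s): %s (registered: %s)",
                 paste(bad, collapse = ", "),
                 paste(BENCH_METHODS, collapse = ", ")))
  structure(list(methods = methods, snr_grid_db = snr_grid_db,
                 n_simulations = n_simulations, seed = seed, l1 = l1,
                 l2 = l2, lags_s = lags_s, graph_mm = graph_mm,
                 mspoc = mspoc, eeg_rate = eeg_rate,
                 train_fraction = train_fraction),
            class = "benchmark_config")
}

#' Default benchmark SNR grid
#'
#' 20 equally spaced levels spanning -25 to 10 dB.
#'
#' @return numeric vector of SNRs in dB.
#' @export
default_snr_grid <- function() seq(-25, 10, length.out = 20)

#' Fit one registered benchmark method on a train split
#'
#' @param method registered method name.
#' @param train named list of concatenated train series (`fnirs`,
#'   `eeg_alpha`, `eeg_bandpower`).
#' @param cfg a `benchmark_config`.
#' @param geom the `montage_geometry` (for the channel graphs).
#' @param seed integer seed (consumed by mSPoC restarts).
#' @return a `decomposition_model`.
#' @export
fit_benchmark_method <- function(method, train, cfg, geom, seed = 1) {
  emb <- embedding_config(cfg$lags_s)
  graphs <- NULL
  if (method == "ss-tcca") {
    graphs <- list(
      x = build_channel_graph(geom, "eeg", "distance_threshold",
                              cfg$graph_mm[["eeg"]]),
      y = build_channel_graph(geom, "fnirs", "distance_threshold",
                              cfg$graph_mm[["fnirs"]])
    )
  }
  switch(method,
    "cca" = fit_cca(train$eeg_bandpower, train$fnirs),
    "tcca" = fit_tcca(train$eeg_bandpower, train$fnirs, lags = emb,
                      penalties = penalty_config()),
    "ridge-tcca" = fit_tcca(train$eeg_bandpower, train$fnirs, lags = emb,
                            penalties = penalty_config(l2_x = cfg$l2,
                                                       l2_y = cfg$l2)),
    "sparse-tcca" = fit_tcca(train$eeg_bandpower, train$fnirs, lags = emb,
                             penalties = penalty_config(l1_x = cfg$l1,
                                                        l1_y = cfg$l1)),
    "elasticnet-tcca" = fit_tcca(train$eeg_bandpower, train$fnirs,
                                 lags = emb,
                                 penalties = penalty_config(
                                   l1_x = cfg$l1, l1_y = cfg$l1,
                                   l2_x = cfg$l2, l2_y = cfg$l2)),
    "ss-tcca" = fit_tcca(train$eeg_bandpower, train$fnirs, lags = emb,
                         penalties = penalty_config(
                           l1_x = cfg$l1, l1_y = cfg$l1,
                           graph_x = cfg$l2, graph_y = cfg$l2),
                         graphs = graphs),
    "mspoc" = {
      mcfg <- cfg$mspoc
      mcfg$seed <- seed
      fit_mspoc(train$eeg_alpha, train$fnirs, mcfg,
                window_s = 1 / train$fnirs$rate)
    },
    stop(sprintf("unknown method '%s'", method))
  )
}

# Prepare a session for the benchmark: preprocess, attach ground-truth
# series on the analysis grids, and epoch.
prepare_session <- function(sess, bp_window_s = 0.5) {
  pf <- preprocess_fnirs(sess$y)
  pe <- preprocess_eeg(sess$x, bp_window_s = bp_window_s)
  truth <- sess$truth
  series <- list(
    fnirs = pf,
    eeg_alpha = pe$x_alpha,
    eeg_bandpower = pe$x_bandpower,
    truth_sx = truth$sx,
    truth_sx_bp = bandpower_series(truth$sx, bp_window_s),
    truth_sy = cts_resample(truth$sy, pf$rate)
  )
  epoch_trials(series, truth$schedule)
}

#' Run the benchmark sweep
#'
#' For every (simulation, SNR): simulate a session, preprocess, epoch,
#' split, fit each requested method on the concatenated train trials, and
#' evaluate source/pattern recovery on the test trials. Failures in a cell
#' are isolated (logged, cell missing) and never abort the sweep.
#'
#' @param cfg a `benchmark_config`.
#' @param out_dir optional directory; when given, the long table is
#'   streamed to `results.csv` as cells complete and a JSON summary is
#'   written at the end.
#' @param progress print per-cell progress lines.
#' @return list of class `benchmark_result`: `table` (long data.frame:
#'   `method`, `snr_db`, `simulation`, `metric`, `value`), `aggregate`
#'   (per method/SNR/metric Fisher mean and error), `failures`, `config`.
#' @export
run_benchmark <- function(cfg = benchmark_config(), out_dir = NULL,
                          progress = FALSE) {
  stopifnot(inherits(cfg, "benchmark_config"))
  tab <- NULL
  failures <- NULL
  csv_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv_path <- file.path(out_dir, "results.csv")
  }
  # geometry, spatial patterns, and background are fixed across simulations;
  # only source time courses (and the SNR mixing) vary
  geom <- make_montage()
  patterns <- make_spatial_patterns(geom)
  bg <- simulate_background(geom,
                            background_model(seed = derive_seed(cfg$seed, 999)),
                            duration_s = 340, eeg_rate = cfg$eeg_rate)
  cell <- 0L
  for (sim in seq_len(cfg$n_simulations)) {
    sim_seed <- derive_seed(cfg$seed, sim)
    schedule <- make_trial_schedule(12, seed = derive_seed(sim_seed, 1))
    truth <- simulate_sources(schedule, eeg_rate = cfg$eeg_rate,
                              seed = derive_seed(sim_seed, 2))
    for (snr in cfg$snr_grid_db) {
      cell <- cell + 1L
      res <- tryCatch({
        sess <- assemble_dataset(truth, patterns, bg, snr)
        sess$geometry <- geom
        epochs <- prepare_session(sess)
        split <- split_trials(epochs, cfg$train_fraction,
                              seed = derive_seed(sim_seed, 1000))
        rows <- NULL
        for (method in cfg$methods) {
          mrow <- tryCatch({
            model <- suppressWarnings(
              fit_benchmark_method(method, split$train, cfg,
                                   sess$geometry,
                                   seed = derive_seed(sim_seed, 2000)))
            ev <- evaluate_model(model, split$test,
                                 patterns = sess$patterns)
            agg <- stats::aggregate(value ~ metric, ev, mean)
            data.frame(method = method, snr_db = snr, simulation = sim,
                       metric = agg$metric, value = agg$value)
          }, error = function(e) {
            failures <<- rbind(failures,
                               data.frame(method = method, snr_db = snr,
                                          simulation = sim,
                                          error = conditionMessage(e)))
            NULL
          })
          rows <- rbind(rows, mrow)
          if (progress)
            message(sprintf("[bench] sim %d snr %.1f %s done", sim, snr,
                            method))
        }
        rows
      }, error = function(e) {
        failures <<- rbind(failures,
                           data.frame(method = "(simulation)", snr_db = snr,
                                      simulation = sim,
                                      error = conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        tab <- rbind(tab, res)
        if (!is.null(csv_path))
          utils::write.table(res, csv_path, sep = ",", append = cell > 1,
                             col.names = cell == 1, row.names = FALSE)
      }
    }
  }
  agg <- NULL
  if (!is.null(tab)) {
    for (m in unique(tab$method)) for (s in unique(tab$snr_db))
      for (met in unique(tab$metric)) {
        v <- tab$value[tab$method == m & tab$snr_db == s & tab$metric == met]
        v <- v[!is.na(v)]
        if (!length(v)) next
        fa <- fisher_average(pmin(v, 1 - 1e-12))
        agg <- rbind(agg, data.frame(method = m, snr_db = s, metric = met,
                                     mean = fa$mean, error = fa$error,
                                     n = length(v)))
      }
  }
  out <- structure(list(table = tab, aggregate = agg, failures = failures,
                        config = cfg),
                   class = "benchmark_result")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(aggregate = agg, failures = failures,
           config = cfg[c("methods", "snr_grid_db", "n_simulations",
                          "seed", "l1", "l2", "lags_s")]),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d rows; %d failures\n",
              if (is.null(x$table)) 0L else nrow(x$table),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  if (!is.null(x$aggregate)) {
    cat("aggregates (Fisher mean):\n")
    print(utils::head(x$aggregate, 20))
  }
  invisible(x)
}
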