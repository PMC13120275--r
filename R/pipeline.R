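# End-to-end pipeline: Las Vegas split search, Monte Carlo model fit,
# metrics, applicability domain, predictions — all artifacts on disk.

#' Default run configuration
#'
#' One master seed governs split search, optimization and synthetic data;
#' subsystem seeds are derived from it deterministically.
#'
#' @param input Path to a compound table, or `NULL` to generate the
#'   synthetic benchmark dataset.
#' @param output_dir Directory for artifacts.
#' @param T,N,target_function,step_magnitude,initial_weight See
#'   [optimizer_config()].
#' @param k,probe_epochs,proportions,criterion See [las_vegas_select()].
#' @param use_existing_split Keep set labels already present in the input
#'   instead of running the split search.
#' @param n_compounds,noise_sd Synthetic-generator settings (used only
#'   when `input` is `NULL`).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = "cwqsar_run",
                       T = 3L, N = 15L, target_function = "TF1",
                       step_magnitude = 0.5, initial_weight = 1.0,
                       k = 10L, probe_epochs = 3L, proportions = rep(0.25, 4),
                       criterion = "iic_cii", use_existing_split = FALSE,
                       n_compounds = 300L, noise_sd = 0.1, seed = 1L) {
  structure(list(input = input, output_dir = output_dir, T = as.integer(T),
                 N = as.integer(N), target_function = target_function,
                 step_magnitude = step_magnitude, initial_weight = initial_weight,
                 k = as.integer(k), probe_epochs = as.integer(probe_epochs),
                 proportions = proportions, criterion = criterion,
                 use_existing_split = isTRUE(use_existing_split),
                 n_compounds = as.integer(n_compounds), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full modeling pipeline
#'
#' Stage 1 selects the best four-way split by the Las Vegas search (unless
#' the input already carries labels and `use_existing_split` is set);
#' stage 2 optimizes correlation weights on that split, fits the final
#' least-squares calibration, and writes all artifacts: the labeled
#' table, candidate-score log, model file, per-block metrics (CSV and
#' readable text), applicability-domain report and prediction table.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the model, labeled dataset, metrics,
#'   domain report and predictions.
#' @export
run_full_pipeline <- function(config = run_config()) {
  seeds <- derive_seeds(config$seed, 3L)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)

  if (is.null(config$input)) {
    message("[data] generating synthetic dataset (n = ", config$n_compounds, ")")
    dataset <- generate_dataset(generator_spec(n_compounds = config$n_compounds,
                                               noise_sd = config$noise_sd,
                                               seed = seeds[1]))
  } else {
    message("[data] reading ", config$input)
    dataset <- read_dataset(config$input)
  }

  if (config$use_existing_split && all(dataset$set != "unassigned")) {
    message("[split] using set labels from the input")
    labeled <- dataset
  } else {
    message("[split] las vegas search over ", config$k, " candidate splits")
    labeled <- las_vegas_select(dataset, k = config$k,
                                probe_epochs = config$probe_epochs,
                                T = config$T, seed = seeds[2],
                                proportions = config$proportions,
                                criterion = config$criterion)
    utils::write.csv(attr(labeled, "candidates"), out_path("split_candidates.csv"),
                     row.names = FALSE)
  }
  write_dataset(labeled, out_path("dataset_labeled.csv"))

  message("[train] optimizing correlation weights (T = ", config$T,
          ", N = ", config$N, ", ", config$target_function, ")")
  opt_cfg <- optimizer_config(T = config$T, N = config$N,
                              target_function = config$target_function,
                              seed = seeds[3],
                              step_magnitude = config$step_magnitude,
                              initial_weight = config$initial_weight)
  model <- fit_qsar_model(labeled, opt_cfg)
  write_model(model, out_path("model.txt"))
  utils::write.csv(attr(model, "trace")$epochs, out_path("trace_epochs.csv"),
                   row.names = FALSE)

  message("[report] metrics, applicability domain, predictions")
  metrics <- block_metrics(model, labeled)
  utils::write.csv(metrics, out_path("metrics.csv"), row.names = FALSE)
  writeLines(format_metrics_text(metrics), out_path("metrics.txt"))
  dom <- domain_report(labeled, attr(model, "dictionary"))
  utils::write.csv(dom, out_path("domain.csv"), row.names = FALSE)
  preds <- predict(model, labeled)
  utils::write.csv(preds, out_path("predictions.csv"), row.names = FALSE)

  invisible(list(model = model, dataset = labeled, metrics = metrics,
                 domain = dom, predictions = preds))
}

# Human-readable metrics block in the conventional column order.
format_metrics_text <- function(metrics) {
  hdr <- sprintf("%-12s %5s %7s %7s %7s %7s %7s %7s %8s",
                 "set", "n", "R2", "CCC", "IIC", "CII", "Q2", "RMSE", "F")
  rows <- vapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    sprintf("%-12s %5d %7.4f %7.4f %7.4f %7.4f %7.4f %7.3f %8.1f",
            m$set, m$n, m$r2, m$ccc, m$iic, m$cii, m$q2, m$rmse, m$f)
  }, "")
  c(hdr, rows)
}
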