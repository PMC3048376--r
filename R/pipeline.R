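#' Default pipeline configuration
#'
#' Nested list of every pipeline setting with its default; unknown keys in
#' a user configuration are rejected. The configuration file format is
#' YAML with the same nesting.
#'
#' @param ... named overrides, e.g. `ga = list(population_size = 30)`.
#' @return nested configuration list.
#' @export
cfl_config <- function(...) {
  base <- list(
    io = list(pkn = NULL, data = NULL),
    expand = list(mode = "all_pairs"),
    sim = cfl_sim_config(),
    ga = cfl_ga_config(),
    train = list(n_runs = 20L, keep_rule = "all"),
    reduction = cfl_refinement_config(),
    optimizer = cfl_optimizer_config(),
    seed = 1L,
    outdir = "cflnet-run")
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown configuration section(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(over)) {
    if (is.list(base[[sec]]) && is.list(over[[sec]])) {
      bad <- setdiff(names(over[[sec]]), names(base[[sec]]))
      if (length(bad)) stop(sprintf("unknown key(s) in [%s]: %s", sec,
                                    paste(bad, collapse = ", ")), call. = FALSE)
      base[[sec]][names(over[[sec]])] <- over[[sec]]
    } else {
      base[[sec]] <- over[[sec]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' @param path YAML file whose top-level keys are the sections of
#'   [cfl_config()].
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  do.call(cfl_config, raw)
}

#' Run the full training pipeline and write its artifacts
#'
#' Executes preprocess, train, reduce/refine/filter and analyze end to end
#' and writes every artifact into the output directory: the compressed
#' network (SIF), the unprocessed and filtered ensemble archives (JSON),
#' the reduction-profile and trade-off tables (CSV), gate frequencies with
#' sensitivities (CSV), the fit-vs-data table (CSV), and a run manifest
#' with the configuration and every derived seed (JSON). Reruns with the
#' same configuration and master seed reproduce the same family.
#'
#' @param config a [cfl_config()] list or path to a YAML file. `io$pkn`
#'   and `io$data` must point to a SIF network and MIDAS CSV.
#' @return the output directory, invisibly; the `cfl_fit` object is
#'   attached as attribute `"fit"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$io$pkn) || !file.exists(config$io$pkn)) {
    stop("configuration error: io$pkn missing or not a file", call. = FALSE)
  }
  if (is.null(config$io$data) || !file.exists(config$io$data)) {
    stop("configuration error: io$data missing or not a file", call. = FALSE)
  }
  pkn <- read_sif(config$io$pkn)
  data <- read_midas(config$io$data)
  fit <- cfl_fit(pkn, data, expand_mode = config$expand$mode,
                 n_runs = config$train$n_runs, seed = config$seed,
                 ga = config$ga, refinement = config$reduction,
                 optimizer = config$optimizer, sim = config$sim)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_sif(fit$compressed, file.path(out, "compressed_network.sif"))
  save_ensemble(fit$unprocessed, file.path(out, "ensemble_unprocessed.json"))
  save_ensemble(fit$filtered, file.path(out, "ensemble_filtered.json"))
  utils::write.csv(fit$profile$table, file.path(out, "reduction_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(threshold_tradeoff_table(fit$profile),
                   file.path(out, "threshold_tradeoff.csv"), row.names = FALSE)
  sm <- summary(fit)
  utils::write.csv(sm$gates, file.path(out, "gate_frequencies.csv"),
                   row.names = FALSE)
  pred <- predict(fit)
  signals <- colnames(data$obs)
  fit_tab <- data.frame(condition = rep(seq_len(nrow(data$obs)),
                                        times = length(signals)),
                        signal = rep(signals, each = nrow(data$obs)),
                        observed = as.vector(data$obs),
                        predicted = as.vector(t(pred$mean[signals, ,
                                                          drop = FALSE])),
                        sd = as.vector(t(pred$sd[signals, , drop = FALSE])))
  utils::write.csv(fit_tab, file.path(out, "fit_vs_data.csv"),
                   row.names = FALSE)
  manifest <- list(seed = config$seed,
                   run_seeds = vapply(fit$unprocessed$models, `[[`,
                                      NA_integer_, "seed"),
                   config = utils::modifyList(config, list(io = config$io)),
                   n_models = length(fit$unprocessed$models))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  structure(invisible(out), fit = fit)
}
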