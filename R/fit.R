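#' Fit an ensemble of constrained fuzzy logic models
#'
#' The package's front-end: runs the complete training workflow on a prior
#' knowledge network and a perturbation-response dataset —
#' \enumerate{
#'   \item assign experimental roles from the dataset and compress the
#'     network;
#'   \item expand it into the hypothesis space of candidate AND/OR gates
#'     with discrete transfer-function slots;
#'   \item train a family of models with independent runs of the discrete
#'     genetic algorithm (redundant gates removed);
#'   \item reduce each model along the reduction-threshold grid;
#'   \item refine the surviving transfer-function parameters continuously;
#'   \item select each model's fewest-parameter form within the selection
#'     threshold (the filtered family).
#' }
#'
#' @param pkn a `cfl_pkn` (e.g. from [read_sif()]).
#' @param data a `cfl_dataset` (e.g. from [read_midas()]).
#' @param expand_mode gate expansion mode, see [expand_pkn()].
#' @param n_runs number of independent GA runs (family size).
#' @param seed master seed; all randomness derives from it.
#' @param ga,refinement,optimizer,sim configuration objects; see
#'   [cfl_ga_config()], [cfl_refinement_config()], [cfl_optimizer_config()],
#'   [cfl_sim_config()].
#' @param refine run stages 4-6; when FALSE the fit stops at the
#'   unprocessed family.
#' @return an object of class `cfl_fit` with components `pkn`,
#'   `compressed`, `hypothesis`, `unprocessed`, `profile`, `filtered`,
#'   `data` and the configurations used.
#' @seealso [gate_frequencies()], [ensemble_predict()],
#'   [build_reduction_profile()]
#' @export
cfl_fit <- function(pkn, data, expand_mode = c("all_pairs", "inhibitory_only"),
                    n_runs = 20L, seed = 1L, ga = cfl_ga_config(),
                    refinement = cfl_refinement_config(),
                    optimizer = cfl_optimizer_config(),
                    sim = cfl_sim_config(), refine = TRUE) {
  expand_mode <- match.arg(expand_mode)
  stopifnot(inherits(pkn, "cfl_pkn"), inherits(data, "cfl_dataset"))
  cl <- match.call()
  pkn <- designate_roles(pkn, data)
  compressed <- compress(pkn)
  hs <- expand_pkn(compressed, expand_mode)
  ga$seed <- as.integer(seed)
  unprocessed <- train_family(hs, data, ga, n_runs = n_runs, sim = sim)
  profile <- NULL
  filtered <- NULL
  if (refine) {
    profile <- build_reduction_profile(unprocessed, data, refinement,
                                       optimizer, sim)
    filtered <- select_filtered(profile)
  }
  structure(list(call = cl, pkn = pkn, compressed = compressed,
                 hypothesis = hs, unprocessed = unprocessed,
                 profile = profile, filtered = filtered, data = data,
                 seed = seed,
                 config = list(ga = ga, refinement = refinement,
                               optimizer = optimizer, sim = sim,
                               expand_mode = expand_mode)),
            class = "cfl_fit")
}

# family used for prediction-style methods: filtered if available
.fit_family <- function(object) {
  if (!is.null(object$filtered)) object$filtered else object$unprocessed
}

#' @export
print.cfl_fit <- function(x, ...) {
  cat("Constrained fuzzy logic model family\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  ss <- count_search_space(x$hypothesis)
  cat(sprintf("Hypothesis space: %d gates, %d slots (search space %d^%d)\n",
              ss$w, ss$h, ss$alphabet_size, ss$h))
  fam <- .fit_family(x)
  mses <- vapply(fam$models, `[[`, 0, "mse")
  np <- vapply(fam$models, parameter_count, 0L)
  cat(sprintf("%s family: %d models, MSE %.4g (median), %.1f parameters (mean)\n",
              fam$stage, length(fam$models), stats::median(mses), mean(np)))
  invisible(x)
}

#' @export
summary.cfl_fit <- function(object, frequency_cut = 0, ...) {
  fam <- .fit_family(object)
  freq <- gate_frequencies(fam)
  freq <- freq[freq$frequency > frequency_cut, , drop = FALSE]
  sens <- lapply(freq$gate, function(gi) {
    if (freq$frequency[match(gi, freq$gate)] == 0) return(c(NA, NA))
    s <- ensemble_sensitivity(fam, gi)
    c(s$mean, s$sd)
  })
  freq$sensitivity <- vapply(sens, `[[`, 0, 1)
  freq$sensitivity_sd <- vapply(sens, `[[`, 0, 2)
  mses <- vapply(fam$models, `[[`, 0, "mse")
  out <- list(gates = freq, stage = fam$stage, n_models = length(fam$models),
              mse = c(min = min(mses), median = stats::median(mses),
                      max = max(mses)),
              n_params = vapply(fam$models, parameter_count, 0L))
  class(out) <- "summary.cfl_fit"
  out
}

#' @export
print.summary.cfl_fit <- function(x, ...) {
  cat(sprintf("cFL %s family of %d models\n", x$stage, x$n_models))
  cat(sprintf("MSE: min %.4g, median %.4g, max %.4g; parameters: %.1f (mean)\n\n",
              x$mse["min"], x$mse["median"], x$mse["max"], mean(x$n_params)))
  cat("Gate frequencies and sensitivities:\n")
  tab <- x$gates[order(-x$gates$frequency), c("output", "inputs", "frequency",
                                              "sensitivity", "sensitivity_sd")]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.cfl_fit <- function(object, ...) {
  fam <- .fit_family(object)
  freq <- gate_frequencies(fam)
  freq[freq$frequency > 0, , drop = FALSE]
}

#' Ensemble predictions from a fitted family
#'
#' @param object a `cfl_fit`.
#' @param newdata a `cfl_dataset` or design list; defaults to the training
#'   design.
#' @param ... unused.
#' @return a `cfl_prediction_summary` (mean/sd/CV per node x condition).
#' @export
predict.cfl_fit <- function(object, newdata = NULL, ...) {
  conditions <- if (is.null(newdata)) object$data else newdata
  ensemble_predict(.fit_family(object), conditions, object$config$sim)
}

#' @export
residuals.cfl_fit <- function(object, ...) {
  pred <- predict(object)
  signals <- colnames(object$data$obs)
  t(pred$mean[signals, , drop = FALSE]) - object$data$obs
}

#' Simulate datasets from a fitted family
#'
#' Draws `nsim` models from the filtered family (with replacement when
#' `nsim` exceeds the family size) and returns the dataset each would
#' generate on the training design.
#'
#' @param object a `cfl_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed for the member draw.
#' @param ... unused.
#' @return list of `cfl_dataset`s.
#' @export
simulate.cfl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  fam <- .fit_family(object)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(fam$models), nsim, replace = nsim > length(fam$models))
  design <- list(stimuli = object$data$stimuli,
                 inhibitors = object$data$inhibitors)
  lapply(idx, function(i) {
    simulate_dataset(fam$models[[i]], design, noise_sd = 0,
                     measured = colnames(object$data$obs),
                     sim = object$config$sim)
  })
}

#' Plot a fitted cFL family
#'
#' `type = "profile"` draws each model's refined MSE along the
#' reduction-threshold grid (the curves whose jumps define the filter
#' points); `type = "fit"` draws ensemble-mean predictions against the
#' observations.
#'
#' @param x a `cfl_fit`.
#' @param type `"profile"` or `"fit"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.cfl_fit <- function(x, type = c("profile", "fit"), ...) {
  type <- match.arg(type)
  if (type == "profile") {
    if (is.null(x$profile)) stop("fit has no reduction profile", call. = FALSE)
    tab <- x$profile$table
    thr <- pmax(tab$threshold, min(tab$threshold[tab$threshold > 0]) / 10)
    graphics::plot(NA, xlim = range(thr), ylim = range(tab$mse), log = "x",
                   xlab = "reduction threshold", ylab = "refined MSE", ...)
    for (mi in unique(tab$model)) {
      sub <- tab[tab$model == mi, ]
      graphics::lines(pmax(sub$threshold,
                           min(tab$threshold[tab$threshold > 0]) / 10),
                      sub$mse, col = grDevices::grey(0.3), lwd = 1)
    }
  } else {
    pred <- predict(x)
    signals <- colnames(x$data$obs)
    p <- as.vector(t(pred$mean[signals, , drop = FALSE]))
    o <- as.vector(x$data$obs)
    graphics::plot(o, p, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "observed", ylab = "ensemble mean prediction", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
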