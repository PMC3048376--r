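#' Accuracy/precision quadrant of a held-out prediction
#'
#' Classifies a prediction by its test MSE (accuracy) and the ensemble's
#' mean coefficient of variation on the held-out cells (precision):
#' predictions with MSE > `mse_cut` are inaccurate, those with CV >
#' `cv_cut` imprecise.
#'
#' @param mse held-out test MSE.
#' @param cv mean CV of the ensemble predictions on the held-out cells.
#' @param mse_cut,cv_cut thresholds (defaults 0.20 and 0.25).
#' @return one of `"precise_accurate"`, `"imprecise_accurate"`,
#'   `"precise_inaccurate"`, `"imprecise_inaccurate"`.
#' @export
prediction_quadrant <- function(mse, cv, mse_cut = 0.20, cv_cut = 0.25) {
  paste0(if (!is.na(cv) && cv > cv_cut) "imprecise" else "precise", "_",
         if (mse > mse_cut) "inaccurate" else "accurate")
}

# shared trainer for the cross-validation harnesses: family -> filtered (or
# unprocessed when refinement is disabled for speed)
.cv_train <- function(hs, dataset, ga, n_runs, refinement, do_refine, sim) {
  fam <- train_family(hs, dataset, ga, n_runs = n_runs, sim = sim)
  if (!do_refine) return(fam)
  prof <- build_reduction_profile(fam, dataset, refinement, sim = sim)
  select_filtered(prof)
}

# mean per-model MSE of an ensemble on a set of observation cells
.cells_mse <- function(ensemble, dataset, cells, sim) {
  obs <- dataset$obs
  sims <- lapply(ensemble$models, simulate_model, conditions = dataset,
                 sim = sim)
  per_model <- vapply(sims, function(sr) {
    p <- t(sr$x[colnames(obs), , drop = FALSE])
    err <- ifelse(is.na(p[cells]), 1, (p[cells] - obs[cells])^2)
    mean(err)
  }, 0)
  mean(per_model)
}

#' k-fold cross-validation of the training workflow
#'
#' Partitions the non-missing observation cells into `folds` random
#' disjoint subsets; for each fold, trains a model family on the dataset
#' with the fold's cells masked out and evaluates the MSE on the held-out
#' cells. The partition is exhaustive and seeded.
#'
#' @param hs a `cfl_hypothesis`.
#' @param dataset a `cfl_dataset`.
#' @param folds number of folds (>= 2).
#' @param seed partition seed.
#' @param ga a [cfl_ga_config()].
#' @param n_runs GA runs per fold family.
#' @param refinement a [cfl_refinement_config()].
#' @param do_refine run the reduce/refine/filter stage per fold (slower);
#'   when FALSE the unprocessed family is evaluated.
#' @param mse_cut,cv_cut quadrant thresholds, see [prediction_quadrant()].
#' @param sim a [cfl_sim_config()].
#' @return object of class `cfl_crossval`: data.frame `report` with one row
#'   per fold (train/test MSE, mean CV, quadrant) plus the partition.
#' @export
kfold_crossval <- function(hs, dataset, folds = 10L, seed = 1L,
                           ga = cfl_ga_config(), n_runs = 3L,
                           refinement = cfl_refinement_config(),
                           do_refine = FALSE, mse_cut = 0.20, cv_cut = 0.25,
                           sim = cfl_sim_config()) {
  stopifnot(folds >= 2)
  cells <- which(!is.na(dataset$obs))
  if (length(cells) < folds) stop("fewer observation cells than folds",
                                  call. = FALSE)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(folds), length(cells)))
  rows <- list()
  for (f in seq_len(folds)) {
    test_cells <- cells[assignment == f]
    train_obs <- dataset$obs
    train_obs[test_cells] <- NA_real_
    train_ds <- cfl_dataset(dataset$stimuli, dataset$inhibitors, train_obs)
    cfg <- ga
    cfg$seed <- (seed + 7919L * f) %% .Machine$integer.max
    fam <- .cv_train(hs, train_ds, cfg, n_runs, refinement, do_refine, sim)
    pred <- ensemble_predict(fam, dataset, sim)
    cvv <- t(pred$cv[colnames(dataset$obs), , drop = FALSE])[test_cells]
    rows[[f]] <- data.frame(
      fold = f,
      n_test = length(test_cells),
      train_mse = .cells_mse(fam, dataset, setdiff(cells, test_cells), sim),
      test_mse = .cells_mse(fam, dataset, test_cells, sim),
      mean_cv = if (all(is.na(cvv))) NA_real_ else mean(cvv, na.rm = TRUE))
  }
  report <- do.call(rbind, rows)
  report$quadrant <- mapply(prediction_quadrant, report$test_mse,
                            report$mean_cv,
                            MoreArgs = list(mse_cut = mse_cut, cv_cut = cv_cut))
  structure(list(report = report, folds = folds, seed = seed,
                 assignment = assignment, cells = cells),
            class = "cfl_crossval")
}

#' @export
print.cfl_crossval <- function(x, ...) {
  cat(sprintf("cFL cross-validation (%d test sets)\n", nrow(x$report)))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Signal/stimulus holdout cross-validation
#'
#' Removes from the training data all measurements of one signal under one
#' stimulus (across all inhibitor treatments), trains a family on the rest,
#' and scores the prediction of the held-out cells. The pair is eligible
#' only if the signal is at least partially activated (observed >=
#' `activation_floor`) under the held-out stimulus and under some other
#' stimulus — otherwise there is nothing to predict or nothing to learn
#' from.
#'
#' @param hs a `cfl_hypothesis`.
#' @param dataset a `cfl_dataset`.
#' @param signal measured node to hold out.
#' @param stimulus stimulus node defining the held-out conditions (rows
#'   where this stimulus is > 0).
#' @param activation_floor eligibility threshold (default 0.1).
#' @inheritParams kfold_crossval
#' @return a one-row `cfl_crossval` report.
#' @export
holdout_crossval <- function(hs, dataset, signal, stimulus,
                             activation_floor = 0.1, seed = 1L,
                             ga = cfl_ga_config(), n_runs = 3L,
                             refinement = cfl_refinement_config(),
                             do_refine = FALSE, mse_cut = 0.20,
                             cv_cut = 0.25, sim = cfl_sim_config()) {
  stopifnot(signal %in% colnames(dataset$obs),
            stimulus %in% colnames(dataset$stimuli))
  on_rows <- which(dataset$stimuli[[stimulus]] > 0)
  off_rows <- setdiff(seq_len(nrow(dataset$stimuli)), on_rows)
  obs_on <- dataset$obs[on_rows, signal]
  obs_off <- dataset$obs[off_rows, signal]
  if (!any(obs_on >= activation_floor, na.rm = TRUE)) {
    stop(sprintf("ineligible pair: '%s' is never activated (>= %.2g) under %s",
                 signal, activation_floor, stimulus), call. = FALSE)
  }
  if (!any(obs_off >= activation_floor, na.rm = TRUE)) {
    stop(sprintf("ineligible pair: '%s' is never activated (>= %.2g) under any other stimulation",
                 signal, activation_floor), call. = FALSE)
  }
  sig_col <- match(signal, colnames(dataset$obs))
  test_cells <- on_rows[!is.na(dataset$obs[on_rows, signal])] +
    (sig_col - 1L) * nrow(dataset$obs)
  train_obs <- dataset$obs
  train_obs[on_rows, signal] <- NA_real_
  train_ds <- cfl_dataset(dataset$stimuli, dataset$inhibitors, train_obs)
  cfg <- ga
  cfg$seed <- seed
  fam <- .cv_train(hs, train_ds, cfg, n_runs, refinement, do_refine, sim)
  pred <- ensemble_predict(fam, dataset, sim)
  cvv <- t(pred$cv[colnames(dataset$obs), , drop = FALSE])[test_cells]
  test_mse <- .cells_mse(fam, dataset, test_cells, sim)
  mean_cv <- if (all(is.na(cvv))) NA_real_ else mean(cvv, na.rm = TRUE)
  all_cells <- which(!is.na(train_obs))
  report <- data.frame(
    signal = signal, stimulus = stimulus, n_test = length(test_cells),
    train_mse = .cells_mse(fam, dataset, all_cells, sim),
    test_mse = test_mse, mean_cv = mean_cv,
    quadrant = prediction_quadrant(test_mse, mean_cv, mse_cut, cv_cut))
  structure(list(report = report, seed = seed, held_out = test_cells,
                 family = fam),
            class = "cfl_crossval")
}
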