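#' Refinement and filtering settings
#'
#' @param reduction_grid ascending reduction thresholds; must contain 0.
#'   The default spans the decades over which trained models typically show
#'   their characteristic jump in refined MSE.
#' @param selection_threshold allowed MSE increase over a model's baseline
#'   when selecting its final (fewest-parameter) reduced-refined form.
#' @return list of refinement settings.
#' @export
cfl_refinement_config <- function(reduction_grid = c(0, 1e-5, 5e-5, 1e-4,
                                                     5e-4, 1e-3, 5e-3,
                                                     1e-2, 5e-2),
                                  selection_threshold = 5e-3) {
  stopifnot(0 %in% reduction_grid, !is.unsorted(reduction_grid),
            selection_threshold >= 0)
  list(reduction_grid = reduction_grid,
       selection_threshold = selection_threshold)
}

#' Continuous-optimizer settings
#'
#' Bounds and tolerances for the local continuous parameter search used in
#' refinement. Bounds cover the discrete libraries with margin.
#'
#' @param k_bounds,n_bounds,slope_bounds parameter box constraints.
#' @param maxit iteration cap for the bounded quasi-Newton optimizer.
#' @param tol convergence tolerance passed to the optimizer (factr-style).
#' @return list of optimizer settings.
#' @export
cfl_optimizer_config <- function(k_bounds = c(0.01, 2), n_bounds = c(1, 5),
                                 slope_bounds = c(0, 1), maxit = 200L,
                                 tol = 1e7) {
  list(k_bounds = k_bounds, n_bounds = n_bounds, slope_bounds = slope_bounds,
       maxit = as.integer(maxit), tol = tol)
}

# enumerate candidate alterations of a model: deactivate an active gate, or
# replace an active 2-input AND gate by one of its 1-input sub-gates
# (retaining the slot's transfer spec), when that sub-gate exists in the
# hypothesis space. Deterministic order: (output, gate index, kind).
.alterations <- function(model) {
  hs <- model$hypothesis
  act <- active_gates(model)
  alts <- list()
  for (gi in act) {
    g <- hs$gates[[gi]]
    alts[[length(alts) + 1L]] <- list(kind = "drop", gate = gi,
                                      output = g$output)
    if (nrow(g$inputs) == 2) {
      for (i in 1:2) {
        target <- which(vapply(hs$gates, function(gg) {
          gg$output == g$output && nrow(gg$inputs) == 1 &&
            gg$inputs$node == g$inputs$node[i] &&
            gg$inputs$sign == g$inputs$sign[i]
        }, TRUE))
        if (length(target) == 1) {
          alts[[length(alts) + 1L]] <- list(kind = "replace", gate = gi,
                                            sub = target, keep_slot = g$slots[i],
                                            output = g$output)
        }
      }
    }
  }
  ord <- order(vapply(alts, `[[`, "", "output"),
               vapply(alts, `[[`, 0L, "gate"),
               vapply(alts, `[[`, "", "kind"))
  alts[ord]
}

.apply_alteration <- function(model, alt) {
  hs <- model$hypothesis
  if (alt$kind == "replace") {
    sub_slot <- hs$gates[[alt$sub]]$slots
    model$type[sub_slot] <- model$type[alt$keep_slot]
    model$p1[sub_slot] <- model$p1[alt$keep_slot]
    model$p2[sub_slot] <- model$p2[alt$keep_slot]
  }
  deactivate_gates(model, alt$gate)
}

#' Reduce a trained model at a reduction threshold
#'
#' Greedy simplification: at each step every candidate alteration (gate
#' removal, or replacement of a 2-input AND gate by one of its 1-input
#' sub-gates retaining that slot's transfer function) is scored, and the
#' one with the smallest resulting MSE is applied provided that MSE does
#' not exceed the unprocessed model's MSE by more than `threshold`
#' (cumulative degradation is capped against the starting model, matching
#' the filter-point semantics of the workflow). Ties break deterministically
#' by (output name, gate index, alteration kind).
#'
#' @param model a `cfl_model`.
#' @param dataset a `cfl_dataset`.
#' @param threshold allowed MSE increase over the unprocessed MSE (>= 0;
#'   `Inf` removes every gate).
#' @param sim a [cfl_sim_config()].
#' @param base_mse reference MSE for the cap; defaults to the model's
#'   current MSE (recomputed if unset).
#' @return the reduced `cfl_model`, stage `"reduced"`, `mse` updated.
#' @export
reduce_model <- function(model, dataset, threshold, sim = cfl_sim_config(),
                         base_mse = NULL) {
  stopifnot(threshold >= 0)
  ev <- .make_evaluator(model$hypothesis, dataset, sim)
  cur_mse <- ev(model$type, model$p1, model$p2)
  if (is.null(base_mse)) base_mse <- cur_mse
  repeat {
    alts <- .alterations(model)
    if (!length(alts)) break
    cand <- lapply(alts, function(a) .apply_alteration(model, a))
    mses <- vapply(cand, function(m) ev(m$type, m$p1, m$p2), 0)
    ok <- mses <= base_mse + threshold
    if (!any(ok)) break
    best <- which(ok)[which.min(mses[ok])]
    model <- cand[[best]]
    cur_mse <- mses[best]
  }
  model$stage <- "reduced"
  model$mse <- cur_mse
  model
}

#' Refine the continuous parameters of a reduced model
#'
#' Treats the transfer-function parameters of all active slots as
#' continuous (Hill: k in `k_bounds`, n in `n_bounds`; linear: slope in
#' `slope_bounds`) and minimizes the MSE with a bounded quasi-Newton local
#' search (L-BFGS-B) started from the current values. The topology (active
#' gate set) is fixed. If the optimizer fails or returns a worse model, the
#' incoming model is returned with a warning.
#'
#' @param model a `cfl_model` (typically stage `"reduced"`).
#' @param dataset a `cfl_dataset`.
#' @param optimizer a [cfl_optimizer_config()].
#' @param sim a [cfl_sim_config()].
#' @return the model with refined parameters, stage `"reduced_refined"`.
#' @export
refine_parameters <- function(model, dataset,
                              optimizer = cfl_optimizer_config(),
                              sim = cfl_sim_config()) {
  hs <- model$hypothesis
  ev <- .make_evaluator(hs, dataset, sim)
  act_slots <- unlist(lapply(hs$gates[active_gates(model)], `[[`, "slots"))
  incoming_mse <- ev(model$type, model$p1, model$p2)
  model$mse <- incoming_mse
  if (!length(act_slots)) {
    model$stage <- "reduced_refined"
    return(model)
  }
  # parameter vector layout: for each active slot, slope (linear) or (n, k)
  theta <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  idx <- list()
  for (s in act_slots) {
    if (model$type[s] == 1L) {
      idx[[as.character(s)]] <- length(theta) + 1L
      theta <- c(theta, model$p1[s])
      lower <- c(lower, optimizer$slope_bounds[1])
      upper <- c(upper, optimizer$slope_bounds[2])
    } else {
      idx[[as.character(s)]] <- length(theta) + 1:2
      theta <- c(theta, model$p1[s], model$p2[s])
      lower <- c(lower, optimizer$n_bounds[1], optimizer$k_bounds[1])
      upper <- c(upper, optimizer$n_bounds[2], optimizer$k_bounds[2])
    }
  }
  theta <- pmin(pmax(theta, lower), upper)
  inject <- function(th) {
    p1 <- model$p1; p2 <- model$p2
    for (s in act_slots) {
      i <- idx[[as.character(s)]]
      if (model$type[s] == 1L) {
        p1[s] <- th[i]
      } else {
        p1[s] <- th[i[1]]; p2[s] <- th[i[2]]
      }
    }
    list(p1 = p1, p2 = p2)
  }
  obj <- function(th) {
    p <- inject(th)
    ev(model$type, p$p1, p$p2)
  }
  fit <- tryCatch(
    stats::optim(theta, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = optimizer$maxit,
                                factr = optimizer$tol)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > incoming_mse + 1e-9) {
    if (is.null(fit)) warning("parameter refinement failed; keeping incoming model",
                              call. = FALSE)
    model$stage <- "reduced_refined"
    return(model)
  }
  p <- inject(fit$par)
  model$p1 <- p$p1
  model$p2 <- p$p2
  model$genome <- NULL
  model$mse <- fit$value
  model$stage <- "reduced_refined"
  model
}

#' Build a reduction profile for an ensemble
#'
#' Reduces each unprocessed model along the ascending reduction-threshold
#' grid (reduction continues from the previous threshold's topology, so
#' parameter counts are nonincreasing along the grid by construction) and
#' refines the parameters at every grid point. Records MSE and parameter
#' count per (model, threshold); the per-model baseline is the minimum
#' refined MSE across the grid, and the filter point is the largest
#' threshold whose refined MSE stays within the selection threshold of that
#' baseline.
#'
#' @param ensemble a `cfl_ensemble`, stage `"unprocessed"`.
#' @param dataset a `cfl_dataset`.
#' @param config a [cfl_refinement_config()].
#' @param optimizer a [cfl_optimizer_config()].
#' @param sim a [cfl_sim_config()].
#' @return object of class `cfl_reduction_profile`: list with `table`
#'   (data.frame model/threshold/mse/n_params), `models` (nested list of
#'   reduced-refined models), `baseline`, `filter_point` and `config`.
#' @export
build_reduction_profile <- function(ensemble, dataset,
                                    config = cfl_refinement_config(),
                                    optimizer = cfl_optimizer_config(),
                                    sim = cfl_sim_config()) {
  stopifnot(inherits(ensemble, "cfl_ensemble"))
  grid <- config$reduction_grid
  n_m <- length(ensemble$models)
  rows <- list()
  all_models <- vector("list", n_m)
  for (mi in seq_len(n_m)) {
    m0 <- ensemble$models[[mi]]
    ev <- .make_evaluator(ensemble$hypothesis, dataset, sim)
    base_mse <- ev(m0$type, m0$p1, m0$p2)
    cur <- m0
    per_thr <- vector("list", length(grid))
    for (ti in seq_along(grid)) {
      cur <- reduce_model(cur, dataset, grid[ti], sim, base_mse = base_mse)
      ref <- refine_parameters(cur, dataset, optimizer, sim)
      per_thr[[ti]] <- ref
      rows[[length(rows) + 1L]] <- data.frame(
        model = mi, threshold = grid[ti], mse = ref$mse,
        n_params = parameter_count(ref))
    }
    all_models[[mi]] <- per_thr
  }
  tab <- do.call(rbind, rows)
  baseline <- vapply(seq_len(n_m), function(mi) {
    min(tab$mse[tab$model == mi])
  }, 0)
  filter_point <- vapply(seq_len(n_m), function(mi) {
    sub <- tab[tab$model == mi, ]
    max(sub$threshold[sub$mse <= baseline[mi] + config$selection_threshold])
  }, 0)
  structure(list(table = tab, models = all_models, baseline = baseline,
                 filter_point = filter_point, config = config),
            class = "cfl_reduction_profile")
}

#' @export
print.cfl_reduction_profile <- function(x, ...) {
  cat(sprintf("cFL reduction profile: %d models x %d thresholds\n",
              length(x$baseline), length(x$config$reduction_grid)))
  cat(sprintf("  baseline MSE: %.4g - %.4g; filter points: %s\n",
              min(x$baseline), max(x$baseline),
              paste(format(sort(unique(x$filter_point))), collapse = ", ")))
  invisible(x)
}

#' Select the filtered family from a reduction profile
#'
#' For each unprocessed model, selects among its reduced-refined variants
#' the one with the fewest fitted parameters whose MSE stays within
#' `selection_threshold` of the model's baseline; ties go to the larger
#' reduction threshold.
#'
#' @param profile a `cfl_reduction_profile`.
#' @param selection_threshold overrides the profile's configured value when
#'   given.
#' @return a `cfl_ensemble`, stage `"filtered"`; each member carries the
#'   chosen reduction threshold in attribute `"threshold"`.
#' @export
select_filtered <- function(profile, selection_threshold = NULL) {
  stopifnot(inherits(profile, "cfl_reduction_profile"))
  sel <- if (is.null(selection_threshold)) profile$config$selection_threshold
         else selection_threshold
  grid <- profile$config$reduction_grid
  picks <- lapply(seq_along(profile$baseline), function(mi) {
    sub <- profile$table[profile$table$model == mi, ]
    ok <- which(sub$mse <= profile$baseline[mi] + sel)
    ok <- ok[order(sub$n_params[ok], -sub$threshold[ok])]
    ti <- ok[1]
    m <- profile$models[[mi]][[ti]]
    m$stage <- "filtered"
    attr(m, "threshold") <- sub$threshold[ti]
    m
  })
  hs <- picks[[1]]$hypothesis
  cfl_ensemble(hs, picks, stage = "filtered")
}

#' Selection-threshold trade-off table
#'
#' For each candidate selection threshold, the filtered family it would
#' induce is computed and its mean MSE and mean parameter count reported —
#' the curve used to choose a selection threshold by balancing fit against
#' model size.
#'
#' @param profile a `cfl_reduction_profile`.
#' @param candidates candidate selection thresholds; defaults to the
#'   reduction grid.
#' @return data.frame with columns `selection_threshold`, `mean_mse`,
#'   `mean_n_params`.
#' @export
threshold_tradeoff_table <- function(profile, candidates = NULL) {
  if (is.null(candidates)) candidates <- profile$config$reduction_grid
  rows <- lapply(candidates, function(s) {
    fam <- select_filtered(profile, s)
    data.frame(selection_threshold = s,
               mean_mse = mean(vapply(fam$models, `[[`, 0, "mse")),
               mean_n_params = mean(vapply(fam$models, parameter_count, 0L)))
  })
  do.call(rbind, rows)
}
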