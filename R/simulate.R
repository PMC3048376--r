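#' Simulation settings
#'
#' @param tol convergence tolerance on the maximum absolute node change per
#'   synchronous update (default 1e-4).
#' @param max_iter iteration cap; defaults to 10 times the node count when
#'   NULL.
#' @param operator_mode `"minmax"` (AND = min, OR = max), `"prodsum"`
#'   (AND = product, OR = sum capped at 1) or `"boolean"` (inputs
#'   thresholded at 0.5, logical AND/OR).
#' @return list of simulation settings.
#' @export
cfl_sim_config <- function(tol = 1e-4, max_iter = NULL,
                           operator_mode = c("minmax", "prodsum", "boolean")) {
  list(tol = tol, max_iter = max_iter,
       operator_mode = match.arg(operator_mode))
}

.mode_code <- function(mode) {
  match(mode, c("minmax", "prodsum", "boolean")) - 1L
}

#' Simulate a cFL model over experimental conditions
#'
#' Stimulus nodes are clamped to their design values and inhibited nodes
#' with flag 1 are clamped to 0; every other node starts at 0 (no basal
#' activity) and is updated synchronously — each node's value is the OR over
#' its active gates of the AND over the gate's transferred inputs — until
#' the maximum absolute change falls below `tol` or the iteration cap is
#' reached. Non-convergence is flagged, not an error: predictions of a
#' non-converged condition are reported as NA.
#'
#' @param model a `cfl_model`.
#' @param conditions a `cfl_dataset` (its design is used) or a list with
#'   data.frames `stimuli` and `inhibitors`.
#' @param sim a [cfl_sim_config()].
#' @return object of class `cfl_sim`: list with `x` (nodes x conditions
#'   matrix of activities, NA for non-converged conditions' free nodes),
#'   `converged` (logical per condition) and `iterations`.
#' @export
simulate_model <- function(model, conditions, sim = cfl_sim_config()) {
  stopifnot(inherits(model, "cfl_model"))
  hs <- model$hypothesis
  stim <- conditions$stimuli
  inhib <- conditions$inhibitors
  cl <- .clamp_matrix(hs$compiled$nodes, stim, inhib)
  .simulate_clamped(model, cl, sim)
}

# core wrapper over the C++ simulator given a prebuilt clamp matrix
.simulate_clamped <- function(model, clamp, sim) {
  hs <- model$hypothesis
  cp <- hs$compiled
  max_iter <- if (is.null(sim$max_iter)) 10L * cp$n_nodes else sim$max_iter
  res <- cfl_sim_cpp(cp$n_nodes, cp$gate_output, cp$gate_start, cp$gate_len,
                     cp$slot_input, cp$slot_sign,
                     model$type, model$p1, model$p2,
                     clamp, .mode_code(sim$operator_mode), sim$tol,
                     as.integer(max_iter))
  x <- res$x
  rownames(x) <- cp$nodes
  if (any(!res$converged)) {
    free <- is.na(clamp)
    for (j in which(!res$converged)) x[free[, j], j] <- NA_real_
  }
  structure(list(x = x, converged = res$converged,
                 iterations = res$iterations), class = "cfl_sim")
}

#' Evaluate a single gate (reference implementation)
#'
#' AND-combines the transferred values of a gate's inputs: minimum in
#' `minmax` mode, product in `prodsum` mode, logical AND on thresholded
#' inputs in `boolean` mode. A 1-input gate is the degenerate AND and
#' equals [apply_edge_tf()] of its input.
#'
#' @param inputs data.frame with columns `node` and `sign`.
#' @param specs list of `cfl_tf` specs, one per input (none may be NULL).
#' @param input_values named numeric vector of node activities.
#' @param operator_mode see [cfl_sim_config()].
#' @return gate output in \[0,1\].
#' @export
eval_gate <- function(inputs, specs, input_values,
                      operator_mode = c("minmax", "prodsum", "boolean")) {
  operator_mode <- match.arg(operator_mode)
  if (any(vapply(specs, is.null, TRUE))) {
    stop("inactive gate: a slot spec is absent", call. = FALSE)
  }
  v <- vapply(seq_len(nrow(inputs)), function(i) {
    xi <- input_values[[inputs$node[i]]]
    if (operator_mode == "boolean") {
      b <- as.numeric(xi >= 0.5)
      if (inputs$sign[i] > 0) b else 1 - b
    } else {
      apply_edge_tf(xi, specs[[i]], inputs$sign[i])
    }
  }, 0)
  if (operator_mode == "prodsum") prod(v) else min(v)
}

#' Evaluate a node from its active gates (reference implementation)
#'
#' OR-combines gate outputs: maximum in `minmax` mode, sum capped at 1 in
#' `prodsum` mode, logical OR in `boolean` mode. A node with no active
#' gates evaluates to 0.
#'
#' @param gate_values numeric vector of active-gate outputs.
#' @param operator_mode see [cfl_sim_config()].
#' @return node activity in \[0,1\].
#' @export
eval_node <- function(gate_values, operator_mode = c("minmax", "prodsum", "boolean")) {
  operator_mode <- match.arg(operator_mode)
  if (length(gate_values) == 0) return(0)
  if (operator_mode == "prodsum") min(1, sum(gate_values)) else max(gate_values)
}

#' Mean squared error between predictions and observations
#'
#' MSE = (1/N) * sum over signals i, stimulation conditions j and
#' inhibition conditions k of (x_pred_ijk - x_obs_ijk)^2, where N is the
#' number of non-missing observations. Observations whose prediction is
#' undefined (non-converged simulation) contribute a squared error of 1.0
#' and still count toward N, so oscillating models are penalized. The
#' computation can be restricted to a subset of signals and/or conditions
#' for finer error analysis (e.g. the MSE under a single stimulation).
#'
#' Both arguments may also be plain numeric vectors of equal length, in
#' which case the plain mean of squared differences over non-missing pairs
#' is returned.
#'
#' @param pred a `cfl_sim` result (or plain numeric vector).
#' @param dataset a `cfl_dataset` (or plain numeric vector).
#' @param signals optional character vector restricting to these measured
#'   nodes.
#' @param conditions optional integer vector restricting to these design
#'   rows.
#' @return nonnegative mean squared error.
#' @export
compute_mse <- function(pred, dataset, signals = NULL, conditions = NULL) {
  if (is.numeric(pred) && is.numeric(dataset)) {
    stopifnot(length(pred) == length(dataset))
    keep <- !is.na(dataset)
    err <- ifelse(is.na(pred[keep]), 1, (pred[keep] - dataset[keep])^2)
    if (!length(err)) stop("no observations: MSE undefined", call. = FALSE)
    return(mean(err))
  }
  stopifnot(inherits(dataset, "cfl_dataset"))
  x <- if (inherits(pred, "cfl_sim")) pred$x else pred
  obs <- dataset$obs
  sig <- if (is.null(signals)) colnames(obs) else signals
  cond <- if (is.null(conditions)) seq_len(nrow(obs)) else conditions
  o <- obs[cond, sig, drop = FALSE]
  p <- t(x[sig, cond, drop = FALSE])
  keep <- !is.na(o)
  if (!any(keep)) stop("no observations in the requested subset: MSE undefined",
                       call. = FALSE)
  err <- ifelse(is.na(p[keep]), 1, (p[keep] - o[keep])^2)
  mean(err)
}
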