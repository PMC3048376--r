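#' Gate frequencies across an ensemble
#'
#' The fraction of models in which each candidate gate is active — the
#' quantity displayed as edge shading in family-topology figures. Values
#' near 1 mark interactions required by the data; intermediate values mark
#' interactions the data cannot pin down.
#'
#' @param ensemble a `cfl_ensemble`.
#' @return data.frame with one row per candidate gate: `gate` (index),
#'   `output`, `inputs` (readable label) and `frequency` in \[0,1\].
#' @export
gate_frequencies <- function(ensemble) {
  stopifnot(inherits(ensemble, "cfl_ensemble"))
  hs <- ensemble$hypothesis
  counts <- integer(hs$w)
  for (m in ensemble$models) {
    if (!identical(m$hypothesis$slots$id, hs$slots$id)) {
      stop("ensemble members do not share one hypothesis space", call. = FALSE)
    }
    counts[active_gates(m)] <- counts[active_gates(m)] + 1L
  }
  data.frame(
    gate = seq_len(hs$w),
    output = vapply(hs$gates, `[[`, "", "output"),
    inputs = vapply(hs$gates, function(g) {
      paste0(ifelse(g$inputs$sign < 0, "!", ""), g$inputs$node,
             collapse = " AND ")
    }, ""),
    frequency = counts / length(ensemble$models))
}

#' Ensemble sensitivity of a gate
#'
#' Mean and standard deviation, over the models containing the gate, of the
#' gate's transfer-function sensitivity (1 - k for Hill, 0.5 * slope for
#' linear; 2-input gates average their two slots). The spread reflects the
#' various best-fit EC50s across the family.
#'
#' @param ensemble a `cfl_ensemble`.
#' @param gate gate index into the hypothesis space.
#' @return list with `mean`, `sd` and `n` (models containing the gate).
#' @export
ensemble_sensitivity <- function(ensemble, gate) {
  hs <- ensemble$hypothesis
  stopifnot(gate >= 1, gate <= hs$w)
  sens <- numeric(0)
  for (m in ensemble$models) {
    if (!gate %in% active_gates(m)) next
    sl <- hs$gates[[gate]]$slots
    sens <- c(sens, mean(vapply(sl, function(s) tf_sensitivity(slot_spec(m, s)), 0)))
  }
  if (!length(sens)) stop("gate is active in no ensemble member", call. = FALSE)
  list(mean = mean(sens), sd = if (length(sens) > 1) stats::sd(sens) else 0,
       n = length(sens))
}

#' Ensemble predictions with uncertainty
#'
#' Simulates every ensemble member on every condition and summarizes each
#' (node, condition) cell by the mean, standard deviation and coefficient
#' of variation (sd/mean) over members with converged predictions. The CV
#' flags cells where the family disagrees, i.e. predictions the data do not
#' constrain. CV is undefined (NA) where the mean is 0.
#'
#' @param ensemble a `cfl_ensemble`.
#' @param conditions a `cfl_dataset` or list with `stimuli`/`inhibitors`.
#' @param sim a [cfl_sim_config()].
#' @return object of class `cfl_prediction_summary`: list of matrices
#'   `mean`, `sd`, `cv` (nodes x conditions) and `n` (contributing models
#'   per cell).
#' @export
ensemble_predict <- function(ensemble, conditions, sim = cfl_sim_config()) {
  stopifnot(inherits(ensemble, "cfl_ensemble"))
  sims <- lapply(ensemble$models, simulate_model, conditions = conditions,
                 sim = sim)
  arr <- simplify2array(lapply(sims, `[[`, "x"))  # nodes x cond x models
  mean_m <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  sd_m <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 1) NA_real_ else if (length(v) == 1) 0 else stats::sd(v)
  })
  n_m <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  cv <- sd_m / mean_m
  cv[!is.na(mean_m) & mean_m == 0] <- NA_real_
  structure(list(mean = mean_m, sd = sd_m, cv = cv, n = n_m),
            class = "cfl_prediction_summary")
}

#' @export
print.cfl_prediction_summary <- function(x, ...) {
  cat(sprintf("cFL ensemble prediction summary: %d nodes x %d conditions\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Response surface of one node over an input grid
#'
#' Evaluates only the output node's gates (no upstream simulation) with the
#' named inputs clamped to every combination of the supplied grid values,
#' for each ensemble member, and summarizes mean and sd surfaces. A 21 x 21
#' two-input grid yields 441 evaluation points. Every input of every active
#' gate of the output must appear in `input_grid`.
#'
#' @param ensemble a `cfl_ensemble`.
#' @param output the node whose response is evaluated.
#' @param input_grid named list mapping input node -> vector of values in
#'   \[0,1\].
#' @param operator_mode see [cfl_sim_config()].
#' @return list with `grid` (data.frame of input combinations), `mean`,
#'   `sd` (vectors over grid rows) and `per_model` (matrix grid x models).
#' @export
node_response_surface <- function(ensemble, output, input_grid,
                                  operator_mode = "minmax") {
  hs <- ensemble$hypothesis
  out_gates <- which(vapply(hs$gates, function(g) g$output == output, TRUE))
  if (!length(out_gates)) stop("node '", output, "' has no candidate gates",
                               call. = FALSE)
  gate_inputs <- unique(unlist(lapply(hs$gates[out_gates],
                                      function(g) g$inputs$node)))
  unknown <- setdiff(names(input_grid), gate_inputs)
  if (length(unknown)) {
    stop("grid input(s) not connected to '", output, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(input_grid, KEEP.OUT.ATTRS = FALSE)
  per_model <- matrix(NA_real_, nrow(grid), length(ensemble$models))
  for (mi in seq_along(ensemble$models)) {
    m <- ensemble$models[[mi]]
    act <- intersect(active_gates(m), out_gates)
    need <- unique(unlist(lapply(hs$gates[act], function(g) g$inputs$node)))
    miss <- setdiff(need, names(input_grid))
    if (length(miss)) {
      stop("active gate input(s) missing from the grid: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (r in seq_len(nrow(grid))) {
      vals <- as.list(grid[r, , drop = FALSE])
      gv <- vapply(act, function(gi) {
        g <- hs$gates[[gi]]
        eval_gate(g$inputs, lapply(g$slots, function(s) slot_spec(m, s)),
                  vals, operator_mode)
      }, 0)
      per_model[r, mi] <- eval_node(gv, operator_mode)
    }
  }
  list(grid = grid,
       mean = rowMeans(per_model),
       sd = apply(per_model, 1, function(v) if (length(v) > 1) stats::sd(v) else 0),
       per_model = per_model)
}

#' Topology distance between two model families
#'
#' Each family is summarized by its consensus edges: gates active in more
#' than `frequency_cut` of the models, projected to signed edges and
#' further compressed so only interactions between designated (stimulus,
#' inhibited, measured) nodes remain. The distance is the size of the
#' symmetric difference of the two consensus edge sets divided by the size
#' of their union (0 = identical consensus topology).
#'
#' @param ensemble_a,ensemble_b `cfl_ensemble`s.
#' @param frequency_cut consensus inclusion threshold (default 0.25).
#' @return fraction of differing consensus edges in \[0,1\].
#' @export
topology_distance <- function(ensemble_a, ensemble_b, frequency_cut = 0.25) {
  ea <- .consensus_edges(ensemble_a, frequency_cut)
  eb <- .consensus_edges(ensemble_b, frequency_cut)
  da <- pkn_designated(ensemble_a$hypothesis$pkn)
  db <- pkn_designated(ensemble_b$hypothesis$pkn)
  if (!length(intersect(da, db))) {
    stop("the two families share no designated nodes", call. = FALSE)
  }
  u <- union(ea, eb)
  if (!length(u)) return(0)
  length(setdiff(u, intersect(ea, eb))) / length(u)
}

# consensus gates -> designated-node edge labels "source:sign:target"
.consensus_edges <- function(ensemble, frequency_cut) {
  hs <- ensemble$hypothesis
  freq <- gate_frequencies(ensemble)
  keep <- which(freq$frequency > frequency_cut |
                  (frequency_cut >= 1 & freq$frequency >= 1))
  if (!length(keep)) return(character())
  rows <- do.call(rbind, lapply(hs$gates[keep], function(g) {
    data.frame(source = g$inputs$node, sign = g$inputs$sign,
               target = g$output, stringsAsFactors = FALSE)
  }))
  pkn <- hs$pkn
  proj <- compress(cfl_pkn(unique(rows), stimuli = pkn$stimuli,
                           inhibited = pkn$inhibited,
                           measured = pkn$measured))
  if (!nrow(proj$edges)) return(character())
  sprintf("%s:%d:%s", proj$edges$source, proj$edges$sign, proj$edges$target)
}

#' Save or load a model ensemble archive
#'
#' The archive is a JSON document holding the hypothesis-space definition
#' (PKN edges, roles and expansion mode) plus, per model, the stage, MSE,
#' seed and the slot assignments keyed by stable identifiers of the form
#' `"<output>|<gate-index>|<input>"`. Continuous parameter values are
#' written at full precision. Loading rebuilds the hypothesis space and
#' fails with an integrity error if the archive references a slot that the
#' rebuilt space does not contain.
#'
#' @param ensemble a `cfl_ensemble`.
#' @param path archive path.
#' @return `load_ensemble` returns the restored `cfl_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cfl_ensemble"))
  hs <- ensemble$hypothesis
  pkn <- hs$pkn
  doc <- list(
    format = "cflnet-ensemble/1",
    pkn = list(edges = pkn$edges, stimuli = pkn$stimuli,
               inhibited = pkn$inhibited, measured = pkn$measured,
               nodes = pkn$nodes),
    mode = hs$mode,
    stage = ensemble$stage,
    models = lapply(ensemble$models, function(m) {
      assign <- list()
      for (i in seq_len(hs$h)) {
        id <- hs$slots$id[i]
        assign[[id]] <- if (m$type[i] == 0L) "absent"
          else if (m$type[i] == 1L) list(family = "linear", slope = m$p1[i])
          else list(family = "hill", n = m$p1[i], k = m$p2[i])
      }
      list(stage = m$stage, mse = m$mse, seed = m$seed, slots = assign)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  doc <- jsonlite::read_json(path)
  p <- doc$pkn
  edges <- if (length(p$edges)) {
    do.call(rbind, lapply(p$edges, function(e) {
      data.frame(source = e$source, sign = e$sign, target = e$target,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(source = character(), sign = integer(),
                    target = character())
  pkn <- cfl_pkn(edges, nodes = unlist(p$nodes),
                 stimuli = unlist(p$stimuli) %||% character(),
                 inhibited = unlist(p$inhibited) %||% character(),
                 measured = unlist(p$measured) %||% character())
  hs <- expand_pkn(pkn, doc$mode)
  id_to_slot <- stats::setNames(seq_len(hs$h), hs$slots$id)
  models <- lapply(doc$models, function(md) {
    type <- integer(hs$h); p1 <- numeric(hs$h); p2 <- numeric(hs$h)
    ids <- names(md$slots)
    bad <- setdiff(ids, hs$slots$id)
    if (length(bad)) {
      stop("archive references unknown slot id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (id in ids) {
      s <- id_to_slot[[id]]
      a <- md$slots[[id]]
      if (identical(a, "absent")) next
      if (a$family == "linear") {
        type[s] <- 1L; p1[s] <- a$slope
      } else {
        type[s] <- 2L; p1[s] <- a$n; p2[s] <- a$k
      }
    }
    new_cfl_model(hs, type = type, p1 = p1, p2 = p2, stage = md$stage,
                  mse = md$mse %||% NA_real_, seed = md$seed %||% NA_integer_)
  })
  cfl_ensemble(hs, models, stage = doc$stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
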