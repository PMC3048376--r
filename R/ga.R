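#' Genetic-algorithm settings
#'
#' Defaults are standard small-alphabet GA settings sized to hypothesis
#' spaces with tens to a couple of hundred slots: generational GA with
#' elitism, tournament selection, uniform crossover and per-locus mutation.
#'
#' @param population_size number of genomes per generation (>= 2).
#' @param max_generations hard generation cap.
#' @param stall_generations stop after this many generations without
#'   best-fitness improvement.
#' @param elite_count genomes copied unchanged to the next generation.
#' @param tournament_size selection tournament size.
#' @param mutation_rate per-locus mutation probability; `NULL` means `1/h`.
#' @param seed integer seed; every run is a pure function of it.
#' @return list of GA settings.
#' @export
cfl_ga_config <- function(population_size = 50L, max_generations = 500L,
                          stall_generations = 100L, elite_count = 2L,
                          tournament_size = 3L, mutation_rate = NULL,
                          seed = 1L) {
  stopifnot(population_size >= 2, elite_count < population_size,
            is.null(mutation_rate) || (mutation_rate > 0 && mutation_rate < 1))
  list(population_size = as.integer(population_size),
       max_generations = as.integer(max_generations),
       stall_generations = as.integer(stall_generations),
       elite_count = as.integer(elite_count),
       tournament_size = as.integer(tournament_size),
       mutation_rate = mutation_rate, seed = as.integer(seed))
}

# Precompiles everything fitness evaluation needs for one (hs, dataset)
# pair; returns a closure mapping slot-parameter arrays to MSE. Avoids
# rebuilding clamp/observation matrices inside the GA loop.
.make_evaluator <- function(hs, dataset, sim = cfl_sim_config()) {
  cp <- hs$compiled
  clamp <- .clamp_matrix(cp$nodes, dataset$stimuli, dataset$inhibitors)
  obs <- dataset$obs
  sig_idx <- match(colnames(obs), cp$nodes)
  keep <- !is.na(obs)
  if (!any(keep)) stop("dataset has no observations", call. = FALSE)
  mode <- .mode_code(sim$operator_mode)
  max_iter <- if (is.null(sim$max_iter)) 10L * cp$n_nodes else as.integer(sim$max_iter)
  free <- is.na(clamp)
  function(type, p1, p2) {
    res <- cfl_sim_cpp(cp$n_nodes, cp$gate_output, cp$gate_start, cp$gate_len,
                       cp$slot_input, cp$slot_sign, type, p1, p2,
                       clamp, mode, sim$tol, max_iter)
    x <- res$x
    if (any(!res$converged)) {
      for (j in which(!res$converged)) x[free[, j], j] <- NA_real_
    }
    p <- t(x[sig_idx, , drop = FALSE])
    err <- ifelse(is.na(p[keep]), 1, (p[keep] - obs[keep])^2)
    mean(err)
  }
}

#' Fitness of a genome
#'
#' Decodes the genome and returns the MSE of the decoded model's
#' simulation against the dataset (lower is better).
#'
#' @param genome integer allele vector (see [decode()]).
#' @param hs a `cfl_hypothesis`.
#' @param dataset a `cfl_dataset`.
#' @param sim a [cfl_sim_config()].
#' @return nonnegative MSE.
#' @export
fitness <- function(genome, hs, dataset, sim = cfl_sim_config()) {
  m <- decode(genome, hs)
  .make_evaluator(hs, dataset, sim)(m$type, m$p1, m$p2)
}

#' Train one cFL model with the discrete genetic algorithm
#'
#' Minimizes the MSE over the discrete genome space (one allele in 0..7 per
#' slot). Elitism guarantees a monotone nonincreasing best-so-far fitness
#' trace; identical seeds give bit-identical results.
#'
#' @param hs a `cfl_hypothesis`.
#' @param dataset a `cfl_dataset`.
#' @param ga a [cfl_ga_config()].
#' @param sim a [cfl_sim_config()].
#' @return the best model found, a `cfl_model` with stage `"discrete"`,
#'   `mse` set and the seed recorded; the per-generation best-fitness trace
#'   is attached as attribute `"trace"`.
#' @export
run_ga <- function(hs, dataset, ga = cfl_ga_config(), sim = cfl_sim_config()) {
  stopifnot(inherits(hs, "cfl_hypothesis"))
  h <- hs$h
  eval_mse <- .make_evaluator(hs, dataset, sim)
  mut_rate <- if (is.null(ga$mutation_rate)) 1 / h else ga$mutation_rate
  pop_n <- ga$population_size
  lin <- hs$slots$library == "linear"
  lin_lib <- seq(0.2, 0.8, by = 0.1)
  hill_n <- c(1.01, rep(3, 6))
  hill_k <- c(68.5098, seq(0.2, 0.7, by = 0.1))
  genome_mse <- function(g) {
    on <- g > 0L
    type <- integer(h); p1 <- numeric(h); p2 <- numeric(h)
    type[on & lin] <- 1L; type[on & !lin] <- 2L
    sel <- which(on & lin); p1[sel] <- lin_lib[g[sel]]
    sel <- which(on & !lin); p1[sel] <- hill_n[g[sel]]; p2[sel] <- hill_k[g[sel]]
    eval_mse(type, p1, p2)
  }

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(ga$seed)

  pop <- lapply(seq_len(pop_n), function(i) sample(0:7, h, replace = TRUE))
  fit <- vapply(pop, genome_mse, 0)
  best_fit <- min(fit)
  best_genome <- pop[[which.min(fit)]]
  trace <- best_fit
  stall <- 0L
  for (gen in seq_len(ga$max_generations)) {
    ord <- order(fit)
    new_pop <- pop[ord[seq_len(ga$elite_count)]]
    while (length(new_pop) < pop_n) {
      pick <- function() {
        cand <- sample.int(pop_n, ga$tournament_size, replace = TRUE)
        pop[[cand[which.min(fit[cand])]]]
      }
      a <- pick(); b <- pick()
      mask <- stats::runif(h) < 0.5
      child <- ifelse(mask, a, b)
      mut <- which(stats::runif(h) < mut_rate)
      if (length(mut)) {
        child[mut] <- vapply(child[mut], function(al) {
          sample(setdiff(0:7, al), 1L)
        }, 0L)
      }
      new_pop[[length(new_pop) + 1L]] <- as.integer(child)
    }
    pop <- new_pop
    fit <- vapply(pop, genome_mse, 0)
    if (min(fit) < best_fit - 1e-12) {
      best_fit <- min(fit)
      best_genome <- pop[[which.min(fit)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, best_fit)
    if (stall >= ga$stall_generations) break
  }
  model <- decode(best_genome, hs)
  model$mse <- best_fit
  model$seed <- ga$seed
  attr(model, "trace") <- trace
  model
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Remove logically redundant gates
#'
#' An active AND gate is redundant when another active gate for the same
#' output has an input set (as node/sign pairs) that is a subset of the AND
#' gate's: under OR-of-gates semantics the subsuming gate dominates (e.g.
#' in "(B AND C) OR B activate D" the AND gate never decides D). Redundant
#' gates are deactivated to a fixed point and the MSE is recomputed.
#'
#' @param model a `cfl_model`, stage `"discrete"`.
#' @param dataset a `cfl_dataset`, used to recompute the MSE.
#' @param sim a [cfl_sim_config()].
#' @return the model with stage `"unprocessed"`.
#' @export
remove_redundant_gates <- function(model, dataset, sim = cfl_sim_config()) {
  hs <- model$hypothesis
  key <- function(g) paste(sprintf("%s:%d", g$inputs$node, g$inputs$sign))
  repeat {
    act <- active_gates(model)
    drop <- integer()
    for (gi in act) {
      g <- hs$gates[[gi]]
      if (nrow(g$inputs) < 2) next
      for (gj in act) {
        if (gj == gi) next
        gk <- hs$gates[[gj]]
        if (gk$output != g$output) next
        if (all(key(gk) %in% key(g)) && nrow(gk$inputs) < nrow(g$inputs)) {
          drop <- c(drop, gi)
          break
        }
      }
    }
    if (!length(drop)) break
    model <- deactivate_gates(model, unique(drop))
  }
  model$stage <- "unprocessed"
  model$mse <- .make_evaluator(hs, dataset, sim)(model$type, model$p1, model$p2)
  model
}

#' Train a family of cFL models
#'
#' Runs the genetic algorithm `n_runs` times with distinct derived seeds,
#' removes redundant gates from each result, and optionally drops poorly
#' fitting runs. Because the GA is stochastic, independent runs return
#' models with (slightly) different topologies; the family as a whole is
#' the object of the downstream analysis.
#'
#' @param hs a `cfl_hypothesis`.
#' @param dataset a `cfl_dataset`.
#' @param ga a [cfl_ga_config()]; its `seed` is the master seed from which
#'   per-run seeds are derived.
#' @param n_runs number of independent runs.
#' @param keep_rule `"all"` keeps every run; `"within_sd"` keeps runs with
#'   MSE <= mean + 1 sd of the family's MSEs; `"within_margin"` keeps runs
#'   with MSE <= best * (1 + margin).
#' @param margin relative margin for `"within_margin"`.
#' @param sim a [cfl_sim_config()].
#' @return object of class `cfl_ensemble`, stage `"unprocessed"`.
#' @export
train_family <- function(hs, dataset, ga = cfl_ga_config(), n_runs = 20L,
                         keep_rule = c("all", "within_sd", "within_margin"),
                         margin = 0.1, sim = cfl_sim_config()) {
  keep_rule <- match.arg(keep_rule)
  stopifnot(n_runs >= 1)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(ga$seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  models <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- ga
    cfg$seed <- run_seeds[i]
    m <- run_ga(hs, dataset, cfg, sim)
    models[[i]] <- remove_redundant_gates(m, dataset, sim)
  }
  mses <- vapply(models, `[[`, 0, "mse")
  keep <- switch(keep_rule,
    all = rep(TRUE, n_runs),
    within_sd = mses <= mean(mses) + stats::sd(mses),
    within_margin = mses <= min(mses) * (1 + margin))
  if (!any(keep)) stop("keep rule eliminated every model", call. = FALSE)
  cfl_ensemble(hs, models[keep], stage = "unprocessed")
}

#' Model ensemble
#'
#' A family of cFL models over one shared hypothesis space, tagged with the
#' workflow stage its members are at.
#'
#' @param hs the shared `cfl_hypothesis`.
#' @param models list of `cfl_model`s.
#' @param stage workflow stage of the members.
#' @return object of class `cfl_ensemble`.
#' @export
cfl_ensemble <- function(hs, models, stage = "unprocessed") {
  stopifnot(inherits(hs, "cfl_hypothesis"), length(models) >= 1)
  structure(list(hypothesis = hs, models = models, stage = stage),
            class = "cfl_ensemble")
}

#' @export
print.cfl_ensemble <- function(x, ...) {
  mses <- vapply(x$models, `[[`, 0, "mse")
  cat(sprintf("cFL model ensemble: %d models (stage %s), MSE %.4g - %.4g (median %.4g)\n",
              length(x$models), x$stage, min(mses), max(mses),
              stats::median(mses)))
  invisible(x)
}

#' @export
length.cfl_ensemble <- function(x) length(x$models)
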