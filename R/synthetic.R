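#' Generate a random signed acyclic PKN with experimental roles
#'
#' Produces a random signed DAG in which the stimuli are sources (no
#' incoming edges, at least one outgoing edge), every non-stimulus node has
#' at least one parent (so every node is reachable from some stimulus), and
#' roles are assigned to satisfy the requested counts. Used to exercise the
#' whole workflow without any external network.
#'
#' @param node_count total nodes.
#' @param stimulus_count,inhibitor_count,measured_count role counts; their
#'   sum (stimuli are disjoint from the other two; inhibited and measured
#'   may overlap only if forced) must fit in `node_count`.
#' @param extra_edge_prob probability of each additional feed-forward edge
#'   beyond the spanning parent (edge density control).
#' @param inhibitory_fraction probability that a non-spanning edge is
#'   inhibitory.
#' @param seed integer seed; identical seeds give identical networks.
#' @return a `cfl_pkn` with roles set.
#' @export
make_toy_pkn <- function(node_count = 15L, stimulus_count = 2L,
                         inhibitor_count = 2L, measured_count = 6L,
                         extra_edge_prob = 0.12,
                         inhibitory_fraction = 0.15, seed = 1L) {
  if (stimulus_count + inhibitor_count + measured_count > node_count) {
    stop("role counts exceed node count: generation impossible", call. = FALSE)
  }
  if (stimulus_count < 1 || node_count < 2) {
    stop("need at least one stimulus and two nodes", call. = FALSE)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(node_count))
  stim <- nodes[seq_len(stimulus_count)]
  rest <- setdiff(nodes, stim)
  edges <- list()
  # topological order = node order; every non-stimulus node gets >= 1 parent
  for (i in (stimulus_count + 1L):node_count) {
    parent <- nodes[sample.int(i - 1L, 1L)]
    edges[[length(edges) + 1L]] <- data.frame(
      source = parent, sign = 1L, target = nodes[i],
      stringsAsFactors = FALSE)
    extra <- which(stats::runif(i - 1L) < extra_edge_prob)
    for (j in setdiff(extra, match(parent, nodes))) {
      sgn <- if (stats::runif(1) < inhibitory_fraction) -1L else 1L
      edges[[length(edges) + 1L]] <- data.frame(
        source = nodes[j], sign = sgn, target = nodes[i],
        stringsAsFactors = FALSE)
    }
  }
  edges <- unique(do.call(rbind, edges))
  # each stimulus needs an outgoing edge; guaranteed for node 1, force others
  for (s in stim) {
    if (!s %in% edges$source) {
      tgt <- rest[sample.int(length(rest), 1L)]
      edges <- rbind(edges, data.frame(source = s, sign = 1L, target = tgt,
                                       stringsAsFactors = FALSE))
    }
  }
  inhibited <- if (inhibitor_count > 0) {
    sample(rest, inhibitor_count)
  } else character()
  measured <- sample(setdiff(rest, inhibited), measured_count)
  cfl_pkn(edges, nodes = nodes, stimuli = stim, inhibited = inhibited,
          measured = measured)
}

#' Hand-authored 15-node toy signaling example
#'
#' A synthetic growth-factor/cytokine signaling network (15 species: 2
#' stimuli, 2 inhibited kinases, 6 measured phosphoproteins, 5
#' intermediates) together with a ground-truth cFL model and a noise-free
#' full-factorial in-silico dataset. It is built so that one stimulus
#' (TGFa) only partially activates the PI3K branch — downstream activities
#' near 0.4 and 0.2 — which is exactly the regime where Boolean logic
#' cannot represent the data but constrained fuzzy logic can. The network
#' is inspired by classic toy examples in the logic-modeling literature but
#' is synthetic: it transcribes no published network.
#'
#' @param expand_mode expansion mode for the returned hypothesis space.
#' @param sim a [cfl_sim_config()] used to simulate the dataset.
#' @return list with elements `pkn` (15-node network), `compressed`,
#'   `hypothesis`, `true_model` (ground truth on the compressed space),
#'   `dataset` (16-condition noise-free data) and `design`.
#' @export
toy_signaling_example <- function(expand_mode = "inhibitory_only",
                                  sim = cfl_sim_config()) {
  e <- function(s, sgn, t) data.frame(source = s, sign = sgn, target = t,
                                      stringsAsFactors = FALSE)
  edges <- rbind(
    e("TGFa", 1L, "RAS"),    e("RAS", 1L, "MEK"),    e("MEK", 1L, "ERK"),
    e("TGFa", 1L, "PI3K"),   e("PI3K", 1L, "Akt"),   e("PI3K", 1L, "MKK4"),
    e("TNFa", 1L, "TRAF2"),  e("TRAF2", 1L, "MAP3K1"),
    e("MAP3K1", 1L, "MKK4"), e("MKK4", 1L, "JNK"),
    e("MAP3K1", 1L, "IKK"),  e("IKK", 1L, "NFkB"),
    e("MAP3K1", 1L, "p38"),  e("p38", 1L, "Hsp27"),
    e("Akt", -1L, "MEK"))    # spurious prior edge, absent from the truth
  pkn <- cfl_pkn(edges,
                 stimuli = c("TGFa", "TNFa"),
                 inhibited = c("PI3K", "MEK"),
                 measured = c("Akt", "JNK", "ERK", "p38", "NFkB", "Hsp27"))
  comp <- compress(pkn)
  hs <- expand_pkn(comp, expand_mode)
  truth <- list(  # output -> single generating gate with its transfer spec
    list(out = "PI3K", node = "TGFa", sign = 1L, tf = tf_linear(0.4)),
    list(out = "Akt",  node = "PI3K", sign = 1L, tf = tf_hill(3, 0.5)),
    list(out = "JNK",  node = "PI3K", sign = 1L, tf = tf_hill(3, 0.7)),
    list(out = "JNK",  node = "TNFa", sign = 1L, tf = tf_linear(0.8)),
    list(out = "MEK",  node = "TGFa", sign = 1L, tf = tf_linear(0.7)),
    list(out = "ERK",  node = "MEK",  sign = 1L, tf = tf_hill(3, 0.4)),
    list(out = "p38",  node = "TNFa", sign = 1L, tf = tf_linear(0.6)),
    list(out = "Hsp27", node = "p38", sign = 1L, tf = tf_hill(3, 0.3)),
    list(out = "NFkB", node = "TNFa", sign = 1L, tf = tf_linear(0.8)))
  type <- integer(hs$h); p1 <- numeric(hs$h); p2 <- numeric(hs$h)
  for (tr in truth) {
    s <- which(hs$slots$output == tr$out & hs$slots$input == tr$node &
                 hs$slots$sign == tr$sign &
                 hs$slots$gate %in% which(vapply(hs$gates, function(g)
                   nrow(g$inputs) == 1, TRUE)))
    stopifnot(length(s) == 1)
    if (tr$tf$family == "linear") {
      type[s] <- 1L; p1[s] <- tr$tf$slope
    } else {
      type[s] <- 2L; p1[s] <- tr$tf$n; p2[s] <- tr$tf$k
    }
  }
  true_model <- new_cfl_model(hs, type = type, p1 = p1, p2 = p2,
                              stage = "discrete")
  design <- full_factorial_design(c("TGFa", "TNFa"), c("PI3K", "MEK"))
  dataset <- simulate_dataset(true_model, design, noise_sd = 0, seed = 1L,
                              sim = sim)
  list(pkn = pkn, compressed = comp, hypothesis = hs,
       true_model = true_model, dataset = dataset, design = design)
}

#' Full-factorial experimental design
#'
#' All combinations of the given stimulus levels across stimuli and on/off
#' states across inhibitors: 2 stimuli at levels \{0,1\} with 2 inhibitors
#' give 16 conditions.
#'
#' @param stimuli character vector of stimulus node names.
#' @param inhibitors character vector of inhibited node names.
#' @param stim_levels levels applied to every stimulus (default c(0, 1)).
#' @return list with data.frames `stimuli` and `inhibitors`.
#' @export
full_factorial_design <- function(stimuli, inhibitors = character(),
                                  stim_levels = c(0, 1)) {
  cols <- c(lapply(stimuli, function(s) stim_levels),
            lapply(inhibitors, function(i) c(0, 1)))
  names(cols) <- c(stimuli, inhibitors)
  grid <- expand.grid(cols, KEEP.OUT.ATTRS = FALSE)
  list(stimuli = grid[, stimuli, drop = FALSE],
       inhibitors = grid[, inhibitors, drop = FALSE])
}

#' Ground-truth model for a hypothesis space
#'
#' Randomly selects one candidate gate per output (1-input gates preferred)
#' and assigns transfer functions: on-grid draws from the discrete
#' libraries; `off_grid = TRUE` draws Hill k uniformly in \[0.15, 0.75\]
#' (n = 3) and linear slopes uniformly in \[0.2, 0.8\], off the discrete
#' grid, to exercise continuous refinement.
#'
#' @param hs a `cfl_hypothesis` (or a `cfl_pkn`, expanded with defaults).
#' @param seed integer seed.
#' @param off_grid draw continuous off-grid parameters.
#' @return a `cfl_model`; for on-grid models `$genome` decodes back to the
#'   identical model.
#' @export
make_ground_truth_model <- function(hs, seed = 1L, off_grid = FALSE) {
  if (inherits(hs, "cfl_pkn")) hs <- expand_pkn(hs)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  outputs <- unique(vapply(hs$gates, `[[`, "", "output"))
  genome <- integer(hs$h)
  type <- integer(hs$h); p1 <- numeric(hs$h); p2 <- numeric(hs$h)
  for (out in outputs) {
    cand <- which(vapply(hs$gates, function(g) g$output == out, TRUE))
    arity <- vapply(hs$gates[cand], function(g) nrow(g$inputs), 0L)
    pool <- if (any(arity == 1) && stats::runif(1) < 0.8) {
      cand[arity == 1]
    } else cand
    gi <- pool[sample.int(length(pool), 1L)]
    for (s in hs$gates[[gi]]$slots) {
      if (hs$slots$library[s] == "linear") {
        if (off_grid) {
          type[s] <- 1L
          p1[s] <- stats::runif(1, 0.2, 0.8)
        } else {
          genome[s] <- sample.int(7L, 1L)
          type[s] <- 1L
          p1[s] <- seq(0.2, 0.8, by = 0.1)[genome[s]]
        }
      } else {
        if (off_grid) {
          type[s] <- 2L
          p1[s] <- 3
          p2[s] <- stats::runif(1, 0.15, 0.75)
        } else {
          genome[s] <- sample.int(6L, 1L) + 1L  # sigmoid members only
          type[s] <- 2L
          p1[s] <- 3
          p2[s] <- seq(0.2, 0.7, by = 0.1)[genome[s] - 1L]
        }
      }
    }
  }
  m <- new_cfl_model(hs, genome = if (off_grid) NULL else genome,
                     type = type, p1 = p1, p2 = p2, stage = "discrete",
                     seed = seed)
  m
}

#' Simulate an in-silico dataset from a ground-truth model
#'
#' Simulates the model on every design condition and records the measured
#' nodes' activities, optionally corrupted by truncated Gaussian noise
#' (a N(0, noise_sd) perturbation with the result clipped back to
#' \[0,1\]). Non-convergence on any condition is an error naming the
#' condition: ground-truth data must be well defined.
#'
#' @param model a `cfl_model`.
#' @param design list with data.frames `stimuli` and `inhibitors` (see
#'   [full_factorial_design()]).
#' @param noise_sd truncated-Gaussian noise standard deviation (default 0,
#'   noise-free).
#' @param seed noise seed.
#' @param measured measured node names; defaults to the PKN's measured set.
#' @param sim a [cfl_sim_config()].
#' @return a `cfl_dataset`.
#' @export
simulate_dataset <- function(model, design, noise_sd = 0, seed = 1L,
                             measured = NULL, sim = cfl_sim_config()) {
  stopifnot(inherits(model, "cfl_model"))
  if (is.null(measured)) measured <- model$hypothesis$pkn$measured
  res <- simulate_model(model, design, sim)
  if (any(!res$converged)) {
    stop("ground-truth simulation did not converge on condition(s) ",
         paste(which(!res$converged), collapse = ", "), call. = FALSE)
  }
  obs <- t(res$x[measured, , drop = FALSE])
  if (noise_sd > 0) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed))
    set.seed(seed)
    obs <- obs + stats::rnorm(length(obs), 0, noise_sd)
    obs <- pmin(pmax(obs, 0), 1)
  }
  cfl_dataset(design$stimuli, design$inhibitors, obs)
}

#' Randomize a dataset by pairwise exchange of values
#'
#' Applies a seeded random sequence of pairwise swaps to the non-missing
#' observed values: positions (and missingness) are preserved, values are
#' permuted. The design is untouched. This destroys the association
#' between conditions and responses while keeping the value distribution
#' identical — the null control for training significance.
#'
#' @param dataset a `cfl_dataset`.
#' @param seed integer seed.
#' @param n_swaps number of pairwise exchanges (default 10x the cell
#'   count).
#' @return the randomized `cfl_dataset`.
#' @export
randomize_data <- function(dataset, seed = 1L, n_swaps = NULL) {
  cells <- which(!is.na(dataset$obs))
  if (length(cells) < 2) {
    warning("fewer than 2 observed cells: nothing to randomize")
    return(dataset)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  if (is.null(n_swaps)) n_swaps <- 10L * length(cells)
  obs <- dataset$obs
  for (i in seq_len(n_swaps)) {
    ij <- sample(cells, 2L)
    obs[ij] <- obs[rev(ij)]
  }
  cfl_dataset(dataset$stimuli, dataset$inhibitors, obs, da = dataset$da)
}

#' Randomize a PKN
#'
#' Network null controls: `swap_heads` randomly permutes edge sources
#' across edges (each interaction's input is exchanged with another's, the
#' sign traveling with the moved source); `swap_tails` permutes targets the
#' same way; `swap_inputs` repeatedly exchanges the complete incoming edge
#' sets of two randomly chosen output nodes; `fully_random` draws a fresh
#' network with the same node and edge counts in which every node touches
#' at least one edge and stimuli have no incoming and at least one outgoing
#' edge.
#'
#' @param pkn a `cfl_pkn` with >= 2 edges.
#' @param method randomization scheme.
#' @param seed integer seed.
#' @param n_exchanges number of output-pair exchanges for `swap_inputs`.
#' @param max_tries retry bound for `fully_random`.
#' @return the randomized `cfl_pkn` (roles preserved).
#' @export
randomize_network <- function(pkn, method = c("swap_heads", "swap_tails",
                                              "swap_inputs", "fully_random"),
                              seed = 1L, n_exchanges = NULL,
                              max_tries = 100L) {
  method <- match.arg(method)
  stopifnot(inherits(pkn, "cfl_pkn"))
  edges <- pkn$edges
  if (nrow(edges) < 2) stop("need at least 2 edges to randomize", call. = FALSE)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  remake <- function(ed) {
    cfl_pkn(unique(ed), nodes = pkn$nodes, stimuli = pkn$stimuli,
            inhibited = pkn$inhibited, measured = pkn$measured)
  }
  # permutation of edge endpoints that creates no self-loop and no
  # duplicate record (so edge and endpoint multisets are preserved exactly)
  try_perm <- function(apply_perm) {
    for (i in seq_len(max_tries)) {
      ed <- apply_perm(sample.int(nrow(edges)))
      if (all(ed$source != ed$target) && !anyDuplicated(ed)) return(ed)
    }
    stop("could not find a self-loop-free endpoint permutation in ",
         max_tries, " tries", call. = FALSE)
  }
  if (method == "swap_heads") {
    return(remake(try_perm(function(perm) {
      ed <- edges
      ed$source <- edges$source[perm]
      ed$sign <- edges$sign[perm]
      ed
    })))
  }
  if (method == "swap_tails") {
    return(remake(try_perm(function(perm) {
      ed <- edges
      ed$target <- edges$target[perm]
      ed$sign <- edges$sign[perm]
      ed
    })))
  }
  if (method == "swap_inputs") {
    outs <- unique(edges$target)
    if (is.null(n_exchanges)) n_exchanges <- length(outs)
    for (i in seq_len(n_exchanges)) {
      ab <- sample(outs, 2L)
      ia <- edges$target == ab[1]
      ib <- edges$target == ab[2]
      cand <- edges
      cand$target[ia] <- ab[2]
      cand$target[ib] <- ab[1]
      if (all(cand$source != cand$target) && !anyDuplicated(cand)) {
        edges <- cand
      }
    }
    return(remake(edges))
  }
  # fully_random: construct rather than reject — first an edge out of every
  # stimulus, then an incoming edge for every remaining non-stimulus node,
  # then random fill to the original edge count
  n_edges <- nrow(edges)
  nodes <- pkn$nodes
  stim <- pkn$stimuli
  non_stim <- setdiff(nodes, stim)
  p_inh <- mean(edges$sign == -1)
  rsign <- function(n) sample(c(1L, -1L), n, replace = TRUE,
                              prob = c(1 - p_inh, p_inh))
  for (try in seq_len(max_tries)) {
    ed <- data.frame(source = stim,
                     sign = rsign(length(stim)),
                     target = sample(non_stim, length(stim), replace = TRUE),
                     stringsAsFactors = FALSE)
    uncovered <- setdiff(non_stim, ed$target)
    for (nd in uncovered) {
      ed <- rbind(ed, data.frame(source = sample(setdiff(nodes, nd), 1L),
                                 sign = rsign(1L), target = nd,
                                 stringsAsFactors = FALSE))
    }
    ed <- unique(ed)
    if (nrow(ed) > n_edges) next   # more constraints than edges available
    guard <- 0L
    while (nrow(ed) < n_edges && guard < 1000L * n_edges) {
      guard <- guard + 1L
      cand <- data.frame(source = sample(nodes, 1L), sign = rsign(1L),
                         target = sample(non_stim, 1L),
                         stringsAsFactors = FALSE)
      if (cand$source == cand$target) next
      ed2 <- unique(rbind(ed, cand))
      ed <- ed2
    }
    if (nrow(ed) == n_edges && all(nodes %in% c(ed$source, ed$target)) &&
        all(stim %in% ed$source)) {
      return(remake(ed))
    }
  }
  stop("could not generate a constraint-satisfying random network in ",
       max_tries, " tries", call. = FALSE)
}

#' Randomly remove or add PKN edges
#'
#' Emulates an imperfect prior: `remove` deletes `round(fraction * |E|)`
#' uniformly chosen edges; `add` inserts that many new random signed edges
#' between existing nodes (never into a stimulus, never duplicating an
#' existing source/target/sign triple).
#'
#' @param pkn a `cfl_pkn`.
#' @param fraction fraction of the edge count to perturb, in (0, 1\].
#' @param operation `"remove"` or `"add"`.
#' @param seed integer seed.
#' @return the perturbed `cfl_pkn`.
#' @export
perturb_pkn <- function(pkn, fraction, operation = c("remove", "add"),
                        seed = 1L) {
  operation <- match.arg(operation)
  stopifnot(fraction > 0, fraction <= 1)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  edges <- pkn$edges
  k <- round(fraction * nrow(edges))
  remake <- function(ed) cfl_pkn(ed, nodes = pkn$nodes, stimuli = pkn$stimuli,
                                 inhibited = pkn$inhibited,
                                 measured = pkn$measured)
  if (operation == "remove") {
    if (k >= nrow(edges)) return(remake(edges[0, ]))
    return(remake(edges[-sample.int(nrow(edges), k), ]))
  }
  existing <- sprintf("%s:%d:%s", edges$source, edges$sign, edges$target)
  non_stim <- setdiff(pkn$nodes, pkn$stimuli)
  added <- 0L
  guard <- 0L
  while (added < k) {
    guard <- guard + 1L
    if (guard > 1000L * k) {
      stop("could not place ", k, " new edges (graph too dense)", call. = FALSE)
    }
    s <- sample(pkn$nodes, 1L)
    t <- sample(non_stim, 1L)
    if (s == t) next
    sgn <- sample(c(1L, -1L), 1L)
    key <- sprintf("%s:%d:%s", s, sgn, t)
    if (key %in% existing) next
    edges <- rbind(edges, data.frame(source = s, sign = sgn, target = t,
                                     stringsAsFactors = FALSE))
    existing <- c(existing, key)
    added <- added + 1L
  }
  remake(edges)
}

#' Batch of perturbed PKNs
#'
#' Generates `n` independently perturbed copies of a PKN at one
#' fraction/operation setting (default 90, the batch size used when
#' assessing robustness of training to errors in the prior network).
#'
#' @inheritParams perturb_pkn
#' @param n number of perturbed networks.
#' @return list of `cfl_pkn`s.
#' @export
perturb_pkn_batch <- function(pkn, fraction, operation = c("remove", "add"),
                              n = 90L, seed = 1L) {
  operation <- match.arg(operation)
  lapply(seq_len(n), function(i) {
    perturb_pkn(pkn, fraction, operation,
                seed = (seed + 104729L * i) %% .Machine$integer.max)
  })
}
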