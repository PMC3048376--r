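# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: brute-force
# loops and direct formula transcriptions only.

# Boolean steady state of a raw PKN under OR-of-edges semantics:
# node = OR over incoming edges of (source if sign>0 else NOT source).
# Stimuli are clamped; everything else starts FALSE. Synchronous update to
# a fixed point (acyclic networks converge within n iterations).
oracle_boolean_state <- function(pkn, stim_values) {
  nodes <- pkn$nodes
  x <- setNames(rep(FALSE, length(nodes)), nodes)
  x[names(stim_values)] <- as.logical(stim_values)
  for (iter in seq_len(length(nodes) + 2)) {
    xn <- x
    for (nd in setdiff(nodes, names(stim_values))) {
      ins <- pkn$edges[pkn$edges$target == nd, , drop = FALSE]
      if (nrow(ins) == 0) { xn[nd] <- FALSE; next }
      vals <- mapply(function(s, sg) if (sg > 0) x[[s]] else !x[[s]],
                     ins$source, ins$sign)
      xn[nd] <- any(vals)
    }
    if (identical(xn, x)) break
    x <- xn
  }
  x
}

# Full input-output truth table of a PKN over its designated nodes: one row
# per Boolean stimulus assignment, columns = designated node values.
oracle_truth_table <- function(pkn) {
  stim <- pkn$stimuli
  desig <- pkn_designated(pkn)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(stim)),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- stim
  t(apply(combos, 1, function(row) {
    st <- oracle_boolean_state(pkn, setNames(as.logical(row), stim))
    st[desig]
  }))
}

# random acyclic PKN with roles, independent of make_toy_pkn's internals
random_acyclic_pkn <- function(n_nodes, n_stim, n_meas, edge_prob = 0.35,
                               inhib_prob = 0.2) {
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  edges <- NULL
  for (i in seq(n_stim + 1, n_nodes)) {
    parents <- which(runif(i - 1) < edge_prob)
    if (!length(parents)) parents <- sample.int(i - 1, 1)
    sgn <- ifelse(runif(length(parents)) < inhib_prob, -1L, 1L)
    edges <- rbind(edges, data.frame(source = nodes[parents], sign = sgn,
                                     target = nodes[i],
                                     stringsAsFactors = FALSE))
  }
  meas <- sample(nodes[(n_stim + 1):n_nodes], n_meas)
  cfl_pkn(unique(edges), nodes = nodes, stimuli = nodes[seq_len(n_stim)],
          measured = meas)
}

# brute-force triple-loop MSE (signals x stimulation x inhibition), with
# the same undefined-prediction penalty contract
oracle_mse <- function(pred_mat, obs_mat) {
  total <- 0
  n <- 0
  for (i in seq_len(ncol(obs_mat))) {
    for (j in seq_len(nrow(obs_mat))) {
      o <- obs_mat[j, i]
      if (is.na(o)) next
      p <- pred_mat[j, i]
      total <- total + if (is.na(p)) 1 else (p - o)^2
      n <- n + 1
    }
  }
  as.numeric(total / n)
}

# direct transcription of the normalized Hill formula
oracle_hill <- function(x, n, k) x^n * (1 + k^n) / (x^n + k^n)

# gate/slot counts by exhaustive enumeration over subsets of input edges
oracle_expansion_counts <- function(m_act, m_inh, mode) {
  m <- m_act + m_inh
  if (mode == "all_pairs") {
    gates <- m + choose(m, 2)
    slots <- m + 2 * choose(m, 2)
  } else {
    gates <- m_act + m_act * m_inh
    slots <- m_act + 2 * m_act * m_inh
  }
  c(gates = gates, slots = slots)
}

# small helpers shared by tests
toy_cache <- local({
  ex <- NULL
  function() {
    if (is.null(ex)) ex <<- toy_signaling_example()
    ex
  }
})

fast_ga <- function(seed, pop = 40L, gens = 150L, stall = 40L) {
  cfl_ga_config(seed = seed, population_size = pop, max_generations = gens,
                stall_generations = stall)
}
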