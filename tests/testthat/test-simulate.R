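test_that("gate and node evaluation combine transferred inputs correctly", {
  inputs <- data.frame(node = c("A", "B"), sign = c(1L, -1L))
  specs <- list(tf_hill(3, 0.5), tf_hill(3, 0.5))
  vals <- list(A = 0.5, B = 0.8)
  v1 <- oracle_hill(0.5, 3, 0.5)          # 0.5625
  v2 <- 1 - oracle_hill(0.8, 3, 0.5)      # 0.0958
  expect_equal(eval_gate(inputs, specs, vals, "minmax"), min(v1, v2))
  expect_equal(eval_gate(inputs, specs, vals, "prodsum"), v1 * v2)
  # 1-input gate degenerates to the edge transfer in every mode
  one <- data.frame(node = "A", sign = 1L)
  for (mode in c("minmax", "prodsum")) {
    expect_equal(eval_gate(one, specs[1], vals, mode),
                 apply_edge_tf(0.5, specs[[1]], 1))
  }
  expect_error(eval_gate(one, list(NULL), vals), "inactive gate")

  expect_equal(eval_node(c(0.6, 0.7), "minmax"), 0.7)
  expect_equal(eval_node(c(0.6, 0.7), "prodsum"), 1.0)
  expect_equal(eval_node(c(0.2, 0.3), "prodsum"), 0.5)
  expect_equal(eval_node(numeric(0)), 0)
})

test_that("simulation clamps, converges, and composes transfer functions", {
  ex <- toy_cache()
  # all stimuli at zero: every non-clamped node is 0 (no basal activity)
  res <- simulate_model(ex$true_model,
                        list(stimuli = data.frame(TGFa = 0, TNFa = 0),
                             inhibitors = data.frame(PI3K = 0, MEK = 0)))
  expect_true(all(res$x == 0))
  expect_true(all(res$converged))

  # chain: S --linear 0.5--> A --near-linear hill--> B
  pkn <- cfl_pkn(data.frame(source = c("S", "A"), sign = 1L,
                            target = c("A", "B")),
                 stimuli = "S", measured = c("A", "B"))
  hs <- expand_pkn(pkn)
  genome <- integer(hs$h)
  genome[hs$slots$input == "S"] <- 4L   # slope 0.5
  genome[hs$slots$input == "A"] <- 1L   # n = 1.01, k = 68.5098
  m <- decode(genome, hs)
  res <- simulate_model(m, list(stimuli = data.frame(S = 1),
                                inhibitors = data.frame()))
  expect_equal(unname(res$x["A", 1]), 0.5, tolerance = 1e-6)
  expect_equal(unname(res$x["B", 1]), 0.5, tolerance = 0.005 / 0.5)

  # inhibited node is clamped to zero regardless of inputs
  res <- simulate_model(ex$true_model,
                        list(stimuli = data.frame(TGFa = 1, TNFa = 1),
                             inhibitors = data.frame(PI3K = 1, MEK = 0)))
  expect_equal(unname(res$x["PI3K", 1]), 0)
  expect_equal(unname(res$x["Akt", 1]), 0)
})

test_that("node values stay in [0,1] in all modes; convergence is a fixed point", {
  ex <- toy_cache()
  hs <- ex$hypothesis
  set.seed(5)
  for (rep in 1:10) {
    m <- decode(sample(0:7, hs$h, replace = TRUE), hs)
    for (mode in c("minmax", "prodsum", "boolean")) {
      sim <- cfl_sim_config(operator_mode = mode)
      res <- simulate_model(m, ex$dataset, sim)
      vals <- res$x[!is.na(res$x)]
      expect_true(all(vals >= 0 & vals <= 1))
      # converged states are fixed points: re-simulating is idempotent
      if (all(res$converged)) {
        res2 <- simulate_model(m, ex$dataset, sim)
        expect_equal(res2$x, res$x)
      }
    }
  }
})

test_that("minmax and prodsum operators are ordered as expected", {
  ex <- toy_cache()
  hs <- ex$hypothesis
  set.seed(9)
  for (rep in 1:5) {
    inputs <- data.frame(node = c("A", "B"), sign = c(1L, 1L))
    specs <- list(tf_hill(3, runif(1, 0.2, 0.7)), tf_hill(3, runif(1, 0.2, 0.7)))
    vals <- list(A = runif(1), B = runif(1))
    and_min <- eval_gate(inputs, specs, vals, "minmax")
    and_prod <- eval_gate(inputs, specs, vals, "prodsum")
    per_input <- c(apply_edge_tf(vals$A, specs[[1]], 1),
                   apply_edge_tf(vals$B, specs[[2]], 1))
    expect_lte(and_min, min(per_input) + 1e-12)
    expect_lte(and_prod, and_min + 1e-12)
    g <- runif(3)
    expect_gte(eval_node(g, "prodsum"), eval_node(g, "minmax") - 1e-12)
    expect_gte(eval_node(g, "minmax"), max(g) - 1e-12)
  }
})

test_that("MSE reproduces the Boolean-vs-graded worked comparison", {
  # a Boolean model forced to predict full activation of two partially
  # activated nodes (observed 0.32 and 0.19) scores far worse than one
  # omitting the interaction entirely
  expect_equal(round(compute_mse(c(1, 1), c(0.32, 0.19)), 2), 0.56)
  expect_equal(round(compute_mse(c(0, 0), c(0.32, 0.19)), 2), 0.07)
  expect_equal(compute_mse(c(0.32, 0.19), c(0.32, 0.19)), 0)
})

test_that("MSE matches the brute-force triple loop and its contracts", {
  ex <- toy_cache()
  set.seed(13)
  hs <- ex$hypothesis
  for (rep in 1:8) {
    m <- decode(sample(0:7, hs$h, replace = TRUE), hs)
    res <- simulate_model(m, ex$dataset)
    obs <- ex$dataset$obs
    pred <- t(res$x[colnames(obs), , drop = FALSE])
    expect_equal(compute_mse(res, ex$dataset), oracle_mse(pred, obs))
    # invariant to permutation of conditions
    perm <- sample(nrow(obs))
    ds2 <- cfl_dataset(ex$dataset$stimuli[perm, , drop = FALSE],
                       ex$dataset$inhibitors[perm, , drop = FALSE],
                       obs[perm, , drop = FALSE])
    res2 <- simulate_model(m, ds2)
    expect_equal(compute_mse(res2, ds2), compute_mse(res, ex$dataset))
  }
  # subsetting by signal and condition
  m <- ex$true_model
  res <- simulate_model(m, ex$dataset)
  full <- compute_mse(res, ex$dataset)
  expect_lt(full, 1e-6)
  sub <- compute_mse(res, ex$dataset, signals = "Akt",
                     conditions = which(ex$dataset$stimuli$TGFa == 1))
  expect_lt(sub, 1e-6)
  # undefined when the subset holds no observations
  empty <- cfl_dataset(ex$dataset$stimuli, ex$dataset$inhibitors,
                       matrix(NA_real_, nrow(ex$dataset$obs), 1,
                              dimnames = list(NULL, "Akt")))
  expect_error(compute_mse(res, empty), "undefined")
  # undefined predictions are penalized with unit squared error
  expect_equal(compute_mse(c(NA, 0.5), c(0.5, 0.5)), 0.5)
})

test_that("boolean mode reproduces classical Boolean steady states", {
  set.seed(17)
  for (rep in 1:8) {
    pkn <- random_acyclic_pkn(sample(5:8, 1), 2, 2)
    hs <- expand_pkn(pkn, "all_pairs")
    # activate exactly the 1-input gates: the model's logic then equals the
    # PKN's OR-of-edges semantics
    genome <- integer(hs$h)
    one_in <- which(vapply(hs$gates, function(g) nrow(g$inputs) == 1, TRUE))
    for (gi in one_in) genome[hs$gates[[gi]]$slots] <- 3L
    m <- decode(genome, hs)
    combos <- expand.grid(rep(list(c(0, 1)), 2), KEEP.OUT.ATTRS = FALSE)
    names(combos) <- pkn$stimuli
    res <- simulate_model(m, list(stimuli = combos, inhibitors = data.frame()),
                          cfl_sim_config(operator_mode = "boolean"))
    for (ci in seq_len(nrow(combos))) {
      oracle <- oracle_boolean_state(pkn, setNames(as.logical(combos[ci, ]),
                                                   pkn$stimuli))
      expect_equal(res$x[pkn$nodes, ci], as.numeric(oracle[pkn$nodes]),
                   ignore_attr = TRUE)
    }
  }
})
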