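# builds a 1-stimulus chain hypothesis space and an ensemble of simple
# models whose S->A slope is given per model
slope_ensemble <- function(slopes) {
  pkn <- cfl_pkn(data.frame(source = "S", sign = 1L, target = "A"),
                 stimuli = "S", measured = "A")
  hs <- expand_pkn(pkn)
  models <- lapply(slopes, function(s) {
    m <- decode(1L, hs)
    m$p1[1] <- s
    m
  })
  cfl_ensemble(hs, models)
}

test_that("gate frequencies count active gates per model", {
  ex <- toy_cache()
  hs <- ex$hypothesis
  truth <- ex$true_model
  empty <- decode(integer(hs$h), hs)
  # 4 of 5 models share the generating topology, one is empty
  ens <- cfl_ensemble(hs, c(rep(list(truth), 4), list(empty)))
  freq <- gate_frequencies(ens)
  expect_true(all(freq$frequency %in% c(0, 0.8)))
  expect_equal(sum(freq$frequency == 0.8), length(active_gates(truth)))
  # invariant to model order
  ens2 <- cfl_ensemble(hs, c(list(empty), rep(list(truth), 4)))
  expect_equal(gate_frequencies(ens2)$frequency, freq$frequency)
  # all and none
  all_ens <- cfl_ensemble(hs, rep(list(truth), 3))
  f <- gate_frequencies(all_ens)
  expect_true(all(f$frequency[active_gates(truth)] == 1))
  expect_true(all(f$frequency[setdiff(seq_len(hs$w),
                                      active_gates(truth))] == 0))
})

test_that("ensemble sensitivity aggregates per-model gate sensitivities", {
  pkn <- cfl_pkn(data.frame(source = "X", sign = 1L, target = "A"),
                 measured = c("A"), stimuli = character())
  # non-stimulus source: Hill slots
  hs <- expand_pkn(cfl_pkn(data.frame(source = "X", sign = 1L, target = "A"),
                           measured = c("X", "A")))
  mk <- function(k) {
    m <- decode(2L, hs)
    m$p2[1] <- k
    m
  }
  one <- cfl_ensemble(hs, list(mk(0.3)))
  s <- ensemble_sensitivity(one, 1)
  expect_equal(s$mean, 0.7)
  expect_equal(s$sd, 0)
  two <- cfl_ensemble(hs, list(mk(0.2), mk(0.4)))
  s2 <- ensemble_sensitivity(two, 1)
  expect_equal(s2$mean, 0.7)
  expect_equal(s2$sd, sd(c(0.8, 0.6)))
  # linear slopes
  lins <- slope_ensemble(c(0.6, 0.6))
  sl <- ensemble_sensitivity(lins, 1)
  expect_equal(sl$mean, 0.3)
  expect_equal(sl$sd, 0)
  # gate active in no member
  none <- cfl_ensemble(hs, list(decode(0L, hs)))
  expect_error(ensemble_sensitivity(none, 1), "no ensemble member")
})

test_that("ensemble predictions summarize mean, sd and CV per cell", {
  ens <- slope_ensemble(c(0.2, 0.4))
  conds <- list(stimuli = data.frame(S = c(0, 1)), inhibitors = data.frame())
  pred <- ensemble_predict(ens, conds)
  expect_equal(unname(pred$mean["A", 2]), 0.3)
  expect_equal(unname(pred$sd["A", 2]), sd(c(0.2, 0.4)))
  expect_equal(unname(pred$cv["A", 2]), sd(c(0.2, 0.4)) / 0.3)
  # all-zero stimulus: mean 0 and CV undefined
  expect_equal(unname(pred$mean["A", 1]), 0)
  expect_true(is.na(pred$cv["A", 1]))
  # identical members: sd and CV are 0 where defined
  same <- slope_ensemble(c(0.5, 0.5, 0.5))
  p2 <- ensemble_predict(same, conds)
  expect_equal(unname(p2$sd["A", 2]), 0)
  expect_equal(unname(p2$cv["A", 2]), 0)
  # brute-force per-cell recomputation
  sims <- lapply(ens$models, function(m) simulate_model(m, conds)$x)
  for (nd in rownames(pred$mean)) for (ci in 1:2) {
    vals <- vapply(sims, function(x) x[nd, ci], 0)
    expect_equal(unname(pred$mean[nd, ci]), mean(vals))
  }
})

test_that("response surfaces evaluate only the output's gates", {
  ex <- toy_cache()
  hs <- ex$hypothesis
  ens <- cfl_ensemble(hs, list(ex$true_model))
  grid <- list(PI3K = seq(0, 1, length.out = 21),
               TNFa = seq(0, 1, length.out = 21))
  surf <- node_response_surface(ens, "JNK", grid)
  expect_equal(nrow(surf$grid), 441)
  expect_equal(surf$sd, rep(0, 441))
  # the surface is the OR of the two generating transfer functions
  expect_equal(surf$mean,
               pmax(oracle_hill(surf$grid$PI3K, 3, 0.7),
                    0.8 * surf$grid$TNFa))
  # single 1-input gate: surface equals the transfer curve
  s2 <- node_response_surface(ens, "Akt", list(PI3K = seq(0, 1, by = 0.1)))
  expect_equal(s2$mean, oracle_hill(seq(0, 1, by = 0.1), 3, 0.5))
  expect_error(node_response_surface(ens, "Akt", list(TNFa = c(0, 1))),
               "not connected")
})

test_that("topology distance compares consensus edge sets", {
  ex <- toy_cache()
  hs <- ex$hypothesis
  ens <- cfl_ensemble(hs, list(ex$true_model))
  expect_equal(topology_distance(ens, ens), 0)
  # drop the TGFa->PI3K gate from the second family: the symmetric
  # difference loses the PI3K-dependent edges
  pi3k_gate <- which(vapply(hs$gates, function(g) g$output == "PI3K", TRUE))
  m2 <- ex$true_model
  sl <- hs$gates[[pi3k_gate]]$slots
  m2$type[sl] <- 0L
  ens2 <- cfl_ensemble(hs, list(m2))
  d <- topology_distance(ens, ens2)
  expect_gt(d, 0)
  expect_lte(d, 1)
  # constructed three-edge example: consensus {e1,e2} vs {e2,e3} -> 2/3
  pkn <- cfl_pkn(data.frame(source = c("S", "S", "S"), sign = 1L,
                            target = c("A", "B", "C")),
                 stimuli = "S", measured = c("A", "B", "C"))
  h2 <- expand_pkn(pkn)
  pick <- function(outs) {
    g <- integer(h2$h)
    for (o in outs) g[h2$slots$output == o] <- 1L
    decode(g, h2)
  }
  ea <- cfl_ensemble(h2, list(pick(c("A", "B"))))
  eb <- cfl_ensemble(h2, list(pick(c("B", "C"))))
  expect_equal(topology_distance(ea, eb), 2 / 3)
  # cut = 1 keeps only unanimous gates: the mixed family's consensus is {B}
  mixed <- cfl_ensemble(h2, list(pick(c("A", "B")), pick(c("B"))))
  expect_equal(topology_distance(mixed, eb, frequency_cut = 1.0), 1 / 2)
})

test_that("significance against randomized-control MSE distributions", {
  set.seed(41)
  # symmetric, mesokurtic null: auto picks the z-score branch
  null_norm <- qnorm(ppoints(200), mean = 0.5, sd = 0.05)
  jb <- jarque_bera(null_norm)
  expect_lt(jb$statistic, 1)
  res <- significance_vs_null(0.5, null_norm, method = "auto")
  expect_identical(unique(res$method), "zscore")
  expect_equal(res$p, 0.5, tolerance = 1e-6)
  # real model better than every null: empirical p reported as < 1/n
  null_mses <- runif(100, 0.3, 0.6)
  res2 <- significance_vs_null(0.01, null_mses, method = "empirical")
  expect_true(res2$upper_bound)
  expect_equal(res2$p, 1 / 100)
  # empirical p is invariant under strictly monotone transforms
  f <- function(x) exp(3 * x) + 1
  res3 <- significance_vs_null(f(0.35), f(null_mses), method = "empirical")
  expect_equal(significance_vs_null(0.35, null_mses, "empirical")$p, res3$p)
  # heavily skewed null: auto switches to the empirical branch
  skewed <- c(rep(0.1, 150), rexp(50, 1) + 0.1)
  expect_identical(unique(significance_vs_null(0.05, skewed, "auto")$method),
                   "empirical")
  expect_error(significance_vs_null(0.1, rep(0.5, 10), method = "zscore"),
               "degenerate")
})

test_that("k-fold partitions are exhaustive, disjoint and seeded", {
  ex <- toy_cache()
  cv <- kfold_crossval(ex$hypothesis, ex$dataset, folds = 3, seed = 5,
                       ga = fast_ga(1, pop = 15, gens = 10, stall = 5),
                       n_runs = 1)
  cells <- which(!is.na(ex$dataset$obs))
  expect_setequal(cv$cells, cells)
  expect_equal(sort(unique(cv$assignment)), 1:3)
  expect_equal(length(cv$assignment), length(cells))
  expect_equal(nrow(cv$report), 3)
  expect_true(all(cv$report$quadrant %in%
                    c("precise_accurate", "imprecise_accurate",
                      "precise_inaccurate", "imprecise_inaccurate")))
  cv2 <- kfold_crossval(ex$hypothesis, ex$dataset, folds = 3, seed = 5,
                        ga = fast_ga(1, pop = 15, gens = 10, stall = 5),
                        n_runs = 1)
  expect_identical(cv$assignment, cv2$assignment)
})

test_that("holdout cross-validation masks the held-out cells and classifies", {
  expect_identical(prediction_quadrant(0.05, 0.10), "precise_accurate")
  expect_identical(prediction_quadrant(0.25, 0.30), "imprecise_inaccurate")
  expect_identical(prediction_quadrant(0.25, 0.10), "precise_inaccurate")
  expect_identical(prediction_quadrant(0.05, 0.30), "imprecise_accurate")

  ex <- toy_cache()
  hv <- holdout_crossval(ex$hypothesis, ex$dataset, signal = "JNK",
                         stimulus = "TNFa", seed = 3,
                         ga = fast_ga(1, pop = 20, gens = 30, stall = 10),
                         n_runs = 2)
  expect_equal(hv$report$n_test,
               sum(!is.na(ex$dataset$obs[ex$dataset$stimuli$TNFa > 0, "JNK"])))
  expect_true(hv$report$test_mse >= 0)
  # ineligible pairs are refused with the failing criterion named
  stim2 <- data.frame(S1 = c(0, 1, 0, 1), S2 = c(0, 0, 1, 1))
  never_under_s1 <- cfl_dataset(stim2, obs = cbind(A = c(0, 0, 0.5, 0.05)))
  expect_error(holdout_crossval(ex$hypothesis, never_under_s1, "A", "S1"),
               "never activated .* under S1")
  only_under_s1 <- cfl_dataset(stim2, obs = cbind(A = c(0, 0.5, 0, 0.5)))
  expect_error(holdout_crossval(ex$hypothesis, only_under_s1, "A", "S1"),
               "under any other")
})
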