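# small fixture: stimulus chain with an off-grid generating parameter
offgrid_chain <- function(k_true = 0.45, slope_true = 0.6) {
  pkn <- cfl_pkn(data.frame(source = c("S", "A"), sign = 1L,
                            target = c("A", "B")),
                 stimuli = "S", measured = c("A", "B"))
  hs <- expand_pkn(pkn)
  truth <- decode(c(1L, 2L), hs)
  truth$p1[hs$slots$input == "S"] <- slope_true
  truth$type[hs$slots$input == "A"] <- 2L
  truth$p1[hs$slots$input == "A"] <- 3
  truth$p2[hs$slots$input == "A"] <- k_true
  design <- list(stimuli = data.frame(S = seq(0, 1, by = 0.1)),
                 inhibitors = data.frame())
  ds <- simulate_dataset(truth, design, measured = c("A", "B"))
  list(pkn = pkn, hs = hs, truth = truth, dataset = ds)
}

test_that("reduction removes only what the threshold allows", {
  ex <- toy_cache()
  truth <- ex$true_model
  # every generating gate is necessary: threshold 0 leaves the model intact
  red0 <- reduce_model(truth, ex$dataset, 0)
  expect_setequal(active_gates(red0), active_gates(truth))
  expect_identical(red0$stage, "reduced")
  # an effect-free duplicate gate is removed at threshold 0
  hs <- ex$hypothesis
  mek2 <- which(vapply(hs$gates, function(g) g$output == "MEK" &&
                         nrow(g$inputs) == 2, TRUE))
  m <- truth
  for (s in hs$gates[[mek2]]$slots) {
    lib <- hs$slots$library[s]
    m$type[s] <- if (lib == "linear") 1L else 2L
    m$p1[s] <- if (lib == "linear") 0.7 else 3
    if (lib == "hill") m$p2[s] <- 0.5
  }
  red <- reduce_model(m, ex$dataset, 0)
  expect_false(mek2 %in% active_gates(red))
  # unbounded threshold strips every gate
  red_inf <- reduce_model(truth, ex$dataset, Inf)
  expect_length(active_gates(red_inf), 0)
  # soundness: reduced MSE <= base + threshold across the grid
  base <- compute_mse(simulate_model(truth, ex$dataset), ex$dataset)
  for (thr in c(0, 1e-4, 1e-3, 1e-2)) {
    expect_lte(reduce_model(truth, ex$dataset, thr)$mse, base + thr + 1e-12)
  }
})

test_that("AND gates can be replaced by their 1-input sub-gates", {
  # output with a necessary activating input and a useless partner: the
  # reduction should keep the informative arm via gate replacement
  pkn <- cfl_pkn(data.frame(source = c("S1", "S2"), sign = 1L,
                            target = c("OUT", "OUT")),
                 stimuli = c("S1", "S2"), measured = "OUT")
  hs <- expand_pkn(pkn, "all_pairs")
  and_gate <- which(vapply(hs$gates, function(g) nrow(g$inputs) == 2, TRUE))
  g <- integer(hs$h)
  g[hs$gates[[and_gate]]$slots] <- 4L   # OUT = min(0.5*S1, 0.5*S2)
  m <- decode(g, hs)
  design <- full_factorial_design(c("S1", "S2"))
  # data generated by S1 alone: dropping S2 from the AND improves the fit
  truth_gate <- which(vapply(hs$gates, function(g) nrow(g$inputs) == 1 &&
                               g$inputs$node == "S1", TRUE))
  gt <- integer(hs$h)
  gt[hs$gates[[truth_gate]]$slots] <- 4L
  ds <- simulate_dataset(decode(gt, hs), design, measured = "OUT")
  red <- reduce_model(m, ds, 1e-6)
  expect_setequal(active_gates(red), truth_gate)
  expect_lt(red$mse, 1e-9)
})

test_that("continuous refinement recovers off-grid parameters", {
  fx <- offgrid_chain(k_true = 0.45)
  # discrete training cannot do better than the nearest grid point
  disc <- run_ga(fx$hs, fx$dataset, fast_ga(5, pop = 20, gens = 60, stall = 20))
  expect_gt(disc$mse, 1e-6)
  ref <- refine_parameters(reduce_model(disc, fx$dataset, 0), fx$dataset)
  expect_identical(ref$stage, "reduced_refined")
  expect_lte(ref$mse, disc$mse + 1e-9)
  k_hat <- ref$p2[fx$hs$slots$input == "A"]
  expect_lt(abs(k_hat - 0.45), 0.02)
  expect_lt(ref$mse, 1e-5)
  # refinement of an empty model is a no-op
  empty <- decode(integer(fx$hs$h), fx$hs)
  ref0 <- refine_parameters(empty, fx$dataset)
  expect_length(active_gates(ref0), 0)
})

test_that("reduction profiles are monotone and filtering respects thresholds", {
  ex <- toy_cache()
  fam <- train_family(ex$hypothesis, ex$dataset,
                      fast_ga(31, pop = 30, gens = 60, stall = 20), n_runs = 3)
  cfg <- cfl_refinement_config(reduction_grid = c(0, 1e-4, 1e-3, 1e-2, 5e-2))
  prof <- build_reduction_profile(fam, ex$dataset, cfg)
  for (mi in unique(prof$table$model)) {
    sub <- prof$table[prof$table$model == mi, ]
    expect_true(all(diff(sub$n_params) <= 0))        # nonincreasing params
    expect_true(all(diff(sub$mse) >= -1e-9))         # nondecreasing MSE
  }
  filt <- select_filtered(prof)
  expect_identical(filt$stage, "filtered")
  for (i in seq_along(filt$models)) {
    expect_lte(filt$models[[i]]$mse,
               prof$baseline[i] + cfg$selection_threshold + 1e-12)
  }
  # selection at threshold 0 returns each model's baseline fit
  filt0 <- select_filtered(prof, 0)
  expect_equal(vapply(filt0$models, `[[`, 0, "mse"), prof$baseline)
  # filter points live on the grid; a model whose MSE never leaves the
  # selection band has its filter point at the grid maximum
  expect_true(all(prof$filter_point %in% cfg$reduction_grid))
  for (mi in seq_along(prof$baseline)) {
    sub <- prof$table[prof$table$model == mi, ]
    if (all(sub$mse <= prof$baseline[mi] + cfg$selection_threshold)) {
      expect_equal(prof$filter_point[mi], max(cfg$reduction_grid))
    }
  }

  tt <- threshold_tradeoff_table(prof)
  expect_true(all(diff(tt$mean_n_params) <= 0))    # params shrink
  expect_true(all(diff(tt$mean_mse) >= -1e-9))     # fit degrades
  expect_equal(tt$mean_mse[1], mean(prof$baseline))
})
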