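edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], sign = as.integer(m[, 2]), target = m[, 3],
             stringsAsFactors = FALSE)
}

test_that("role designation follows the dataset and flags all columns", {
  ex <- toy_cache()
  pkn <- cfl_pkn(ex$pkn$edges)  # strip roles
  des <- designate_roles(pkn, ex$dataset)
  expect_setequal(des$stimuli, c("TGFa", "TNFa"))
  expect_setequal(des$inhibited, c("PI3K", "MEK"))
  expect_length(des$measured, 6)
  expect_setequal(pkn_intermediates(des),
                  c("RAS", "TRAF2", "MAP3K1", "MKK4", "IKK"))

  bad <- cfl_dataset(data.frame(TGFa = c(0, 1)),
                     obs = cbind(FOO = c(0.1, 0.2)))
  expect_error(designate_roles(pkn, bad), "FOO")

  # a measured stimulus carries both flags
  ds <- cfl_dataset(data.frame(TGFa = c(0, 1)),
                    obs = cbind(TGFa = c(0, 1), Akt = c(0.1, 0.2)))
  both <- designate_roles(pkn, ds)
  expect_true("TGFa" %in% both$stimuli && "TGFa" %in% both$measured)
})

test_that("compression splices linear intermediates with sign products", {
  pkn <- cfl_pkn(edge_df("A", 1, "B", "B", 1, "C"),
                 stimuli = "A", measured = "C")
  cc <- compress(pkn)
  expect_equal(cc$edges, edge_df("A", 1, "C"))

  pkn <- cfl_pkn(edge_df("A", 1, "B", "B", -1, "C"),
                 stimuli = "A", measured = "C")
  expect_equal(compress(pkn)$edges, edge_df("A", -1, "C"))

  # double negation gives activation
  pkn <- cfl_pkn(edge_df("A", -1, "B", "B", -1, "C"),
                 stimuli = "A", measured = "C")
  expect_equal(compress(pkn)$edges, edge_df("A", 1, "C"))
})

test_that("multi-in multi-out intermediates are retained", {
  # X has 2 in- and 2 out-edges: splicing it would change the logic
  pkn <- cfl_pkn(edge_df("S1", 1, "X", "S2", -1, "X",
                         "X", 1, "M1", "X", 1, "M2"),
                 stimuli = c("S1", "S2"), measured = c("M1", "M2"))
  cc <- compress(pkn)
  expect_true("X" %in% cc$nodes)
  expect_equal(nrow(cc$edges), 4)
})

test_that("compression preserves Boolean input-output truth tables", {
  set.seed(31)
  for (rep in 1:20) {
    pkn <- random_acyclic_pkn(sample(6:10, 1), 2, 3)
    cc <- compress(pkn)
    expect_equal(oracle_truth_table(cc), oracle_truth_table(pkn))
  }
})

test_that("expansion enumerates gates and slots per the combinatorial count", {
  # outputs with m <= 5 inputs, varying inhibitory composition, both modes
  for (m_act in 0:4) for (m_inh in 0:(5 - m_act)) {
    if (m_act + m_inh == 0) next
    srcs_a <- sprintf("A%d", seq_len(m_act))
    srcs_i <- sprintf("I%d", seq_len(m_inh))
    ed <- rbind(
      if (m_act) data.frame(source = srcs_a, sign = 1L, target = "OUT"),
      if (m_inh) data.frame(source = srcs_i, sign = -1L, target = "OUT"))
    pkn <- cfl_pkn(ed, measured = "OUT")
    for (mode in c("all_pairs", "inhibitory_only")) {
      exp_counts <- oracle_expansion_counts(m_act, m_inh, mode)
      hs <- suppressWarnings(expand_pkn(pkn, mode))
      expect_equal(hs$w, unname(exp_counts["gates"]),
                   info = sprintf("%s m_act=%d m_inh=%d", mode, m_act, m_inh))
      expect_equal(hs$h, unname(exp_counts["slots"]))
      # every gate input corresponds to a PKN edge with matching sign
      for (g in hs$gates) {
        for (i in seq_len(nrow(g$inputs))) {
          expect_true(any(ed$source == g$inputs$node[i] &
                            ed$sign == g$inputs$sign[i] &
                            ed$target == g$output))
        }
      }
    }
  }
})

test_that("inhibitory_only expansion builds A-AND-NOT-B gates", {
  pkn <- cfl_pkn(edge_df("A", 1, "OUT", "B", 1, "OUT", "C", -1, "OUT"),
                 measured = "OUT")
  hs <- expand_pkn(pkn, "inhibitory_only")
  expect_equal(hs$w, 4)   # {A}, {B}, {A AND !C}, {B AND !C}
  expect_equal(hs$h, 6)
  labels <- vapply(hs$gates, function(g) {
    paste0(ifelse(g$inputs$sign < 0, "!", ""), g$inputs$node, collapse = "&")
  }, "")
  expect_setequal(labels, c("A", "B", "A&!C", "B&!C"))
  expect_equal(count_search_space(hs)[c("w", "h", "alphabet_size")],
               list(w = 4L, h = 6L, alphabet_size = 8L))

  only_inh <- cfl_pkn(edge_df("C", -1, "OUT"), measured = "OUT")
  expect_warning(expand_pkn(only_inh, "inhibitory_only"), "only inhibitory")
})

test_that("single-input expansion and search-space accounting", {
  pkn <- cfl_pkn(edge_df("A", 1, "OUT"), stimuli = "A", measured = "OUT")
  for (mode in c("all_pairs", "inhibitory_only")) {
    hs <- expand_pkn(pkn, mode)
    expect_equal(hs$w, 1)
    expect_equal(hs$h, 1)
    expect_equal(hs$slots$library, "linear")  # stimulus-sourced slot
  }
  ex <- toy_cache()
  ss <- count_search_space(ex$hypothesis)
  expect_equal(ss$alphabet_size, 8L)
  expect_gte(ss$h, ss$w)
  expect_equal(ss$log10_size, ss$h * log10(8))
  # w = h when every gate has one input
  hs1 <- expand_pkn(cfl_pkn(edge_df("A", 1, "B", "C", 1, "D"),
                            measured = c("B", "D")), "all_pairs")
  expect_equal(hs1$w, hs1$h)
})
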