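tiny_problem <- function(criterion = "D") {
  net <- one_gene()
  design_problem(net, db_params(), stocks = c(g1 = 5), n_cycles = 6,
                 levels = seq(0, 1, 0.25),
                 par_names = c("kcat_TX_s70", "kdeg_deGFP"),
                 criterion = criterion)
}

test_that("uninformative designs score lowest", {
  prob <- tiny_problem()
  zero <- inflow_protocol(matrix(0, 6, 1, dimnames = list(NULL, "g1")),
                          c(g1 = 5))
  some <- inflow_protocol(matrix(0.5, 6, 1, dimnames = list(NULL, "g1")),
                          c(g1 = 5))
  expect_lt(score_design(zero, prob), score_design(some, prob))
})

test_that("for a linear gene the D-score grows with DNA delivered", {
  prob <- tiny_problem()
  scores <- vapply(c(0.25, 0.5, 1), function(f)
    score_design(inflow_protocol(matrix(f, 6, 1,
                                        dimnames = list(NULL, "g1")),
                                 c(g1 = 5)), prob), 0.0)
  expect_true(all(diff(scores) > 0))
})

test_that("the search is elitist and reproducible", {
  prob <- tiny_problem()
  best <- optimize_design(prob, budget = 20, seed = 5, pop_size = 6,
                          elite = 2)
  h <- attr(best, "history")
  expect_true(all(diff(h$best) >= 0))             # elitism: never degrades
  expect_equal(attr(best, "score"), h$best[nrow(h)])
  best2 <- optimize_design(prob, budget = 20, seed = 5, pop_size = 6,
                           elite = 2)
  expect_identical(best$fractions, best2$fractions)
  # degenerate budget: best of the random initial population
  b0 <- optimize_design(prob, budget = 6, seed = 2, pop_size = 6)
  expect_equal(attr(b0, "score"), attr(b0, "history")$best[1])
  expect_error(optimize_design(prob, budget = 3, pop_size = 6), "budget")
})

test_that("independent seeds reach comparable scores", {
  net <- one_gene()
  prob <- design_problem(net, db_params(), stocks = c(g1 = 5),
                         n_cycles = 4, levels = seq(0, 1, length.out = 4),
                         par_names = c("kcat_TX_s70", "kdeg_deGFP"))
  s1 <- attr(optimize_design(prob, budget = 80, seed = 1, pop_size = 8),
             "score")
  s2 <- attr(optimize_design(prob, budget = 80, seed = 2, pop_size = 8),
             "score")
  # D-scores are log-determinants: compare the determinants themselves
  expect_lt(abs(exp(s1 - s2) - 1), 0.10)
})

test_that("designed fractions live on the admissible level grid", {
  prob <- tiny_problem()
  best <- optimize_design(prob, budget = 12, seed = 3, pop_size = 6)
  expect_true(all(best$fractions %in% prob$levels))
  expect_true(all(rowSums(best$fractions) <= 1 + 1e-12))
})

test_that("multi-construct designs develop distinct inflow columns", {
  net <- make_iffl("TetR", TRUE)
  prob <- design_problem(net, db_params(),
                         stocks = stats::setNames(rep(10, 3), net$names),
                         n_cycles = 8, levels = seq(0, 0.3, 0.1),
                         par_names = c("kcat_TX_s19", "kd_TetR",
                                       "kcat_TL_TetR_RiboJ"))
  best <- optimize_design(prob, budget = 16, seed = 4, pop_size = 8)
  fr <- best$fractions
  expect_false(all(fr[, 2] == fr[, 3]))
  expect_true(any(apply(fr, 2, function(col) length(unique(col)) > 1)))
})

test_that("an optimized design is estimate-dependent, not universal", {
  prob <- tiny_problem()
  best <- optimize_design(prob, budget = 12, seed = 6, pop_size = 6)
  far <- update_params(db_params(),
                       c(kcat_TX_s70 = 4, kdeg_deGFP = 0.008),
                       validate = FALSE)
  prob_far <- design_problem(one_gene(), far, stocks = c(g1 = 5),
                             n_cycles = 6, levels = seq(0, 1, 0.25),
                             par_names = c("kcat_TX_s70", "kdeg_deGFP"))
  s_near <- score_design(best, prob)
  s_far <- score_design(best, prob_far)
  expect_false(isTRUE(all.equal(s_near, s_far)))
})
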