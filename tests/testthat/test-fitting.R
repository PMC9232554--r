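test_that("the soft constraint accepts exactly the (2, 500) ratio band", {
  ps <- db_params()
  net <- one_gene()    # p70a reporter: ratio = kcat_TX_s70/(kdeg+lambda)
  # database means: ratio ~ 7.4, inside the band
  expect_equal(soft_constraint_penalty(ps, net, LAMBDA_DEFAULT), 0)
  # ratio below 2: positive penalty
  low <- update_params(ps, c(kcat_TX_s70 = 0.05), validate = FALSE)
  expect_gt(soft_constraint_penalty(low, net, LAMBDA_DEFAULT), 0)
  # ratio exactly 2 and exactly 500: boundary accepted
  r2 <- update_params(ps, c(kcat_TX_s70 = 2 * ps[["kdeg_deGFP"]]),
                      validate = FALSE)
  expect_equal(soft_constraint_penalty(r2, net, 0), 0)
  r500 <- update_params(ps, c(kcat_TX_s70 = 500 * ps[["kdeg_deGFP"]]),
                        validate = FALSE)
  expect_equal(soft_constraint_penalty(r500, net, 0), 0)
  rover <- update_params(ps, c(kcat_TX_s70 = 520 * ps[["kdeg_deGFP"]]),
                         validate = FALSE)
  expect_gt(soft_constraint_penalty(rover, net, 0), 0)
})

test_that("the objective vanishes at the truth on noiseless data", {
  ps <- db_params()
  db <- single_gene_db(ps)
  expect_lt(cfps_objective(db, ps), 1e-12)
  # any perturbation scores worse (local optimality at the truth)
  set.seed(8)
  for (i in 1:5) {
    pert <- update_params(ps, c(kcat_TX_s70 =
      ps[["kcat_TX_s70"]] * exp(stats::rnorm(1, 0, 0.3))), validate = FALSE)
    expect_gt(cfps_objective(db, pert), cfps_objective(db, ps))
  }
})

test_that("residual changes are confined to experiments sharing the part", {
  ps <- db_params()
  nets <- list(rj = make_iffl("TetR", TRUE), plain = make_iffl("TetR",
                                                               FALSE))
  exps <- lapply(names(nets), function(nm)
    experiment(nets[[nm]],
               iffl_step_protocol(nets[[nm]], n_cycles = 16,
                                  step_cycle = 6), name = nm))
  db <- generate_study(ps, exps, sd_abs = 0, sd_rel = 0)
  # perturbing the RiboJ-specific translation rate only moves the RiboJ
  # experiment's simulation
  pert <- update_params(ps, c(kcat_TL_TetR_RiboJ = 2), validate = FALSE)
  sim_plain_a <- simulate_experiment(db$experiments[[2]], ps)
  sim_plain_b <- simulate_experiment(db$experiments[[2]], pert)
  expect_identical(sim_plain_a, sim_plain_b)
  sim_rj_a <- simulate_experiment(db$experiments[[1]], ps)
  sim_rj_b <- simulate_experiment(db$experiments[[1]], pert)
  expect_gt(max(abs(sim_rj_a - sim_rj_b)), 0)
  # a shared transcription rate moves both
  pert2 <- update_params(ps, c(kcat_TX_s19 = 3), validate = FALSE)
  expect_gt(max(abs(simulate_experiment(db$experiments[[2]], pert2) -
                      sim_plain_a)), 0)
})

test_that("distribution width follows the top-five / bottom-five rule", {
  expect_equal(distribution_width(1:10), 8 / 3)
  expect_equal(distribution_width(rep(3.7, 12)), 1)
  expect_equal(distribution_width(7 * (1:10)), 8 / 3)   # scale invariant
  expect_error(distribution_width(1:9), ">= 10")
})

test_that("the RiboJ factor is the median pair ratio and round-trips", {
  expect_equal(riboj_factor(c(2, 3, 1), c(1, 1, 1)), 2)
  expect_equal(riboj_factor(5.5, 2), 2.75)
  expect_error(riboj_factor(c(1, -2), c(1, 1)), "> 0")
  ps <- db_params()
  f <- 3.123
  ps2 <- apply_riboj_factor(ps, "mmCherry", f)
  expect_equal(ps2[["kcat_TL_mmCherry_RiboJ"]] / f,
               ps[["kcat_TL_mmCherry"]], tolerance = 1e-12)
})

test_that("prediction bands behave for degenerate ensembles", {
  ps <- db_params()
  fit <- fake_fit(list(ps, ps, ps, ps))
  net <- one_gene()
  proto <- constant_protocol(net, n_cycles = 6)
  band <- prediction_band(fit, net, proto, quantile = 1)
  expect_true(all(band$sd == 0))
  single <- simulate_circuit(net, ps, proto)$observables
  expect_equal(unname(band$mean), unname(single))
  expect_error(prediction_band(fit, net, proto, quantile = 0), "quantile")
})

test_that("a small ensemble fit recovers the identifiable combination", {
  ps <- db_params()
  db <- single_gene_db(ps, sd_abs = 0.5, sd_rel = 0.02, seed = 3,
                       n_cycles = 10)
  fit <- cfps_fit(db, free = c("kcat_TX_s70", "kcat_TL_deGFP_RiboJ",
                               "kdeg_deGFP"),
                  start = ps, n_agents = 20, n_rounds = 18, seed = 2)
  expect_s3_class(fit, "cfps_fit")
  expect_gte(length(fit$ensemble), 10)
  # the product kcat_TX * kcat_TL is identifiable even if the factors
  # covary
  best <- coef(fit)
  prod_true <- ps[["kcat_TX_s70"]] * ps[["kcat_TL_deGFP_RiboJ"]]
  prod_fit <- best[["kcat_TX_s70"]] * best[["kcat_TL_deGFP_RiboJ"]]
  expect_lt(abs(prod_fit - prod_true) / prod_true, 0.10)
  # methods exercise
  expect_output(print(fit), "ensemble")
  s <- summary(fit)
  expect_true(all(c("best", "width", "category") %in% names(s)))
  expect_length(residuals(fit), db$n)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
})

test_that("point-collapsed bounds give a width-one ensemble", {
  ps <- db_params()
  db <- single_gene_db(ps)
  b <- cbind(lower = ps[["kcat_TX_s70"]], upper = ps[["kcat_TX_s70"]])
  rownames(b) <- "kcat_TX_s70"
  fit <- cfps_fit(db, free = "kcat_TX_s70", start = ps, bounds = b,
                  n_agents = 20, n_rounds = 2, seed = 1)
  expect_equal(distribution_width(fit, "kcat_TX_s70"), 1)
})
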