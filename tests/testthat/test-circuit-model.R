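test_that("Hill repression has the right landmarks and monotonicity", {
  expect_equal(hill_repression(0, 10, 2), 1.0)
  expect_equal(hill_repression(10, 10, 1), 0.5)
  expect_equal(hill_repression(10, 10, 3.7), 0.5)
  expect_equal(hill_repression(20, 10, 2), 0.2)   # 1/(1+2^2)
  r <- seq(0, 100, by = 5)
  f <- hill_repression(r, kd = 7, n = 2.5)
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(1 - f) > 0))   # complement monotone increasing
  expect_error(hill_repression(-1, 10, 2), "concentration")
  expect_error(hill_repression(1, 0, 2), "kd")
})

test_that("transcription rates follow the promoter logic", {
  ps <- db_params()
  k70 <- gene_construct("a", "p70a", "sigma19")
  expect_equal(transcription_rate(k70, dna = 1, sigma19 = 0, repressor = 0,
                                  params = ps), 0.5)  # kcat_TX_s70 = 0.5
  k19 <- gene_construct("b", "p19a", "TetR")
  expect_equal(transcription_rate(k19, dna = 3, sigma19 = 0, repressor = 0,
                                  params = ps), 0)
  # saturating sigma19 and repressor at kd: kcat * dna * 0.5
  kop <- gene_construct("c", "p19a", "deGFP", operator = "TetRO1")
  r <- transcription_rate(kop, dna = 2, sigma19 = 1e9,
                          repressor = ps[["kd_TetR"]], params = ps)
  expect_equal(r, ps[["kcat_TX_s19"]] * 2 * 0.5, tolerance = 1e-6)
})

test_that("steady-state mRNA/DNA ratio matches the closed form", {
  ps <- db_params()
  k <- gene_construct("a", "p70a", "TetR")   # kdeg_TetR = 0.04
  expect_equal(steady_state_mrna_ratio(k, ps, LAMBDA_DEFAULT),
               0.5 / (0.04 + 0.4 / 22.5), tolerance = 1e-12)
  expect_equal(round(steady_state_mrna_ratio(k, ps, LAMBDA_DEFAULT), 2),
               8.65)
  expect_error(steady_state_mrna_ratio(k, ps, -0.1), "lambda")
  ps0 <- update_params(ps, c(kdeg_TetR = 0), validate = FALSE)
  expect_error(steady_state_mrna_ratio(k, ps0, 0), "degenerate")
})

test_that("parameter sets enforce bounds and Hill ranges", {
  b <- cbind(lower = c(a = 1, n_TetR = 1), upper = c(a = 10, n_TetR = 4))
  expect_error(parameter_set(c(a = 20, n_TetR = 2), b), "outside")
  expect_error(parameter_set(c(a = -2, n_TetR = 2), b), "> 0")
  expect_silent(parameter_set(c(a = 5, n_TetR = 2), b))
  ps <- db_params()
  expect_true(all(as.numeric(ps) >= param_bounds(ps)[, 1] - 1e-12))
  expect_true(all(as.numeric(ps) <= param_bounds(ps)[, 2] + 1e-12))
})

test_that("the assembled rhs vanishes at the zero state with zero inflow", {
  ps <- db_params()
  sys <- build_ode_system(make_iffl("TetR", TRUE), ps)
  dy <- sys$rhs(0, rep(0, length(sys$species)),
                kin = rep(0, 3), lambda = LAMBDA_DEFAULT)
  expect_equal(dy, rep(0, length(sys$species)))
})

test_that("a missing translation rate raises an uncharacterized-part error", {
  ps <- db_params()
  net <- network_spec(list(gene_construct("x", "p70a", "sigma19",
                                          riboj = TRUE)))  # no such entry
  expect_error(build_ode_system(net, ps), "uncharacterized part")
  # resolved by extrapolating across the insulator
  ps2 <- apply_riboj_factor(ps, "sigma19", 2)
  expect_silent(build_ode_system(net, ps2))
})

test_that("simulated steady state matches the closed-form cascade oracle", {
  ps <- db_params()
  net <- one_gene()
  proto <- constant_protocol(net, frac = 0.2, stock = 5, n_cycles = 60)
  traj <- simulate_circuit(net, ps, proto, rtol = 1e-11, atol = 1e-13)
  ss <- cascade_steady_state(ps, dna = 0.2 * 5)
  end <- nrow(traj$states)
  expect_equal(unname(traj$states[end, "DNA_g1"]), ss[["dna"]],
               tolerance = 1e-6)
  expect_equal(unname(traj$states[end, "mRNA_g1"]), ss[["mrna"]],
               tolerance = 1e-6)
  expect_equal(unname(traj$states[end, "Pmat_g1"]), ss[["mature"]],
               tolerance = 1e-6)
  # mRNA_ss / DNA_ss equals the soft-constraint ratio
  expect_equal(unname(traj$states[end, "mRNA_g1"] /
                        traj$states[end, "DNA_g1"]),
               steady_state_mrna_ratio(net$constructs[[1]], ps,
                                       LAMBDA_DEFAULT),
               tolerance = 1e-6)
})

test_that("the unregulated circuit responds linearly to DNA inflow", {
  ps <- db_params()
  net <- one_gene()
  t1 <- simulate_circuit(net, ps, constant_protocol(net, frac = 0.1,
                                                    n_cycles = 50))
  t2 <- simulate_circuit(net, ps, constant_protocol(net, frac = 0.2,
                                                    n_cycles = 50))
  end <- length(t1$times)
  expect_equal(unname(2 * t1$states[end, "mRNA_g1"]),
               unname(t2$states[end, "mRNA_g1"]),
               tolerance = 1e-5)
  expect_equal(unname(2 * t1$observables[end, 1]),
               unname(t2$observables[end, 1]),
               tolerance = 1e-5)
})

test_that("states stay non-negative under random protocols", {
  ps <- db_params()
  net <- make_iffl("CymR", FALSE)
  set.seed(99)
  for (i in 1:4) {
    fr <- matrix(stats::runif(8 * 3, 0, 0.33), 8, 3,
                 dimnames = list(NULL, net$names))
    proto <- inflow_protocol(fr, stats::setNames(rep(8, 3), net$names))
    traj <- simulate_circuit(net, ps, proto)
    expect_true(all(traj$states >= 0))
    expect_true(all(is.finite(traj$states)))
    expect_true(all(diff(traj$times) > 0))
  }
})
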