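test_that("IFFL variants share the activator and differ only in RiboJ", {
  net <- make_iffl("TetR", TRUE)
  expect_equal(net$names, c("p70a-S19", "p19a-RiboJ-TetR",
                            "p19aTetRO1-RiboJ-deGFP"))
  expect_equal(vapply(net$constructs, `[[`, "", "orf"),
               c("sigma19", "TetR", "deGFP"))
  plain <- make_iffl("TetR", FALSE)
  expect_false(plain$constructs[[2]]$riboj)
  expect_true(net$constructs[[2]]$riboj)
  # same activator object in every variant
  for (r in c("TetR", "CymR", "PhlF")) for (rj in c(TRUE, FALSE))
    expect_identical(make_iffl(r, rj)$constructs[[1]],
                     activator_construct())
  # matching operator for each repressor
  cym <- make_iffl("CymR", TRUE)
  expect_equal(cym$constructs[[3]]$operator, "CymRO1")
})

test_that("the characterization registry counts 13 experiments, 7 models", {
  reg <- experiment_registry()
  expect_equal(nrow(reg), 13)
  expect_equal(length(unique(reg$model)), 7)
  expect_equal(sum(reg$kind == "step"), 6)
  expect_equal(sum(reg$kind == "optimized"), 6)
  expect_equal(sum(reg$kind == "sigma19_pulse"), 1)
  expect_length(iffl_models(), 7)
})

test_that("prediction circuits assemble with the expected structure", {
  pd <- make_pulse_decoder()
  # 5 constructs: 4 x (DNA, mRNA, P) + reporter dark/mature split
  expect_length(pd$species, 16)
  expect_equal(pd$reporters, "p19aTetRO1-RiboJ-deGFP")
  bs <- make_bistable_switch()
  expect_length(bs$reporters, 2)
  # topology symmetric under TetR<->CymR, deGFP<->mmCherry
  ops <- vapply(bs$constructs, function(k)
    if (is.null(k$operator)) "" else k$operator, "")
  orfs <- vapply(bs$constructs, `[[`, "", "orf")
  expect_equal(ops[orfs == "CymR"], "TetRO1")
  expect_equal(ops[orfs == "TetR"], "CymRO1")
  expect_equal(ops[orfs == "deGFP"], "TetRO1")
  expect_equal(ops[orfs == "mmCherry"], "CymRO1")
})

test_that("with both repressors absent the bistable reporters co-express", {
  ps <- db_params()
  net <- make_bistable_switch()
  fr <- matrix(0.1, 30, 5, dimnames = list(NULL, net$names))
  fr[, c(2, 3)] <- 0                     # no repressor constructs
  proto <- inflow_protocol(fr, stats::setNames(rep(10, 5), net$names))
  traj <- simulate_circuit(net, ps, proto)
  end <- nrow(traj$observables)
  expect_gt(traj$observables[end, 1], 1)
  expect_gt(traj$observables[end, 2], 1)
})

test_that("switch classification counts hysteresis crossings", {
  t <- seq(0, 900, by = 22.5)
  # constant traces: a state but no switches
  traj <- fake_trajectory(t, rep(10, length(t)), rep(1, length(t)))
  expect_equal(as.integer(classify_switches(traj, c(100, 300))), 0)
  # one clean crossing
  g <- c(rep(10, 20), rep(0.5, 21)); m <- c(rep(0.5, 20), rep(10, 21))
  traj2 <- fake_trajectory(t, g, m)
  sw <- classify_switches(traj2, 22.5 * 19)
  expect_equal(as.integer(sw), 1)
  expect_true(all(attr(sw, "aligned")))
  # all-zero traces: undefined state
  traj3 <- fake_trajectory(t, rep(0, length(t)), rep(0, length(t)))
  expect_error(classify_switches(traj3, 100), "undefined state")
})

test_that("the triple-switch protocol pulses alternate constructs", {
  proto <- bistable_protocol()
  pt <- attr(proto, "pulse_times")
  expect_length(pt, 3)
  Tc <- proto$config$cycle_time
  cyc <- pt / Tc + 1
  fr <- proto$fractions
  # pulse 1 and 3 raise the TetR construct, pulse 2 the CymR construct
  expect_gt(fr[cyc[1], 3], fr[cyc[1] - 1, 3])
  expect_gt(fr[cyc[2], 2], fr[cyc[2] - 1, 2])
  expect_gt(fr[cyc[3], 3], fr[cyc[3] - 1, 3])
  # delivered pulse concentrations: 5 nM TetR construct, 2 nM CymR
  expect_equal(unname(fr[cyc[1], 3] * proto$stocks[3]), 5)
  expect_equal(unname(fr[cyc[2], 2] * proto$stocks[2]), 2)
  expect_true(all(rowSums(fr) <= 1 + 1e-12))
})

test_that("zero-duration pulses leave the decoder untouched", {
  ps <- db_params()
  curve <- pulse_response_curve(ps, cymr_nM = 0.5, durations = c(0, 67.5))
  expect_equal(curve$ratio[1], 1, tolerance = 1e-3)
  expect_lt(curve$ratio[2], curve$ratio[1])
  expect_gt(attr(curve, "baseline"), 1)
})

test_that("networks round-trip through YAML", {
  net <- make_pulse_decoder()
  f <- withr::local_tempfile(fileext = ".yaml")
  network_to_yaml(net, f)
  net2 <- network_from_yaml(f)
  expect_equal(net2$names, net$names)
  expect_equal(net2$species, net$species)
  expect_equal(vapply(net2$constructs, `[[`, "", "orf"),
               vapply(net$constructs, `[[`, "", "orf"))
})
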