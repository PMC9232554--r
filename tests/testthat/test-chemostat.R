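test_that("chemostat configuration validates its invariants", {
  expect_silent(chemostat_config())
  expect_error(chemostat_config(refresh_fraction = 0))
  expect_error(chemostat_config(refresh_fraction = 1.2))
  expect_error(chemostat_config(cycle_time = -1))
  cfg <- chemostat_config()
  expect_equal(cfg$lysate_fraction + cfg$dna_mq_fraction, 1)
})

test_that("inflow protocols validate fractions and stocks", {
  fr <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
               dimnames = list(NULL, c("a", "b")))
  p <- inflow_protocol(fr, c(a = 5, b = 10))
  expect_equal(p$n_cycles, 2)
  frsum <- matrix(c(0.6, 0.2, 0.7, 0.3), 2, 2,
                  dimnames = list(NULL, c("a", "b")))
  expect_error(inflow_protocol(frsum, c(a = 5, b = 10)), "exceed")
  fr2 <- fr; fr2[1, 1] <- -0.1
  expect_error(inflow_protocol(fr2, c(a = 5, b = 10)), "\\[0, 1\\]")
  expect_error(inflow_protocol(fr, c(a = 5)), "stocks missing")
})

test_that("inflow files round-trip exactly", {
  set.seed(4)
  fr <- matrix(stats::runif(9, 0, 1 / 3), 3, 3,
               dimnames = list(NULL, c("g1", "g2", "g3")))
  fr[2, ] <- c(1 / 3, 1 / 7, 1 / 9)   # non-terminating decimals
  stocks <- c(g1 = 5, g2 = 5, g3 = 2.5)
  p <- inflow_protocol(fr, stocks)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_inflow_file(p, f)
  q <- parse_inflow_file(f, stocks)
  expect_identical(q$fractions, p$fractions)
  expect_identical(q$stocks, p$stocks)
})

test_that("malformed inflow files fail with the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "0.1\t0.2", "0.3"), f)
  expect_error(parse_inflow_file(f, c(a = 1, b = 1)), "line 3")
  writeLines(c("a\tb", "0.6\t0.7"), f)
  expect_error(parse_inflow_file(f, c(a = 1, b = 1)), "sum > 1")
  writeLines(c("a\tb", "1.2\t0"), f)
  expect_error(parse_inflow_file(f, c(a = 1, b = 1)), "outside")
  writeLines("a\tb", f)   # empty body: valid, unsimulatable
  p <- parse_inflow_file(f, c(a = 1, b = 1))
  expect_equal(p$n_cycles, 0)
})

test_that("continuous controls give the expected steady state and decay", {
  fr <- matrix(0.3, 40, 1, dimnames = list(NULL, "g"))
  p <- inflow_protocol(fr, c(g = 10))
  tr <- realized_dna_trace(p, seq(0, 900, by = 22.5))
  expect_equal(unname(tr[nrow(tr), 1]), 0.3 * 10, tolerance = 1e-4)
  expect_true(all(tr <= 10 + 1e-9))          # never exceeds stock
  # zero inflow: pure exponential decay at RF / cycle_time
  p0 <- inflow_protocol(matrix(0, 10, 1, dimnames = list(NULL, "g")),
                        c(g = 10))
  tr0 <- realized_dna_trace(p0, c(0, 45, 90), dna0 = 4)
  lam <- 0.4 / 22.5
  expect_equal(unname(tr0[, 1]), 4 * exp(-lam * c(0, 45, 90)),
               tolerance = 1e-12)
})

test_that("the discrete replacement map shares the continuous fixed point", {
  ps <- db_params()
  net <- one_gene()
  proto <- constant_protocol(net, frac = 0.25, stock = 8, n_cycles = 30)
  trj <- simulate_circuit(net, ps, proto, mode = "discrete")
  # pre-replacement boundary DNA converges to IF * stock
  expect_equal(unname(trj$states[31, "DNA_g1"]), 0.25 * 8,
               tolerance = 1e-3)
  # continuous and discrete boundary traces agree within 5% after burn-in
  trc <- simulate_circuit(net, ps, proto, mode = "continuous")
  i <- 10:31
  expect_true(all(abs(trj$states[i, "DNA_g1"] - trc$states[i, "DNA_g1"]) /
                    trc$states[i, "DNA_g1"] < 0.05))
})

test_that("realized DNA traces match the full simulation", {
  ps <- db_params()
  net <- one_gene()
  fr <- matrix(c(rep(1, 2), rep(0, 10)), 12, 1,
               dimnames = list(NULL, "g1"))  # single pulse cycle then decay
  proto <- inflow_protocol(fr, c(g1 = 6))
  times <- seq(0, protocol_horizon(proto), by = 7.5)
  tr <- realized_dna_trace(proto, times)
  full <- simulate_circuit(net, ps, proto, t_obs = times,
                           rtol = 1e-11, atol = 1e-13)
  expect_equal(tr[, 1], unname(full$states[, "DNA_g1"]), tolerance = 1e-9)
  expect_true(max(tr) <= 6)                      # peak below stock
  expect_lt(tr[nrow(tr), 1], max(tr))            # rising-decaying transient
  expect_error(realized_dna_trace(proto, 1e5), "horizon")
})

test_that("identical protocol columns give identical DNA traces", {
  fr <- matrix(0.2, 6, 2, dimnames = list(NULL, c("a", "b")))
  p <- inflow_protocol(fr, c(a = 5, b = 5))
  tr <- realized_dna_trace(p, seq(0, 135, by = 22.5))
  expect_identical(tr[, "a"], tr[, "b"])
  p0 <- inflow_protocol(fr * 0, c(a = 5, b = 5))
  expect_true(all(realized_dna_trace(p0, c(0, 50, 100)) == 0))
})
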