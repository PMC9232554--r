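test_that("collinearity index has its analytic landmarks", {
  S <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))        # orthonormal
  expect_equal(collinearity_index(S), 1, tolerance = 1e-12)
  S2 <- cbind(a = c(1, 2, 3), b = 2 * c(1, 2, 3))   # duplicated direction
  expect_equal(as.numeric(collinearity_index(S2)), 1e6)
  expect_error(collinearity_index(S[, 1, drop = FALSE]), "at least 2")
})

test_that("an all-zero column flags structural unidentifiability", {
  S <- cbind(a = c(1, 1), b = c(0, 0))
  g <- collinearity_index(S)
  expect_equal(as.numeric(g), 1e6)
  expect_equal(attr(g, "structural"), "b")
})

test_that("gamma agrees with the brute-force Gram-matrix oracle", {
  gram_gamma <- function(S) {
    Sn <- sweep(S, 2, sqrt(colSums(S^2)), "/")
    1 / sqrt(min(eigen(crossprod(Sn), symmetric = TRUE)$values))
  }
  S <- cbind(a = c(1, 0), b = c(1, 1) / sqrt(2))
  expect_equal(as.numeric(collinearity_index(S)), gram_gamma(S),
               tolerance = 1e-10)
  set.seed(12)
  for (i in 1:8) {
    S <- matrix(stats::rnorm(40), 10, 4,
                dimnames = list(NULL, letters[1:4]))
    expect_equal(as.numeric(collinearity_index(S)), gram_gamma(S),
                 tolerance = 1e-8)
    sub <- sample(letters[1:4], 2)
    expect_equal(as.numeric(collinearity_index(S, sub)),
                 gram_gamma(S[, sub]), tolerance = 1e-8)
  }
})

test_that("gamma is invariant to parameter rescaling and self-pooling", {
  set.seed(3)
  S <- matrix(stats::rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b",
                                                               "c")))
  g0 <- as.numeric(collinearity_index(S))
  Ssc <- S; Ssc[, 2] <- 100 * Ssc[, 2]    # rescale one parameter
  expect_equal(as.numeric(collinearity_index(Ssc)), g0, tolerance = 1e-10)
  pooled <- pool_experiments(list(S, S))  # duplicate rows rescale uniformly
  expect_equal(as.numeric(collinearity_index(pooled)), g0,
               tolerance = 1e-10)
  zero <- matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(as.numeric(collinearity_index(pool_experiments(
    list(S, zero)))), g0, tolerance = 1e-10)
})

test_that("pooling RiboJ variants breaks the TX-TL collinearity", {
  ps <- db_params()
  pair <- c("kcat_TL_TetR_RiboJ", "kcat_TX_s19")
  e_rj <- experiment(make_iffl("TetR", TRUE),
                     iffl_step_protocol(make_iffl("TetR", TRUE),
                                        n_cycles = 16))
  e_no <- experiment(make_iffl("TetR", FALSE),
                     iffl_step_protocol(make_iffl("TetR", FALSE),
                                        n_cycles = 16))
  S_rj <- forward_sensitivities(e_rj, ps)
  S_no <- forward_sensitivities(e_no, ps)
  g_alone <- as.numeric(collinearity_index(S_rj, pair))
  g_pooled <- as.numeric(collinearity_index(
    pool_experiments(list(S_rj, S_no)), pair))
  expect_lt(g_pooled, g_alone)
})

test_that("category lumping averages, normalizes and flags gaps", {
  par <- c("kcat_TX_s70", "kd_s19", "kcat_TL_sigma19", "kcat_TL_deGFP",
           "kd_TetR", "n_TetR", "kdeg_TetR", "kdeg_deGFP")
  G <- matrix(3, 8, 8, dimnames = list(par, par)); diag(G) <- 1
  class(G) <- c("cfps_collinearity", "matrix")
  L <- lumped_collinearity(G)
  expect_equal(dim(L), c(4, 4))
  expect_true(all(L == 3))                      # uniform everywhere
  expect_true(all(lumped_collinearity(G, reference = L) == 1))
  # one empty category: dropped and flagged
  par2 <- par[1:6]
  G2 <- G[par2, par2]
  class(G2) <- c("cfps_collinearity", "matrix")
  L2 <- lumped_collinearity(G2)
  expect_false("K_deg" %in% rownames(L2))
  expect_equal(attr(L2, "dropped"), "K_deg")
  # unmapped parameter errors
  G3 <- G; rownames(G3)[1] <- colnames(G3)[1] <- "mystery"
  expect_error(lumped_collinearity(G3), "unmapped")
})

test_that("pairwise matrices are symmetric with unit diagonal", {
  set.seed(5)
  S <- matrix(stats::rnorm(50), 10, 5,
              dimnames = list(NULL, letters[1:5]))
  G <- pairwise_collinearity(S)
  expect_true(isSymmetric(unclass(G)))
  expect_equal(unname(diag(G)), rep(1, 5))
  expect_true(all(G >= 1 - 1e-12))
})
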