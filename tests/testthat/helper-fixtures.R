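# Shared fixtures: small circuits, protocols and parameter sets built in
# code at test time.

LAMBDA_DEFAULT <- 0.4 / 22.5

one_gene <- function() {
  network_spec(list(gene_construct("g1", "p70a", "deGFP", riboj = TRUE)))
}

db_params <- function() reference_params("database")

constant_protocol <- function(network, frac = 0.2, stock = 5,
                              n_cycles = 20) {
  nm <- network$names
  fr <- matrix(frac, n_cycles, length(nm), dimnames = list(NULL, nm))
  inflow_protocol(fr, stats::setNames(rep(stock, length(nm)), nm))
}

# analytic steady state of the unregulated p70a -> deGFP cascade under
# constant inflow (the independent oracle for the simulator)
cascade_steady_state <- function(params, dna, lambda = LAMBDA_DEFAULT) {
  mrna <- params[["kcat_TX_s70"]] * dna / (params[["kdeg_deGFP"]] + lambda)
  dark <- params[["kcat_TL_deGFP_RiboJ"]] * mrna /
    (params[["kmat_deGFP"]] + lambda)
  mat <- params[["kmat_deGFP"]] * dark / lambda
  c(dna = dna, mrna = mrna, dark = dark, mature = mat)
}

# tiny synthetic single-gene database (two inflow levels)
single_gene_db <- function(true_params, sd_abs = 0, sd_rel = 0, seed = 1,
                           n_cycles = 12) {
  net <- one_gene()
  exps <- lapply(c(0.1, 0.4), function(f) {
    experiment(net, constant_protocol(net, frac = f, n_cycles = n_cycles),
               name = paste0("gene_f", f))
  })
  generate_study(true_params, exps, sd_abs = sd_abs, sd_rel = sd_rel,
                 seed = seed)
}

fake_fit <- function(members, scores = seq_along(members) - 1,
                     free = names(members[[1]])) {
  structure(list(ensemble = members, scores = scores, free = free),
            class = "cfps_fit")
}

fake_trajectory <- function(times, deGFP, mmCherry) {
  obs <- cbind(`r-deGFP` = deGFP, `r-mmCherry` = mmCherry)
  structure(list(times = times, states = obs, observables = obs),
            class = "cfps_trajectory")
}
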