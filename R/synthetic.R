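# Synthetic ground-truth studies ------------------------------------------
#
# Stands in for the microfluidic measurements: every analysis stage of the
# package can be exercised against data whose generating parameters are
# known exactly.  Noise is additive truncated Gaussian on the mature
# reporter observables only (the instrument observes fluorescence), with
# sd = max(sd_abs, sd_rel * signal); observations are taken at cycle
# boundaries (one image per cycle).

#' Generate a synthetic experiment database with known truth
#'
#' Simulates every experiment in `experiments` at the true parameters, adds
#' measurement noise and clips at zero. Regeneration from the same seed and
#' configuration is bit-identical; the truth is stored as an attribute,
#' separate from the observations.
#'
#' @param true_params the generating `cfps_params`.
#' @param experiments list of [experiment()] objects (default: the full
#'   characterization registry, [registry_experiments()]).
#' @param sd_abs absolute noise floor in nM (default 5).
#' @param sd_rel relative noise (default 0.05).
#' @param seed RNG seed.
#' @return a `cfps_database` whose experiments carry noisy `observed`
#'   traces; attributes `truth` (the parameter set), `seed`, and
#'   `noiseless` (list of clean observable matrices).
#' @export
generate_study <- function(true_params,
                           experiments = registry_experiments(),
                           sd_abs = 5, sd_rel = 0.05, seed = 1) {
  stopifnot(sd_abs >= 0, sd_rel >= 0)
  set.seed(seed)
  clean <- list()
  out <- lapply(experiments, function(e) {
    sim <- simulate_experiment(e, true_params)
    clean[[e$name]] <<- sim
    sd <- pmax(sd_abs, sd_rel * sim)
    noisy <- sim + stats::rnorm(length(sim), 0, sd)
    noisy <- pmax(noisy, 0)
    if (sd_abs == 0 && sd_rel == 0) noisy <- sim
    dim(noisy) <- dim(sim); dimnames(noisy) <- dimnames(sim)
    experiment(e$network, protocol = e$protocol, batch = e$batch,
               t_obs = e$t_obs, observed = noisy, name = e$name)
  })
  db <- experiment_db(out, name = "synthetic study")
  attr(db, "truth") <- true_params
  attr(db, "seed") <- seed
  attr(db, "noiseless") <- clean
  db
}

#' Batch-series experiments for the identifiability comparison
#'
#' Five closed-reactor (no flow) experiments of the TetR IFFL sampling the
#' repressor-construct DNA concentration linearly from 0 to 1 nM, with
#' activator and reporter at 1 nM.
#' @param network the IFFL network (default TetR with RiboJ).
#' @param duration batch horizon in minutes (default 180).
#' @param dt observation interval (default 10 min).
#' @return list of five batch [experiment()]s.
#' @export
batch_series_experiments <- function(network = make_iffl("TetR", TRUE),
                                     duration = 180, dt = 10) {
  nm <- network$names
  lapply(seq(0, 1, length.out = 5), function(d) {
    dna0 <- stats::setNames(c(1, d, 1), nm)
    experiment(network, batch = list(dna0 = dna0, duration = duration),
               t_obs = seq(0, duration, by = dt),
               name = paste0("batch_TetR_", d))
  })
}

#' Sensitivity bundles for the four design scenarios
#'
#' Builds the relative sensitivity matrices that feed the identifiability
#' comparison across experimental designs: a batch dilution series of the
#' TetR IFFL (five experiments at different repressor-construct levels), a
#' single step-flow experiment, a single optimized-flow experiment, and the
#' 13-experiment database (step + optimized for all six IFFL variants plus
#' the sigma19 pulse) pooled as a whole.
#'
#' Each bundle is a list of sensitivity matrices, one per experiment that is
#' analysed individually; the database bundle contains a single pooled
#' matrix, since its point is precisely that the experiments are treated as
#' one collective rather than individually.
#'
#' @param params nominal `cfps_params` at which sensitivities are evaluated.
#' @param scenarios which bundles to compute (default all four).
#' @return named list of bundles (lists of sensitivity matrices).
#' @export
identifiability_scenarios <- function(params = reference_params("step"),
                                      scenarios = c("batch", "step",
                                                    "optimized",
                                                    "database")) {
  net <- make_iffl("TetR", TRUE)
  out <- list()
  if ("batch" %in% scenarios)
    out$batch <- lapply(batch_series_experiments(net),
                        forward_sensitivities, params = params)
  if ("step" %in% scenarios) {
    e <- experiment(net, iffl_step_protocol(net), name = "step")
    out$step <- list(forward_sensitivities(e, params))
  }
  if ("optimized" %in% scenarios) {
    e <- experiment(net, optimized_iffl_protocol(net), name = "optimized")
    out$optimized <- list(forward_sensitivities(e, params))
  }
  if ("database" %in% scenarios) {
    exps <- registry_experiments()
    S <- lapply(exps, forward_sensitivities, params = params)
    out$database <- list(pool_experiments(S))
  }
  out
}

#' Mean lumped collinearity per design scenario
#'
#' For every scenario bundle: pairwise collinearity over the TetR-IFFL
#' parameter subset is computed per experiment, category-lumped, and
#' averaged over the bundle's experiments (the pooled database bundle is a
#' single matrix). The lumped matrices are then normalized to the maximum
#' entry of the first scenario (conventionally batch).
#'
#' @param bundles output of [identifiability_scenarios()].
#' @param par_names parameter subset to compare (default: columns of the
#'   first bundle's first matrix).
#' @return list with `lumped` (list of matrices, normalized) and `mean`
#'   (named vector of mean lumped indices, unnormalized).
#' @export
scenario_collinearity <- function(bundles, par_names = NULL) {
  if (is.null(par_names)) par_names <- colnames(bundles[[1]][[1]])
  lump_of <- function(S) {
    G <- pairwise_collinearity(S, intersect(par_names, colnames(S)))
    lumped_collinearity(G)
  }
  Ls <- lapply(bundles, function(b) {
    mats <- lapply(b, lump_of)
    Reduce(`+`, mats) / length(mats)
  })
  ref <- Ls[[1]]
  lumped <- lapply(Ls, function(L) L / max(ref, na.rm = TRUE))
  means <- vapply(Ls, mean_lumped_index, 0.0)
  list(lumped = lumped, mean = means)
}
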