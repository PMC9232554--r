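# Ensemble database fitting ----------------------------------------------
#
# All experiments in a database are fitted simultaneously: parameters are
# global (shared across experiments by name), the objective is the sum of
# per-experiment normalized squared residuals plus a soft biophysical
# penalty on steady-state mRNA/DNA ratios, and the optimizer is a
# population search (differential evolution in log-parameter space, with
# optional islands and restarts) whose final population is kept as an
# ensemble of plausible parameter sets rather than collapsed to a point.

#' Assemble an experiment database
#'
#' @param experiments list of [experiment()] objects (all with `observed`
#'   traces for fitting; simulation-only databases are allowed elsewhere).
#' @param name database identifier.
#' @return object of class `cfps_database`.
#' @export
experiment_db <- function(experiments, name = "database") {
  if (inherits(experiments, "cfps_experiment"))
    experiments <- list(experiments)
  stopifnot(all(vapply(experiments, inherits, TRUE, "cfps_experiment")))
  structure(list(experiments = experiments, name = name,
                 n = length(experiments)),
            class = "cfps_database")
}

#' @export
print.cfps_database <- function(x, ...) {
  cat("Experiment database '", x$name, "': ", x$n, " experiments\n",
      sep = "")
  for (e in x$experiments)
    cat("  -", e$name, "(", if (is.null(e$protocol)) "batch" else "flow",
        ",", length(e$t_obs), "time points )\n")
  invisible(x)
}

#' Soft biophysical constraint on steady-state mRNA levels
#'
#' For every activated construct of every network, the fully induced
#' steady-state mRNA/DNA ratio ([steady_state_mrna_ratio()]) must lie in the
#' interval (2, 500). The penalty is a smooth quadratic hinge outside that
#' interval (zero at and inside the boundaries, enforced with tolerance
#' 1e-9) so that population search remains well-behaved.
#'
#' @param params a `cfps_params`.
#' @param networks a `cfps_network` or list thereof.
#' @param lambda dilution rate (1/min) at which the ratio is evaluated.
#' @param weight penalty weight (default 10).
#' @return scalar penalty >= 0.
#' @export
soft_constraint_penalty <- function(params, networks,
                                    lambda = 0.4 / 22.5, weight = 10) {
  if (inherits(networks, "cfps_network")) networks <- list(networks)
  pen <- 0
  for (net in networks) for (k in net$constructs) {
    r <- steady_state_mrna_ratio(k, params, lambda)
    lo <- max(0, 2 - r - 1e-9)
    hi <- max(0, r - 500 - 1e-9)
    pen <- pen + lo^2 + hi^2
  }
  weight * pen
}

#' Fitting objective for a parameter vector
#'
#' Weighted sum of squared residuals between simulated and observed
#' mature-reporter traces over every experiment, each observable column
#' normalized by its observed trace maximum (so reporters of different
#' brightness weigh comparably), plus [soft_constraint_penalty()].
#' Simulation failures yield a large finite penalty (1e8) so population
#' search can continue.
#'
#' @param db a [experiment_db()] whose experiments carry `observed` traces.
#' @param params a `cfps_params` (values within bounds).
#' @param penalty_weight weight of the soft constraint (default 10).
#' @param constraint apply the soft constraint (default TRUE).
#' @return scalar objective; lower is better.
#' @export
cfps_objective <- function(db, params, penalty_weight = 10,
                           constraint = TRUE) {
  total <- 0
  for (e in db$experiments) {
    if (is.null(e$observed)) stop("experiment '", e$name, "' has no data")
    sim <- try(simulate_experiment(e, params), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e8)
    obs <- e$observed
    sim <- sim[, colnames(obs), drop = FALSE]
    scale <- pmax(apply(obs, 2, max), 1e-9)
    res <- sweep(sim - obs, 2, scale, "/")
    if (!is.null(e$weights)) res <- res * e$weights
    total <- total + sum(res^2)
  }
  if (constraint) {
    lam <- 0.4 / 22.5
    for (e in db$experiments)
      if (!is.null(e$protocol)) {
        lam <- e$protocol$config$refresh_fraction /
          e$protocol$config$cycle_time
        break
      }
    nets <- lapply(db$experiments, `[[`, "network")
    total <- total + soft_constraint_penalty(params, nets, lam,
                                             penalty_weight)
  }
  total
}

# DE proposal in log space, clipped to bounds
de_propose <- function(logpop, i, F, CR, lo, hi) {
  n <- nrow(logpop)
  idx <- sample(setdiff(seq_len(n), i), 3)
  mut <- logpop[idx[1], ] + F * (logpop[idx[2], ] - logpop[idx[3], ])
  cross <- stats::runif(ncol(logpop)) < CR
  cross[sample(ncol(logpop), 1)] <- TRUE
  trial <- logpop[i, ]
  trial[cross] <- mut[cross]
  pmin(pmax(trial, lo), hi)
}

#' Fit shared kinetic parameters to an experiment database
#'
#' Simultaneous ensemble fit: a population of `n_agents` parameter vectors
#' evolves by differential-evolution proposals (DE/rand/1/bin) in
#' log-parameter space inside hard bounds, minimizing [cfps_objective()].
#' With `n_islands > 1` the population is split into islands that exchange
#' their best member every `migrate_every` generations; stagnating islands
#' are restarted from fresh random draws. The final population is returned
#' as a scored ensemble - the method deliberately keeps distributions, not a
#' point estimate.
#'
#' @param db a [experiment_db()] with observed traces.
#' @param free names of the free parameters (default: every non-`kmat`
#'   parameter used by the database's networks).
#' @param start a `cfps_params` supplying fixed values and bounds (default
#'   [reference_params()]'s database column).
#' @param bounds optional bounds matrix overriding `start`'s for the free
#'   parameters.
#' @param n_agents population size (>= 20, default 40).
#' @param n_rounds DE generations (default 60).
#' @param seed RNG seed (recorded in the result).
#' @param F,CR differential weight and crossover rate.
#' @param n_islands,migrate_every island-model topology (defaults 1, 10).
#' @param keep_factor ensemble membership: agents within `keep_factor` times
#'   the best objective (plus a small absolute slack) are kept; at least 10
#'   members are always retained.
#' @param penalty_weight soft-constraint weight.
#' @param verbose print progress.
#' @return object of class `cfps_fit`; see [summary.cfps_fit()],
#'   [predict.cfps_fit()], [distribution_width()].
#' @export
cfps_fit <- function(db, free = NULL, start = reference_params("database"),
                     bounds = NULL, n_agents = 40, n_rounds = 60, seed = 1,
                     F = 0.7, CR = 0.9, n_islands = 1, migrate_every = 10,
                     keep_factor = 2, penalty_weight = 10, verbose = FALSE) {
  stopifnot(inherits(db, "cfps_database"))
  if (n_agents < 20) stop("n_agents must be >= 20")
  if (is.null(free)) {
    free <- unique(unlist(lapply(db$experiments, function(e)
      used_parameters(e$network, start))))
  }
  b <- param_bounds(start)[free, , drop = FALSE]
  if (!is.null(bounds)) b[rownames(bounds), ] <- bounds
  lo <- log(b[, 1]); hi <- log(b[, 2])
  set.seed(seed)
  obj_of <- function(logv) {
    ps <- update_params(start, stats::setNames(exp(logv), free),
                        validate = FALSE)
    cfps_objective(db, ps, penalty_weight)
  }
  nf <- length(free)
  logpop <- matrix(stats::runif(n_agents * nf, rep(lo, each = n_agents),
                                rep(hi, each = n_agents)),
                   n_agents, nf, dimnames = list(NULL, free))
  scores <- apply(logpop, 1, obj_of)
  if (all(!is.finite(scores)) || all(scores >= 1e8))
    stop("fitting failure: no agent attained a finite objective")
  island <- rep(seq_len(n_islands), length.out = n_agents)
  stagnation <- rep(0, n_islands)
  best_hist <- numeric(n_rounds)
  # archive of agents from the later rounds: along flat (poorly identified)
  # directions the population drifts, and the archive records that spread
  archive_from <- ceiling(n_rounds / 2)
  arch_pop <- NULL; arch_scores <- NULL
  for (g in seq_len(n_rounds)) {
    for (isl in seq_len(n_islands)) {
      members <- which(island == isl)
      sub <- logpop[members, , drop = FALSE]
      if (nrow(sub) < 4) sub <- logpop
      for (i in members) {
        trial <- de_propose(sub, match(i, members, nomatch = 1), F, CR,
                            lo, hi)
        sc <- obj_of(trial)
        if (sc <= scores[i]) { logpop[i, ] <- trial; scores[i] <- sc }
      }
    }
    if (n_islands > 1 && g %% migrate_every == 0) {
      gb <- which.min(scores)
      for (isl in seq_len(n_islands)) {
        members <- which(island == isl)
        ib <- members[which.min(scores[members])]
        if (min(scores[members]) > 1.5 * scores[gb]) {
          stagnation[isl] <- stagnation[isl] + 1
          worst <- members[which.max(scores[members])]
          if (stagnation[isl] >= 2) {  # restart stagnating island member
            logpop[worst, ] <- stats::runif(length(free), lo, hi)
            scores[worst] <- obj_of(logpop[worst, ])
            stagnation[isl] <- 0
          } else {
            logpop[worst, ] <- logpop[gb, ]
            scores[worst] <- scores[gb]
          }
        }
      }
    }
    best_hist[g] <- min(scores)
    if (g >= archive_from) {
      arch_pop <- rbind(arch_pop, logpop)
      arch_scores <- c(arch_scores, scores)
    }
    if (verbose && g %% 10 == 0)
      message("generation ", g, ": best objective ", signif(min(scores), 4))
  }
  dup <- duplicated(arch_pop)
  if (sum(!dup) >= 10) {        # degenerate fits keep duplicate agents
    arch_pop <- arch_pop[!dup, , drop = FALSE]
    arch_scores <- arch_scores[!dup]
  }
  ord <- order(arch_scores)
  arch_pop <- arch_pop[ord, , drop = FALSE]; arch_scores <- arch_scores[ord]
  keep <- arch_scores <= keep_factor * arch_scores[1] + 1e-8
  keep[seq_len(min(10, length(arch_scores)))] <- TRUE
  members <- lapply(which(keep), function(i)
    update_params(start, stats::setNames(exp(arch_pop[i, ]), free),
                  validate = FALSE))
  structure(list(ensemble = members, scores = arch_scores[keep],
                 free = free, bounds = b, start = start, db = db,
                 seed = seed, n_agents = n_agents, n_rounds = n_rounds,
                 history = best_hist),
            class = "cfps_fit")
}

#' @export
print.cfps_fit <- function(x, ...) {
  cat("CFPS ensemble fit\n")
  cat("  experiments :", x$db$n, "\n")
  cat("  free params :", length(x$free), "\n")
  cat("  agents      :", x$n_agents, "x", x$n_rounds, "generations (seed ",
      x$seed, ")\n")
  cat("  best score  :", signif(x$scores[1], 5), "\n")
  cat("  ensemble    :", length(x$ensemble), "members\n")
  invisible(x)
}

#' Summarize a fitted ensemble
#'
#' Per free parameter: best member's value, ensemble mean, minimum, maximum
#' and (for ensembles of >= 10 members) the distribution width
#' (mean of the five highest over mean of the five lowest values).
#' @param object a `cfps_fit`.
#' @param ... unused.
#' @return data frame, one row per free parameter.
#' @export
summary.cfps_fit <- function(object, ...) {
  M <- ensemble_matrix(object)
  width <- if (nrow(M) >= 10)
    apply(M, 2, distribution_width) else rep(NA_real_, ncol(M))
  out <- data.frame(best = M[1, ], mean = colMeans(M),
                    min = apply(M, 2, min), max = apply(M, 2, max),
                    width = width,
                    category = param_categories(colnames(M)),
                    row.names = colnames(M))
  class(out) <- c("summary.cfps_fit", "data.frame")
  out
}

#' @export
print.summary.cfps_fit <- function(x, ...) {
  cat("Ensemble parameter summary\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Ensemble as a members x parameters matrix
#' @param fit a `cfps_fit`.
#' @return numeric matrix (rows ordered by objective score).
#' @export
ensemble_matrix <- function(fit) {
  M <- do.call(rbind, lapply(fit$ensemble, function(ps)
    as.numeric(ps[fit$free])))
  colnames(M) <- fit$free
  M
}

#' @export
coef.cfps_fit <- function(object, type = c("best", "mean"), ...) {
  type <- match.arg(type)
  M <- ensemble_matrix(object)
  if (type == "best") M[1, ] else colMeans(M)
}

#' @export
residuals.cfps_fit <- function(object, ...) {
  ps <- object$ensemble[[1]]
  lapply(object$db$experiments, function(e) {
    sim <- simulate_experiment(e, ps)
    sim[, colnames(e$observed), drop = FALSE] - e$observed
  })
}

#' Predict a circuit's response from a fitted ensemble
#'
#' Thin wrapper around [prediction_band()]: simulates the requested network
#' and protocol with the best-scoring quantile of ensemble members.
#' @param object a `cfps_fit`.
#' @param network a `cfps_network`.
#' @param protocol a `cfps_protocol`.
#' @param quantile fraction of best-scoring members used (default 0.25).
#' @param ... passed to the simulator.
#' @return a `cfps_band` (see [prediction_band()]).
#' @export
predict.cfps_fit <- function(object, network, protocol, quantile = 0.25,
                             ...) {
  prediction_band(object, network, protocol, quantile = quantile, ...)
}

#' @export
simulate.cfps_fit <- function(object, nsim = 1, seed = NULL,
                              network = NULL, protocol = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(network)) {
    e <- object$db$experiments[[1]]
    network <- e$network; protocol <- e$protocol
  }
  idx <- sample(length(object$ensemble), nsim, replace = TRUE)
  lapply(idx, function(i)
    simulate_circuit(network, object$ensemble[[i]], protocol, ...))
}

#' @export
plot.cfps_fit <- function(x, which = 1, ...) {
  e <- x$db$experiments[[which]]
  band <- prediction_band(x, e$network, e$protocol, quantile = 0.25)
  plot(band, ...)
  if (!is.null(e$observed))
    graphics::matpoints(e$t_obs, e$observed, pch = 1)
  invisible(x)
}

# Ensemble summaries ------------------------------------------------------

#' Distribution width of a fitted parameter
#'
#' The ratio of the mean of the five highest to the mean of the five lowest
#' values in the distribution; the package's precision metric for a
#' parameter ensemble. Requires at least 10 values.
#'
#' @param x numeric vector of ensemble values, or a `cfps_fit`.
#' @param parameter parameter name (when `x` is a fit).
#' @return scalar width >= 1 (up to numerical noise for near-constant
#'   distributions).
#' @export
distribution_width <- function(x, parameter = NULL) {
  if (inherits(x, "cfps_fit")) {
    stopifnot(!is.null(parameter))
    x <- ensemble_matrix(x)[, parameter]
  }
  if (length(x) < 10)
    stop("distribution width needs >= 10 ensemble members")
  s <- sort(x)
  mean(utils::tail(s, 5)) / mean(utils::head(s, 5))
}

#' Category-averaged, normalized distribution widths
#'
#' Widths are computed per parameter, averaged within each lumped category
#' and optionally normalized to a reference ensemble (conventionally the
#' individual step-calibration fits).
#'
#' @param fit a `cfps_fit` (>= 10 ensemble members).
#' @param reference optional `cfps_fit` or named numeric vector of reference
#'   category widths.
#' @return named numeric vector over categories.
#' @export
category_widths <- function(fit, reference = NULL) {
  M <- ensemble_matrix(fit)
  w <- apply(M, 2, distribution_width)
  cat <- param_categories(colnames(M))
  out <- tapply(w, cat, mean)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "cfps_fit"))
      category_widths(reference) else reference
    out <- out / ref[names(out)]
  }
  out[!is.na(names(out))]
}

#' Infer the RiboJ translation-enhancement factor
#'
#' The median ratio of with-RiboJ to without-RiboJ translation rates across
#' characterized ORF pairs; used to extrapolate translation rates of parts
#' never measured with the insulator (see [apply_riboj_factor()]).
#'
#' @param with_riboj,without_riboj positive numeric vectors of paired rates,
#'   or `with_riboj` may be a `cfps_fit` (pairs are then extracted from the
#'   best member's repressor translation rates).
#' @return scalar factor.
#' @export
riboj_factor <- function(with_riboj, without_riboj = NULL) {
  if (inherits(with_riboj, "cfps_fit")) {
    ps <- with_riboj$ensemble[[1]]
    orfs <- .REPRESSORS[paste0("kcat_TL_", .REPRESSORS, "_RiboJ") %in%
                          names(ps) &
                        paste0("kcat_TL_", .REPRESSORS) %in% names(ps)]
    with_riboj <- as.numeric(ps[paste0("kcat_TL_", orfs, "_RiboJ")])
    without_riboj <- as.numeric(ps[paste0("kcat_TL_", orfs)])
  }
  stopifnot(length(with_riboj) == length(without_riboj),
            length(with_riboj) >= 1)
  if (any(with_riboj <= 0) || any(without_riboj <= 0))
    stop("translation rates must be > 0")
  stats::median(with_riboj / without_riboj)
}

#' Ensemble prediction band for a circuit
#'
#' Simulates every member of the best-scoring `quantile` fraction of the
#' ensemble under the given protocol and returns the pointwise mean and
#' standard deviation of the observables.
#'
#' @param fit a `cfps_fit`.
#' @param network a `cfps_network`.
#' @param protocol a `cfps_protocol`.
#' @param quantile fraction in (0, 1] of best members used (default 0.25).
#' @param t_obs observation grid (default cycle boundaries).
#' @param ... passed to the simulator.
#' @return object of class `cfps_band`: `times`, `mean`, `sd`
#'   (time x observable matrices) and `n_members`.
#' @export
prediction_band <- function(fit, network, protocol, quantile = 0.25,
                            t_obs = NULL, ...) {
  stopifnot(quantile > 0, quantile <= 1)
  n_use <- max(1, floor(quantile * length(fit$ensemble)))
  members <- fit$ensemble[seq_len(n_use)]   # ensemble is score-sorted
  if (length(members) == 0) stop("empty quantile slice")
  sims <- lapply(members, function(ps)
    simulate_circuit(network, ps, protocol, t_obs = t_obs, ...)$observables)
  times <- if (is.null(t_obs))
    seq(0, protocol_horizon(protocol), by = protocol$config$cycle_time)
  else sort(unique(t_obs))
  arr <- simplify2array(sims)           # time x obs x member
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  if (length(members) == 1) s[] <- 0
  dimnames(m) <- dimnames(s) <- dimnames(sims[[1]])
  structure(list(times = times, mean = m, sd = s,
                 n_members = length(members)),
            class = "cfps_band")
}

#' @export
print.cfps_band <- function(x, ...) {
  cat("Prediction band:", x$n_members, "ensemble members,",
      length(x$times), "time points,", ncol(x$mean), "observable(s)\n")
  invisible(x)
}

#' @export
plot.cfps_band <- function(x, ...) {
  k <- ncol(x$mean)
  graphics::matplot(x$times, x$mean, type = "l", lty = 1,
                    ylim = range(0, x$mean + 2 * x$sd),
                    xlab = "time (min)", ylab = "mature reporter (nM)", ...)
  for (j in seq_len(k))
    graphics::polygon(c(x$times, rev(x$times)),
                      c(x$mean[, j] + x$sd[, j],
                        rev(x$mean[, j] - x$sd[, j])),
                      col = grDevices::adjustcolor(j, 0.2), border = NA)
  invisible(x)
}
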