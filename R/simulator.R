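# Numerical integration of circuits under inflow protocols --------------

.sim_defaults <- list(rtol = 1e-8, atol = 1e-10)

resolve_system <- function(object, params) {
  if (inherits(object, "cfps_ode"))
    list(comp = object$comp, p = object$p, network = object$network)
  else if (inherits(object, "cfps_network")) {
    comp <- compile_network(object, params)
    p <- as.numeric(params); names(p) <- names(params)
    list(comp = comp, p = p, network = object)
  } else stop("expected a cfps_network or cfps_ode")
}

new_trajectory <- function(times, states, comp, network) {
  rep_i <- which(comp$reporter)
  obs <- states[, comp$iPm[rep_i], drop = FALSE]
  colnames(obs) <- network$names[rep_i]
  structure(list(times = times, states = states, observables = obs),
            class = "cfps_trajectory")
}

#' @export
print.cfps_trajectory <- function(x, ...) {
  cat("CFPS trajectory:", length(x$times), "time points,",
      ncol(x$states), "species,", ncol(x$observables), "observable(s)\n")
  invisible(x)
}

#' @export
plot.cfps_trajectory <- function(x, which = colnames(x$observables), ...) {
  obs <- x$observables[, which, drop = FALSE]
  graphics::matplot(x$times, obs, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "mature reporter (nM)", ...)
  graphics::legend("topleft", legend = colnames(obs), lty = 1,
                   col = seq_len(ncol(obs)), bty = "n")
  invisible(x)
}

segment_integrate <- function(y, times, comp, p, kin, lambda, rtol, atol,
                              cycle) {
  sol <- try(deSolve::lsoda(y, times, make_rhs(comp, p, kin, lambda),
                            parms = NULL, rtol = rtol, atol = atol),
             silent = TRUE)
  ok <- !inherits(sol, "try-error") && nrow(sol) == length(times) &&
    all(is.finite(sol[, -1]))
  if (!ok) {
    bad <- if (inherits(sol, "try-error")) "integrator error" else {
      i <- which(!is.finite(sol[nrow(sol), -1]))
      paste("non-finite state:",
            paste(comp$species[i], collapse = ", "))
    }
    stop("integration failed in cycle ", cycle, " (", bad, ")",
         call. = FALSE)
  }
  sol
}

#' Simulate a circuit under an inflow protocol
#'
#' Integrates the CFPS ODEs with stiff-aware `lsoda`, restarting at every
#' refresh-cycle boundary so that the piecewise-constant controls are honored
#' exactly. Default observation grid is the cycle boundaries (one image per
#' cycle). In `"discrete"` mode the per-cycle replacement map is applied at
#' each cycle start (after the boundary observation, mirroring the
#' image-then-load hardware sequence) and no continuous dilution acts within
#' the cycle.
#'
#' @param object a `cfps_network` or prebuilt [build_ode_system()] result.
#' @param params a `cfps_params` (ignored if `object` is a `cfps_ode`).
#' @param protocol a `cfps_protocol`.
#' @param t_obs observation times in minutes (within the protocol horizon);
#'   default: cycle boundaries.
#' @param y0 initial state (default all-zero).
#' @param mode `"continuous"` or `"discrete"` chemostat dynamics.
#' @param rtol,atol integrator tolerances (defaults 1e-8 / 1e-10).
#' @return a `cfps_trajectory`: `times`, `states` (time x species matrix) and
#'   `observables` (time x mature-reporter matrix, nM).
#' @export
simulate_circuit <- function(object, params = NULL, protocol, t_obs = NULL,
                             y0 = NULL, mode = c("continuous", "discrete"),
                             rtol = .sim_defaults$rtol,
                             atol = .sim_defaults$atol) {
  mode <- match.arg(mode)
  sys <- resolve_system(object, params)
  comp <- sys$comp; p <- sys$p
  net <- sys$network
  if (!all(colnames(protocol$fractions) %in% net$names))
    stop("protocol columns not in network: ",
         paste(setdiff(colnames(protocol$fractions), net$names),
               collapse = ", "))
  Tc <- protocol$config$cycle_time
  H <- protocol_horizon(protocol)
  if (is.null(t_obs)) t_obs <- seq(0, H, by = Tc)
  t_obs <- sort(unique(t_obs))
  if (any(t_obs < 0 | t_obs > H + 1e-9))
    stop("t_obs beyond the protocol horizon")
  ctrl <- protocol_to_controls(protocol, mode)
  # map protocol columns onto the network's DNA inflow slots
  kin_full <- function(cycle) {
    v <- rep(0, comp$n); names(v) <- net$names
    v[colnames(protocol$fractions)] <- ctrl$kin(cycle)
    unname(v)
  }
  input_full <- function(cycle) {
    v <- rep(0, comp$n); names(v) <- net$names
    v[colnames(protocol$fractions)] <- ctrl$dna_input(cycle)
    unname(v)
  }
  ns <- length(comp$species)
  if (is.null(y0)) y0 <- rep(0, ns)
  stopifnot(length(y0) == ns)
  states <- matrix(NA_real_, length(t_obs), ns,
                   dimnames = list(NULL, comp$species))
  y <- y0
  hit <- which(t_obs <= 0 + 1e-12)
  for (k in hit) states[k, ] <- y
  if (protocol$n_cycles > 0) for (j in 0:(protocol$n_cycles - 1)) {
    t0 <- j * Tc; t1 <- (j + 1) * Tc
    if (mode == "discrete") {
      RF <- ctrl$refresh_fraction
      inc <- rep(0, ns)
      inc[comp$iDNA] <- input_full(j)
      y <- (1 - RF) * y + RF * inc
      kin <- rep(0, comp$n); lam <- 0
    } else {
      kin <- kin_full(j); lam <- ctrl$lambda
    }
    inner <- t_obs[t_obs > t0 + 1e-12 & t_obs <= t1 + 1e-12]
    tt <- unique(c(t0, inner, t1))
    sol <- segment_integrate(y, tt, comp, p, kin, lam, rtol, atol, j)
    if (length(inner)) {
      rows <- match(round(inner, 10), round(tt, 10))
      states[match(inner, t_obs), ] <- sol[rows, -1, drop = FALSE]
    }
    y <- sol[nrow(sol), -1]
  }
  states[states < 0 & states > -1e-12] <- 0
  new_trajectory(t_obs, states, comp, net)
}

#' Simulate a batch (no-flow) reaction
#'
#' Closed-reactor mode: dilution and inflow are zero, initial DNA
#' concentrations are fixed and expression proceeds from a clean lysate.
#'
#' @param network a `cfps_network`.
#' @param params a `cfps_params`.
#' @param dna0 named initial DNA concentrations in nM (constructs absent from
#'   `dna0` start at 0).
#' @param times observation times in minutes.
#' @inheritParams simulate_circuit
#' @return a `cfps_trajectory`.
#' @export
simulate_batch <- function(network, params, dna0, times,
                           rtol = .sim_defaults$rtol,
                           atol = .sim_defaults$atol) {
  sys <- resolve_system(network, params)
  comp <- sys$comp
  ns <- length(comp$species)
  y0 <- rep(0, ns)
  dna0 <- unlist(dna0)
  stopifnot(all(names(dna0) %in% network$names))
  y0[comp$iDNA[match(names(dna0), network$names)]] <- dna0
  times <- sort(unique(c(0, times)))
  sol <- segment_integrate(y0, times, comp, sys$p, rep(0, comp$n), 0,
                           rtol, atol, "batch")
  keep <- seq_along(times)
  states <- sol[keep, -1, drop = FALSE]
  colnames(states) <- comp$species
  new_trajectory(times, states, comp, network)
}

# Experiments -------------------------------------------------------------

#' Bundle a network, a protocol and (optionally) observed traces
#'
#' The unit of the experiment database: flow experiments carry an inflow
#' protocol, batch experiments a `batch = list(dna0, duration)`
#' specification. Observed reporter traces (matrix `[time x reporter]`,
#' nM) sampled at `t_obs` turn the experiment into fitting data.
#'
#' @param network a `cfps_network`.
#' @param protocol a `cfps_protocol`, or `NULL` for batch.
#' @param batch list with `dna0` (named nM) and `duration` (min); only when
#'   `protocol` is `NULL`.
#' @param t_obs observation times (default: cycle boundaries, or every
#'   10 min for batch).
#' @param observed optional matrix of measured mature-reporter traces with
#'   one column per reporter construct name.
#' @param weights optional per-observation weights (same shape as
#'   `observed`).
#' @param name experiment identifier.
#' @return object of class `cfps_experiment`.
#' @export
experiment <- function(network, protocol = NULL, batch = NULL, t_obs = NULL,
                       observed = NULL, weights = NULL, name = "experiment") {
  stopifnot(inherits(network, "cfps_network"),
            xor(is.null(protocol), is.null(batch)))
  if (is.null(t_obs)) {
    t_obs <- if (!is.null(protocol))
      seq(0, protocol_horizon(protocol), by = protocol$config$cycle_time)
    else seq(0, batch$duration, by = 10)
  }
  if (!is.null(observed)) {
    observed <- as.matrix(observed)
    stopifnot(nrow(observed) == length(t_obs),
              all(colnames(observed) %in% network$reporters))
  }
  structure(list(network = network, protocol = protocol, batch = batch,
                 t_obs = t_obs, observed = observed, weights = weights,
                 name = name),
            class = "cfps_experiment")
}

#' Simulate an experiment's observables
#' @param exp a [experiment()].
#' @param params a `cfps_params`.
#' @param ... passed to the simulator.
#' @return matrix `[t_obs x reporter]` of mature reporter concentrations.
#' @export
simulate_experiment <- function(exp, params, ...) {
  traj <- if (!is.null(exp$protocol))
    simulate_circuit(exp$network, params, exp$protocol, t_obs = exp$t_obs,
                     ...)
  else
    simulate_batch(exp$network, params, exp$batch$dna0, exp$t_obs, ...)
  traj$observables[match(exp$t_obs, traj$times), , drop = FALSE]
}

# Sensitivities -----------------------------------------------------------

#' Relative forward parameter sensitivities of an experiment
#'
#' Central finite differences on log-parameters: column `theta` holds
#' `(dy/d log theta) / max(|y|, floor)` flattened over time points and
#' observables, i.e. the relative sensitivity `(dy/dtheta) (theta/y)` with a
#' guarded denominator. Rates in this problem span orders of magnitude, so
#' the log parameterization keeps steps well-scaled.
#'
#' @param exp a [experiment()].
#' @param params a `cfps_params`.
#' @param par_names parameters to differentiate (default: every non-`kmat`
#'   parameter the experiment's network uses).
#' @param rel_step relative finite-difference step on log-parameters
#'   (default 1e-4).
#' @param floor denominator guard in nM (default 1e-9).
#' @param ... passed to the simulator.
#' @return matrix `[time*observable x parameter]` of class
#'   `cfps_sensitivity` with attributes `par_names`, `times`, `observables`.
#' @export
forward_sensitivities <- function(exp, params, par_names = NULL,
                                  rel_step = 1e-4, floor = 1e-9, ...) {
  if (is.null(par_names))
    par_names <- used_parameters(exp$network, params)
  stopifnot(all(par_names %in% names(params)))
  y0 <- simulate_experiment(exp, params, ...)
  S <- matrix(NA_real_, length(y0), length(par_names),
              dimnames = list(NULL, par_names))
  denom <- pmax(abs(as.numeric(y0)), floor)
  v <- as.numeric(params); names(v) <- names(params)
  for (th in par_names) {
    up <- v; up[th] <- v[th] * exp(rel_step)
    dn <- v; dn[th] <- v[th] * exp(-rel_step)
    yu <- simulate_experiment(exp, update_params(params, up[th],
                                                 validate = FALSE), ...)
    yd <- simulate_experiment(exp, update_params(params, dn[th],
                                                 validate = FALSE), ...)
    col <- (as.numeric(yu) - as.numeric(yd)) / (2 * rel_step) / denom
    if (any(!is.finite(col)))
      stop("non-finite sensitivity for parameter ", th)
    S[, th] <- col
  }
  structure(S, class = c("cfps_sensitivity", "matrix"),
            par_names = par_names, times = exp$t_obs,
            observables = colnames(y0))
}

#' Parameters a network actually uses
#' @param network a `cfps_network`.
#' @param params a `cfps_params`.
#' @param include_fixed include `kmat_*` maturation constants (default
#'   FALSE).
#' @return character vector of parameter names.
#' @export
used_parameters <- function(network, params, include_fixed = FALSE) {
  comp <- compile_network(network, params)
  idx <- c(comp$i_kcatTX, comp$i_kd19, comp$i_kcatTL, comp$i_kdeg,
           comp$i_kdrep, comp$i_nrep,
           if (include_fixed) comp$i_kmat)
  nm <- names(params)[sort(unique(idx[!is.na(idx)]))]
  nm
}

# Trajectory CSV export ---------------------------------------------------

#' Write a trajectory as tidy CSV
#'
#' Columns `time_min`, `species`, `value_nM`; a provenance comment header
#' records the tool version.
#' @param traj a `cfps_trajectory`.
#' @param path file path.
#' @param observables_only export only mature reporters (default FALSE).
#' @export
write_trajectory_csv <- function(traj, path, observables_only = FALSE) {
  m <- if (observables_only) traj$observables else traj$states
  df <- data.frame(time_min = rep(traj$times, ncol(m)),
                   species = rep(colnames(m), each = nrow(m)),
                   value_nM = as.numeric(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cfpsflow ",
                    as.character(utils::packageVersion("cfpsflow"))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
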