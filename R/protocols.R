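# Canonical experiments: registry, calibration patterns, predictions ----
#
# Concentration conventions used throughout the packaged experiments
# (chosen once as realistic chemostat operating points): DNA stocks of 10 nM
# for activator, repressor and reporter templates, held at 1 nM working
# concentration via a constant inflow fraction of 0.1; the step calibration
# switches the repressor construct on (0 -> 1 nM) mid-experiment.  Pulses in
# the prediction circuits are specified by the concentration they deliver
# (inflow fraction x stock): 5 nM PhlF pulses, 2 / 5 nM bistable pulses.
# Fractions of all constructs plus MQ must share one refreshed volume, so a
# holding fraction of 0.1 leaves room for large pulses in the same cycle.

.STOCK_DEFAULT <- 10
.IF_HOLD <- 0.1      # 1 nM working concentration at 10 nM stock

iffl_colnames <- function(network) network$names  # activator, repressor, reporter

#' Canonical step-calibration inflow pattern for a three-construct circuit
#'
#' Activator and reporter held at a constant working concentration; the
#' repressor column steps from 0 to the working concentration at
#' `step_cycle`.
#' @param network a three-construct `cfps_network` (IFFL).
#' @param n_cycles number of cycles (default 32).
#' @param step_cycle 0-based cycle at which the repressor turns on
#'   (default 12).
#' @param config chemostat configuration.
#' @return a `cfps_protocol`.
#' @export
iffl_step_protocol <- function(network, n_cycles = 32, step_cycle = 12,
                               config = chemostat_config()) {
  nm <- iffl_colnames(network)
  stopifnot(length(nm) == 3)
  fr <- matrix(.IF_HOLD, n_cycles, 3, dimnames = list(NULL, nm))
  fr[seq_len(min(step_cycle, n_cycles)), 2] <- 0
  inflow_protocol(fr, stats::setNames(rep(.STOCK_DEFAULT, 3), nm), config)
}

#' Sigma19 activation pulse pattern
#'
#' Activator inflow pulsed (4 cycles on, 6 off) against a constantly
#' supplied unregulated reporter; the calibration experiment for the
#' sigma19 expression model.
#' @param network the [make_sigma19_model()] network.
#' @param n_cycles number of cycles (default 36).
#' @param config chemostat configuration.
#' @return a `cfps_protocol`.
#' @export
sigma19_pulse_protocol <- function(network = make_sigma19_model(),
                                   n_cycles = 36,
                                   config = chemostat_config()) {
  nm <- network$names
  fr <- matrix(0, n_cycles, 2, dimnames = list(NULL, nm))
  phase <- (seq_len(n_cycles) - 1) %% 10
  fr[phase < 4, 1] <- .IF_HOLD
  fr[, 2] <- .IF_HOLD
  inflow_protocol(fr, stats::setNames(rep(.STOCK_DEFAULT, 2), nm), config)
}

#' The packaged information-optimized IFFL inflow pattern
#'
#' A single optimized pattern, found once with [optimize_design()]
#' (D-criterion, step-column nominal parameters, 5%-level grid) and applied
#' to every IFFL variant; shipped as a plain-text inflow file under
#' `inst/extdata`.
#' @param network a three-construct IFFL network whose construct names label
#'   the columns.
#' @param config chemostat configuration.
#' @return a `cfps_protocol`.
#' @export
optimized_iffl_protocol <- function(network, config = chemostat_config()) {
  path <- system.file("extdata", "iffl_optimized_pattern.tsv",
                      package = "cfpsflow", mustWork = TRUE)
  nm <- iffl_colnames(network)
  stopifnot(length(nm) == 3)
  p <- parse_inflow_file(path,
                         stats::setNames(rep(.STOCK_DEFAULT, 3),
                                         c("activator", "repressor",
                                           "reporter")))
  colnames(p$fractions) <- nm
  names(p$stocks) <- nm
  p$config <- config
  p
}

# Registry ----------------------------------------------------------------

#' The seven packaged circuit models
#' @return named list of `cfps_network`s: six IFFL variants plus the
#'   sigma19 expression model.
#' @export
iffl_models <- function() {
  out <- list()
  for (r in .REPRESSORS) for (rj in c(TRUE, FALSE))
    out[[paste0("IFFL_", r, if (rj) "_RiboJ")]] <- make_iffl(r, rj)
  out$SIGMA19 <- make_sigma19_model()
  out
}

#' Registry of the characterization-phase experiments
#'
#' Enumerates the characterization design: one step and one optimized flow
#' experiment per IFFL variant (3 repressors x 2 RiboJ states) plus one
#' sigma19 activation pulse experiment - 13 experiments over 7 models.
#'
#' @return data frame with columns `model`, `experiment`, `kind`.
#' @export
experiment_registry <- function() {
  models <- setdiff(names(iffl_models()), "SIGMA19")
  df <- rbind(
    data.frame(model = models, kind = "step"),
    data.frame(model = models, kind = "optimized"),
    data.frame(model = "SIGMA19", kind = "sigma19_pulse"))
  df$experiment <- paste0(df$model, ".", df$kind)
  df[order(df$model, df$kind), c("model", "experiment", "kind")]
}

#' Instantiate the registry as simulation-ready experiments
#'
#' @param registry a registry data frame (default [experiment_registry()]).
#' @param config chemostat configuration.
#' @return named list of [experiment()] objects (no observed data).
#' @export
registry_experiments <- function(registry = experiment_registry(),
                                 config = chemostat_config()) {
  models <- iffl_models()
  out <- list()
  for (i in seq_len(nrow(registry))) {
    net <- models[[registry$model[i]]]
    proto <- switch(registry$kind[i],
      step = iffl_step_protocol(net, config = config),
      optimized = optimized_iffl_protocol(net, config = config),
      sigma19_pulse = sigma19_pulse_protocol(net, config = config),
      stop("unknown experiment kind: ", registry$kind[i]))
    out[[registry$experiment[i]]] <-
      experiment(net, proto, name = registry$experiment[i])
  }
  out
}

# Pulse decoder ------------------------------------------------------------

#' Relax a circuit to its flow steady state
#'
#' Simulates under a constant-inflow protocol in chunks of `chunk` cycles
#' until every observable changes by less than `tol` nM/min over the last
#' cycle (or `max_cycles` is reached, with a warning).
#' @param network a `cfps_network`.
#' @param params a `cfps_params`.
#' @param fractions single-row inflow-fraction matrix (the holding pattern).
#' @param stocks named stocks (nM).
#' @param config chemostat configuration.
#' @param tol slope tolerance in nM/min (default 1e-4).
#' @param chunk,max_cycles relaxation chunk size and cap.
#' @return list with `state` (steady state vector) and `cycles` used.
#' @export
equilibrate_circuit <- function(network, params, fractions, stocks,
                                config = chemostat_config(), tol = 1e-4,
                                chunk = 10, max_cycles = 200) {
  Tc <- config$cycle_time
  fr <- fractions[rep(1, chunk), , drop = FALSE]
  proto <- inflow_protocol(fr, stocks, config)
  y <- NULL; used <- 0
  repeat {
    traj <- simulate_circuit(network, params, proto, y0 = y)
    y <- traj$states[nrow(traj$states), ]
    used <- used + chunk
    n <- nrow(traj$observables)
    slope <- abs(traj$observables[n, ] - traj$observables[n - 1, ]) / Tc
    if (all(slope < tol)) break
    if (used >= max_cycles) {
      warning("equilibration cap reached (", max_cycles,
              " cycles); slope ", signif(max(slope), 3), " nM/min")
      break
    }
  }
  list(state = y, cycles = used)
}

pulse_decoder_stocks <- function() {
  nm <- make_pulse_decoder()$names
  # driver, PhlF (pulsed), CymR construct, TetR construct, reporter
  stats::setNames(c(.STOCK_DEFAULT, .STOCK_DEFAULT, 5, .STOCK_DEFAULT,
                    .STOCK_DEFAULT), nm)
}

pulse_decoder_hold <- function(cymr_nM) {
  nm <- make_pulse_decoder()$names
  matrix(c(.IF_HOLD, 0, cymr_nM / 5, .IF_HOLD, .IF_HOLD), 1,
         dimnames = list(NULL, nm))
}

#' Inflow protocol for one pulse-decoder run
#'
#' Holding pattern for driver, CymR, TetR and reporter constructs plus a
#' PhlF inflow pulse of `duration` minutes delivering `phlf_pulse_nM`
#' (inflow fraction x stock) starting at cycle 0, followed by a post-pulse
#' observation window.
#' @param duration PhlF pulse duration in minutes (multiple of the cycle
#'   time).
#' @param cymr_nM working concentration of the p19aPhlFO1-CymR construct
#'   (0.1 or 0.5 nM in the characterized configurations).
#' @param post_window post-pulse observation window in minutes
#'   (default 450).
#' @param phlf_pulse_nM PhlF concentration delivered during the pulse
#'   (default 5 nM).
#' @param config chemostat configuration.
#' @return a `cfps_protocol` over the pulse decoder's constructs.
#' @export
pulse_decoder_protocol <- function(duration, cymr_nM = 0.5,
                                   post_window = 450, phlf_pulse_nM = 5,
                                   config = chemostat_config()) {
  net <- make_pulse_decoder()
  nm <- net$names
  Tc <- config$cycle_time
  n_pulse <- ceiling(duration / Tc - 1e-9)
  n_cycles <- n_pulse + ceiling(post_window / Tc)
  stocks <- pulse_decoder_stocks()
  fr <- pulse_decoder_hold(cymr_nM)[rep(1, n_cycles), , drop = FALSE]
  if (n_pulse > 0)
    fr[seq_len(n_pulse), nm[2]] <- phlf_pulse_nM / stocks[nm[2]]
  inflow_protocol(fr, stocks, config)
}

#' Pulse-response curve of the pulse decoder
#'
#' For each pulse duration, the circuit is pre-equilibrated without the PhlF
#' construct, the PhlF pulse applied, and the relative expression a/b
#' computed: `b` is the pre-pulse mature-deGFP plateau and `a` the post-pulse
#' plateau (the minimum over the post-pulse window, which for long pulses is
#' the fully repressed level). a/b = 1 at zero duration by construction.
#'
#' @param params a `cfps_params` (or a `cfps_fit`, whose best member is
#'   used).
#' @param cymr_nM CymR-construct working concentration (default 0.5).
#' @param durations pulse durations in minutes. The default nine values
#'   (0 to 540 min in 67.5-min / three-cycle steps) span the decoder's full
#'   response range, from no perturbation to the saturated, fully repressed
#'   plateau of the four-stage dilution-limited cascade.
#' @param post_window post-pulse observation window (default 450 min).
#' @param config chemostat configuration.
#' @return data frame with columns `duration` and `ratio`, attribute
#'   `baseline` = b.
#' @export
pulse_response_curve <- function(params, cymr_nM = 0.5,
                                 durations = seq(0, 540, by = 67.5),
                                 post_window = 450,
                                 config = chemostat_config()) {
  if (inherits(params, "cfps_fit")) params <- params$ensemble[[1]]
  stopifnot(all(durations >= 0))
  net <- make_pulse_decoder()
  eq <- equilibrate_circuit(net, params, pulse_decoder_hold(cymr_nM),
                            pulse_decoder_stocks(), config)
  comp <- compile_network(net, params)
  b <- eq$state[comp$iPm[comp$n]]   # mature deGFP of the reporter construct
  ratio <- vapply(durations, function(dt) {
    proto <- pulse_decoder_protocol(dt, cymr_nM, post_window,
                                    config = config)
    traj <- simulate_circuit(net, params, proto, y0 = eq$state)
    gfp <- traj$observables[, net$names[5]]
    a <- min(gfp[traj$times >= 0])
    tail2 <- utils::tail(gfp, 2)
    if (abs(diff(tail2)) > 1e-3 * max(b, 1e-9) &&
        which.min(gfp) == length(gfp))
      warning("plateau not reached within the window for duration ", dt,
              "; last value used")
    a / b
  }, 0.0)
  structure(data.frame(duration = durations, ratio = ratio),
            baseline = unname(b))
}

# Bistable switch ----------------------------------------------------------

#' The triple-switch pulse protocol for the bistable circuit
#'
#' The system starts in the CymR state (only the p19aTetRO1-CymR construct
#' at 0.2 nM), the p19aCymRO1-TetR construct is then added at its 0.8 nM
#' baseline, and three alternating DNA pulses (5 nM p19aCymRO1-TetR, 2 nM
#' p19aTetRO1-CymR, 5 nM p19aCymRO1-TetR) toggle the switch. Driver and
#' both reporters are held at 1 nM throughout.
#'
#' @param baseline_cycles cycles per settling phase (default 16; the
#'   mmCherry readout lags the switch by three to four dilution/maturation
#'   stages of roughly 60 min each, so shorter settles truncate slow
#'   switches).
#' @param pulse_cycles cycles per pulse (default 3).
#' @param config chemostat configuration.
#' @return a `cfps_protocol` with attribute `pulse_times` (minutes at which
#'   each pulse starts).
#' @export
bistable_protocol <- function(baseline_cycles = 16, pulse_cycles = 3,
                              config = chemostat_config()) {
  net <- make_bistable_switch()
  nm <- net$names   # driver, CymR construct, TetR construct, deGFP, mmCherry
  stocks <- stats::setNames(c(.STOCK_DEFAULT, 4, .STOCK_DEFAULT,
                              .STOCK_DEFAULT, .STOCK_DEFAULT), nm)
  base_cym <- 0.2 / stocks[2]; base_tet <- 0.8 / stocks[3]
  pulse_cym <- 2 / stocks[2]; pulse_tet <- 5 / stocks[3]
  seg <- function(n, cym, tet) {
    fr <- matrix(0, n, 5, dimnames = list(NULL, nm))
    fr[, 1] <- .IF_HOLD; fr[, 4] <- .IF_HOLD; fr[, 5] <- .IF_HOLD
    fr[, 2] <- cym; fr[, 3] <- tet
    fr
  }
  fr <- rbind(
    seg(baseline_cycles, base_cym, 0),            # CymR state established
    seg(baseline_cycles, base_cym, base_tet),     # both baselines
    seg(pulse_cycles, base_cym, pulse_tet),       # pulse 1: TetR construct
    seg(baseline_cycles, base_cym, base_tet),
    seg(pulse_cycles, pulse_cym, base_tet),       # pulse 2: CymR construct
    seg(baseline_cycles, base_cym, base_tet),
    seg(pulse_cycles, base_cym, pulse_tet),       # pulse 3: TetR construct
    seg(baseline_cycles, base_cym, base_tet))
  Tc <- config$cycle_time
  p1 <- 2 * baseline_cycles
  p2 <- p1 + pulse_cycles + baseline_cycles
  p3 <- p2 + pulse_cycles + baseline_cycles
  out <- inflow_protocol(fr, stocks, config)
  attr(out, "pulse_times") <- c(p1, p2, p3) * Tc
  out
}

#' Count state switches of a bistable-switch trajectory
#'
#' The state is the sign of (normalized deGFP - normalized mmCherry), each
#' reporter scaled by its own trajectory maximum (so fluorophores of very
#' different brightness compare on a common footing), with a hysteresis band
#' of +/- `band`: the state only flips when the difference crosses the
#' opposite band. Switch events are attributed to the most recent pulse; an event is
#' "aligned" when it occurs within `align_window` minutes after a pulse
#' start.
#'
#' @param traj a `cfps_trajectory` of the bistable network.
#' @param protocol the [bistable_protocol()] (source of `pulse_times`), or a
#'   numeric vector of pulse start times.
#' @param band hysteresis half-width on the normalized difference
#'   (default 0.1).
#' @param align_window minutes after a pulse within which a switch counts as
#'   pulse-aligned (default 360, one full settling phase).
#' @return integer switch count with attributes `times` (switch times) and
#'   `aligned` (logical per switch).
#' @export
classify_switches <- function(traj, protocol, band = 0.1,
                              align_window = 360) {
  obs <- traj$observables
  gn <- grep("deGFP", colnames(obs), value = TRUE)
  cn <- grep("mmCherry", colnames(obs), value = TRUE)
  if (length(gn) != 1 || length(cn) != 1)
    stop("trajectory must observe one deGFP and one mmCherry reporter")
  G <- obs[, gn]; C <- obs[, cn]
  if (max(G) <= 0 && max(C) <= 0)
    stop("undefined state: both reporter traces are identically zero")
  nrm <- function(v) if (max(v) > 0) v / max(v) else v
  d <- nrm(G) - nrm(C)
  state <- 0L; switches <- numeric(0)
  for (k in seq_along(d)) {
    s_new <- state
    if (d[k] > band) s_new <- 1L
    if (d[k] < -band) s_new <- -1L
    if (state != 0L && s_new != 0L && s_new != state)
      switches <- c(switches, traj$times[k])
    if (s_new != 0L) state <- s_new
  }
  pulses <- if (is.numeric(protocol)) protocol else
    attr(protocol, "pulse_times")
  aligned <- vapply(switches, function(ts)
    any(ts > pulses & ts <= pulses + align_window), TRUE)
  structure(length(switches), times = switches, aligned = aligned)
}

#' Did a trajectory execute the triple switch?
#'
#' TRUE when exactly three switches occurred, all pulse-aligned, one per
#' pulse.
#' @inheritParams classify_switches
#' @export
is_triple_switch <- function(traj, protocol, band = 0.1,
                             align_window = 360) {
  n <- try(classify_switches(traj, protocol, band, align_window),
           silent = TRUE)
  if (inherits(n, "try-error")) return(FALSE)
  if (as.integer(n) != 3L || !all(attr(n, "aligned"))) return(FALSE)
  pulses <- if (is.numeric(protocol)) protocol else
    attr(protocol, "pulse_times")
  per_pulse <- vapply(pulses, function(p)
    sum(attr(n, "times") > p & attr(n, "times") <= p + align_window), 0L)
  all(per_pulse == 1L)
}

#' Screen sampled parameter sets for triple-switch bistability
#'
#' Samples parameter sets within the bounds of `params` (log-uniform for
#' rates and dissociation constants, uniform for Hill coefficients),
#' simulates the triple-switch protocol for each, and records whether the
#' set reproduced exactly three pulse-aligned switches. The distribution of
#' Hill coefficients among successful sets characterizes the regulatory
#' regime that supports bistable switching.
#'
#' @param n_sets number of sampled parameter sets (default 2000).
#' @param seed RNG seed.
#' @param params parameter set supplying values and sampling bounds
#'   (default the database reference column).
#' @param protocol triple-switch protocol (default [bistable_protocol()]).
#' @param rtol,atol integrator tolerances for the screen (defaults 1e-6 /
#'   1e-8; the classification is threshold-based and does not need tighter
#'   integration).
#' @return data frame, one row per sampled set: `n_TetR`, `n_CymR`,
#'   `kd_TetR`, `kd_CymR`, `switches`, `success`.
#' @export
bistability_screen <- function(n_sets = 2000, seed = 1,
                               params = reference_params("database"),
                               protocol = bistable_protocol(),
                               rtol = 1e-6, atol = 1e-8) {
  net <- make_bistable_switch()
  free <- used_parameters(net, params)
  b <- param_bounds(params)[free, , drop = FALSE]
  is_hill <- grepl("^n_", free)
  set.seed(seed)
  out <- data.frame(n_TetR = numeric(n_sets), n_CymR = numeric(n_sets),
                    kd_TetR = numeric(n_sets), kd_CymR = numeric(n_sets),
                    switches = integer(n_sets), success = logical(n_sets))
  for (i in seq_len(n_sets)) {
    v <- numeric(length(free)); names(v) <- free
    v[!is_hill] <- exp(stats::runif(sum(!is_hill), log(b[!is_hill, 1]),
                                    log(b[!is_hill, 2])))
    v[is_hill] <- stats::runif(sum(is_hill), b[is_hill, 1], b[is_hill, 2])
    ps <- update_params(params, v, validate = FALSE)
    traj <- try(simulate_circuit(net, ps, protocol, rtol = rtol,
                                 atol = atol), silent = TRUE)
    ok <- !inherits(traj, "try-error")
    sw <- if (ok) try(classify_switches(traj, protocol), silent = TRUE)
          else NA
    n_sw <- if (ok && !inherits(sw, "try-error")) as.integer(sw) else NA
    out$n_TetR[i] <- v["n_TetR"]; out$n_CymR[i] <- v["n_CymR"]
    out$kd_TetR[i] <- v["kd_TetR"]; out$kd_CymR[i] <- v["kd_CymR"]
    out$switches[i] <- n_sw
    out$success[i] <- ok && !inherits(sw, "try-error") &&
      is_triple_switch(traj, protocol)
  }
  out
}
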