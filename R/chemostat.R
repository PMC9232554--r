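# Microfluidic chemostat refresh-cycle mechanics and inflow-file I/O ----

#' Chemostat hardware configuration
#'
#' @param refresh_fraction fraction RF of the reactor volume replaced per
#'   dilution cycle (default 0.40).
#' @param cycle_time duration of one refresh cycle in minutes (default 22.5).
#' @param lysate_fraction share of the refreshed volume reserved for lysate
#'   and energy solution (default 0.70); the remaining share carries the DNA
#'   stocks and MQ water.
#' @return object of class `cfps_chemostat`.
#' @export
chemostat_config <- function(refresh_fraction = 0.40, cycle_time = 22.5,
                             lysate_fraction = 0.70) {
  stopifnot(refresh_fraction > 0, refresh_fraction < 1, cycle_time > 0,
            lysate_fraction >= 0, lysate_fraction < 1)
  structure(list(refresh_fraction = refresh_fraction,
                 cycle_time = cycle_time,
                 lysate_fraction = lysate_fraction,
                 dna_mq_fraction = 1 - lysate_fraction),
            class = "cfps_chemostat")
}

#' Per-cycle DNA inflow protocol
#'
#' The control variable of every experiment: a matrix of inflow fractions
#' `IF[cycle, construct]` (each entry the fraction of the DNA/MQ share of the
#' refreshed volume allocated to that construct's stock during that cycle),
#' per-construct stock concentrations, and the chemostat configuration.
#' Cycle indexing is 0-based; time runs from the start of cycle 0.
#'
#' @param fractions numeric matrix `[cycle x construct]` with column names =
#'   construct names; entries in \[0, 1\], row sums <= 1.
#' @param stocks named stock concentrations in nM (one per construct).
#' @param config a [chemostat_config()].
#' @return object of class `cfps_protocol`.
#' @export
inflow_protocol <- function(fractions, stocks, config = chemostat_config()) {
  fractions <- as.matrix(fractions)
  if (is.null(colnames(fractions))) stop("fractions needs construct names")
  if (nrow(fractions) > 0) {
    if (any(fractions < 0 | fractions > 1))
      stop("inflow fractions must lie in [0, 1]")
    if (any(rowSums(fractions) > 1 + 1e-12))
      stop("per-cycle inflow fractions exceed the DNA/MQ share (row sum > 1)")
  }
  stocks <- unlist(stocks)
  if (!all(colnames(fractions) %in% names(stocks)))
    stop("stocks missing for: ",
         paste(setdiff(colnames(fractions), names(stocks)), collapse = ", "))
  stocks <- stocks[colnames(fractions)]
  stopifnot(all(stocks >= 0), inherits(config, "cfps_chemostat"))
  structure(list(fractions = fractions, stocks = stocks, config = config,
                 n_cycles = nrow(fractions)),
            class = "cfps_protocol")
}

#' @export
print.cfps_protocol <- function(x, ...) {
  cat("Inflow protocol:", x$n_cycles, "cycles x", ncol(x$fractions),
      "constructs; RF =", x$config$refresh_fraction, ", cycle =",
      x$config$cycle_time, "min\n")
  invisible(x)
}

#' Protocol horizon in minutes
#' @param protocol a `cfps_protocol`.
#' @export
protocol_horizon <- function(protocol)
  protocol$n_cycles * protocol$config$cycle_time

#' Read / write inflow-pattern text files
#'
#' Tab-delimited text, one header row of construct names, one row per
#' refresh cycle, inflow fractions as decimals. Fractions round-trip exactly
#' through `write_inflow_file` (full double precision is printed).
#'
#' @param path file path (or connection for reading).
#' @param stocks,config passed to [inflow_protocol()] (the file itself only
#'   carries fractions).
#' @return `parse_inflow_file` returns a `cfps_protocol`.
#' @export
parse_inflow_file <- function(path, stocks, config = chemostat_config()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) stop("empty inflow file: no header row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  mat <- matrix(numeric(0), 0, length(header),
                dimnames = list(NULL, header))
  if (length(body)) {
    rows <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_along(rows)) {
      if (length(rows[[i]]) != length(header))
        stop("line ", i + 1, ": expected ", length(header),
             " fields, found ", length(rows[[i]]))
      v <- suppressWarnings(as.numeric(rows[[i]]))
      if (anyNA(v)) stop("line ", i + 1, ": non-numeric inflow fraction")
      if (any(v < 0 | v > 1))
        stop("line ", i + 1, ": inflow fraction outside [0, 1]")
      if (sum(v) > 1 + 1e-12)
        stop("line ", i + 1, ": fractions exceed the DNA/MQ share (sum > 1)")
      mat <- rbind(mat, v)
    }
    rownames(mat) <- NULL
  }
  inflow_protocol(mat, stocks, config)
}

#' @rdname parse_inflow_file
#' @param protocol a `cfps_protocol`.
#' @export
write_inflow_file <- function(protocol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(protocol$fractions), collapse = "\t"), con)
  if (protocol$n_cycles > 0)
    writeLines(apply(protocol$fractions, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Convert a protocol to continuous-time control signals
#'
#' Default (continuous) mode: within cycle `j` the inflow rate of construct
#' `i` is `IF[j, i] * RF * stock_i / cycle_time` (nM/min) and the dilution
#' rate is the constant `lambda = RF / cycle_time`; both piecewise constant.
#' The discrete per-cycle replacement map (`state <- (1 - RF) * state +
#' RF * IF * stock` at cycle boundaries, no dilution in between) is available
#' behind the same contract for fidelity studies.
#'
#' @param protocol a `cfps_protocol`.
#' @param mode `"continuous"` (default) or `"discrete"`.
#' @return list with `mode`, `lambda`, `kin(cycle)` returning the inflow-rate
#'   vector of a 0-based cycle (continuous mode), and `dna_input(cycle)`
#'   returning the incoming DNA mixture concentrations (discrete mode).
#' @export
protocol_to_controls <- function(protocol, mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  cfg <- protocol$config
  RF <- cfg$refresh_fraction; Tc <- cfg$cycle_time
  fr <- protocol$fractions; st <- protocol$stocks
  list(mode = mode,
       lambda = if (mode == "continuous") RF / Tc else 0,
       refresh_fraction = RF, cycle_time = Tc,
       n_cycles = protocol$n_cycles,
       kin = function(cycle) fr[cycle + 1, ] * RF * st / Tc,
       dna_input = function(cycle) fr[cycle + 1, ] * st)
}

#' DNA concentration traces implied by a protocol alone
#'
#' Solves the linear inflow/dilution dynamics of the DNA species in closed
#' form (piecewise-constant inflow, exponential relaxation within each
#' cycle), independent of any gene-expression model. Matches the DNA
#' components of a full simulation to integrator accuracy.
#'
#' @param protocol a `cfps_protocol`.
#' @param times minutes, within the protocol horizon.
#' @param dna0 initial DNA concentrations (default 0).
#' @return matrix `[time x construct]` of concentrations in nM.
#' @export
realized_dna_trace <- function(protocol, times, dna0 = NULL) {
  Tc <- protocol$config$cycle_time
  H <- protocol_horizon(protocol)
  if (any(times < 0 | times > H + 1e-9))
    stop("times beyond the protocol horizon of ", H, " min")
  ctrl <- protocol_to_controls(protocol)
  lam <- ctrl$lambda
  nc <- ncol(protocol$fractions)
  if (is.null(dna0)) dna0 <- rep(0, nc)
  out <- matrix(NA_real_, length(times), nc,
                dimnames = list(NULL, colnames(protocol$fractions)))
  # march cycle by cycle, recording boundary states
  y <- dna0
  bound <- matrix(0, protocol$n_cycles + 1, nc)
  bound[1, ] <- y
  if (protocol$n_cycles > 0) for (j in seq_len(protocol$n_cycles)) {
    kin <- ctrl$kin(j - 1)
    y <- kin / lam + (y - kin / lam) * exp(-lam * Tc)
    bound[j + 1, ] <- y
  }
  for (k in seq_along(times)) {
    t <- times[k]
    j <- min(floor(t / Tc), protocol$n_cycles - 1)
    if (protocol$n_cycles == 0 || t == 0) { out[k, ] <- bound[1, ]; next }
    j <- max(j, 0)
    kin <- ctrl$kin(j)
    y0 <- bound[j + 1, ]
    dt <- t - j * Tc
    out[k, ] <- kin / lam + (y0 - kin / lam) * exp(-lam * dt)
  }
  out
}
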