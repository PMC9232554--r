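# Kinetic parameter sets -------------------------------------------------
#
# All rates are in nM and minutes.  kcat_TX_* are per-nM-template turnover
# numbers (numerically equal to the printed nM min^-1 values), kcat_TL_* are
# per-nM-mRNA turnover numbers, kd_* are dissociation constants in nM, n_*
# dimensionless Hill coefficients, kdeg_* first-order mRNA decay rates in
# min^-1 and kmat_* first-order reporter maturation rates in min^-1.
# kmat_* are treated as known and are never varied during fitting.

.ORFS <- c("sigma19", "TetR", "CymR", "PhlF", "deGFP", "mmCherry")
.REPRESSORS <- c("TetR", "CymR", "PhlF")
.REPORTERS <- c("deGFP", "mmCherry")
.PROMOTERS <- c("p70a", "p19a")
.OPERATORS <- c(TetRO1 = "TetR", CymRO1 = "CymR", PhlFO1 = "PhlF")

.KMAT_DEFAULTS <- c(kmat_deGFP = 0.06, kmat_mmCherry = 0.015)

#' Construct a validated kinetic parameter set
#'
#' A parameter set is a named numeric vector with an attached bounds matrix.
#' Values must be strictly positive and lie within their bounds; Hill
#' coefficients (`n_*`) must lie in \[1, 4\]. Maturation rates (`kmat_*`) are
#' carried along but flagged as fixed: fitting and sensitivity routines never
#' vary them.
#'
#' @param values named numeric vector of parameter values.
#' @param bounds optional two-column matrix (`lower`, `upper`) with rownames
#'   matching `values`; defaults to \code{\link{default_bounds}} for known
#'   names and `(value/100, value*100)` otherwise.
#' @param validate check positivity and bounds (default `TRUE`).
#' @return an object of class `cfps_params`.
#' @seealso [reference_params()] for the packaged characterization databases.
#' @export
parameter_set <- function(values, bounds = NULL, validate = TRUE) {
  stopifnot(is.numeric(values), !is.null(names(values)), !anyNA(values))
  values <- unlist(values)
  if (is.null(bounds)) {
    db <- default_bounds()
    bounds <- matrix(NA_real_, length(values), 2,
                     dimnames = list(names(values), c("lower", "upper")))
    known <- intersect(names(values), rownames(db))
    bounds[known, ] <- db[known, , drop = FALSE]
    miss <- is.na(bounds[, 1])
    bounds[miss, 1] <- values[miss] / 100
    bounds[miss, 2] <- values[miss] * 100
  }
  bounds <- as.matrix(bounds)
  colnames(bounds) <- c("lower", "upper")
  if (!all(names(values) %in% rownames(bounds)))
    stop("bounds missing for: ",
         paste(setdiff(names(values), rownames(bounds)), collapse = ", "))
  bounds <- bounds[names(values), , drop = FALSE]
  if (validate) {
    if (any(values <= 0)) stop("all rates must be > 0")
    bad <- values < bounds[, 1] - 1e-12 | values > bounds[, 2] + 1e-12
    if (any(bad))
      stop("parameter(s) outside declared bounds: ",
           paste(names(values)[bad], collapse = ", "))
    nh <- grep("^n_", names(values))
    if (length(nh) && any(values[nh] < 1 | values[nh] > 4))
      stop("Hill coefficients must lie in [1, 4]")
  }
  structure(values, bounds = bounds, class = "cfps_params")
}

#' @export
print.cfps_params <- function(x, ...) {
  b <- attr(x, "bounds")
  df <- data.frame(value = as.numeric(x),
                   lower = b[, "lower"], upper = b[, "upper"],
                   row.names = names(x))
  cat("Kinetic parameter set (", length(x), " parameters, nM / min units)\n",
      sep = "")
  print(df, digits = 4)
  invisible(x)
}

#' @export
`[.cfps_params` <- function(x, i, ...) {
  y <- NextMethod()
  if (is.character(i) || is.numeric(i) || is.logical(i)) {
    b <- attr(x, "bounds")
    attr(y, "bounds") <- b[names(y), , drop = FALSE]
    class(y) <- "cfps_params"
  }
  y
}

#' Bounds of a parameter set
#' @param params a `cfps_params` object.
#' @return two-column matrix (`lower`, `upper`).
#' @export
param_bounds <- function(params) attr(params, "bounds")

#' Default fitting bounds for every named kinetic parameter
#'
#' Broad biophysical box constraints used when a parameter is created without
#' explicit bounds: catalytic rates 0.1–4 nM/min, repressor dissociation
#' constants 1–1250 nM, Hill coefficients 1–4, mRNA decay 0.008–0.125 min^-1.
#' No-RiboJ translation-rate bounds are the RiboJ bounds divided by the
#' default RiboJ factor of 2.
#'
#' @return matrix with rownames = parameter names, columns `lower`, `upper`.
#' @export
default_bounds <- function() {
  nm <- c("kcat_TX_s70", "kcat_TX_s19", "kd_s19",
          paste0("kcat_TL_", c("sigma19", "TetR", "CymR", "PhlF",
                               "deGFP", "mmCherry")),
          paste0("kcat_TL_", c("TetR", "CymR", "PhlF", "deGFP", "mmCherry"),
                 "_RiboJ"),
          paste0("kd_", .REPRESSORS), paste0("n_", .REPRESSORS),
          paste0("kdeg_", .ORFS), names(.KMAT_DEFAULTS))
  lo <- c(0.1, 0.1, 9,
          rep(0.05, 6),
          rep(0.1, 5),
          rep(1, 3), rep(1, 3),
          rep(0.008, 6), .KMAT_DEFAULTS / 10)
  hi <- c(4, 4, 1250,
          rep(2, 6),
          rep(4, 5),
          rep(1250, 3), rep(4, 3),
          rep(0.125, 6), .KMAT_DEFAULTS * 10)
  matrix(c(lo, hi), ncol = 2, dimnames = list(nm, c("lower", "upper")))
}

#' Parameter category lumping
#'
#' Maps each kinetic parameter to one of the four lumped categories used for
#' identifiability and distribution-width summaries: transcription (`K_TX`:
#' kcat_TX and the sigma19 promoter kd), translation (`K_TL`), regulation
#' (`K_reg`: repressor kd and Hill coefficients) and mRNA degradation
#' (`K_deg`). Maturation rates are known constants and map to `NA`.
#'
#' @param names character vector of parameter names.
#' @return character vector of categories, same length as `names`.
#' @export
param_categories <- function(names) {
  out <- rep(NA_character_, length(names))
  out[grepl("^kcat_TX|^kd_s19", names)] <- "K_TX"
  out[grepl("^kcat_TL", names)] <- "K_TL"
  out[grepl("^kd_(TetR|CymR|PhlF)|^n_", names)] <- "K_reg"
  out[grepl("^kdeg_", names)] <- "K_deg"
  names(out) <- names
  out
}

# Reference characterization databases (values and [lower, upper] brackets).
# Four fitting rounds: individual step calibrations; the pooled flow database;
# the database updated with the pulse-decoder experiments; the database
# updated with the bistable-switch experiments.  No-RiboJ repressor
# translation rates are package-derived defaults (RiboJ value / 2, see
# apply_riboj_factor); the mmCherry rate is stored as the plain-ORF rate.
.ref_table <- function() {
  # name, step(val lo hi), database, database+pulse, database+switch
  t1 <- list(
    kcat_TX_s19  = list(c(1.1, 0.1, 4),    c(1.5, 0.45, 3.5), c(1.7, 0.5, 3),    c(1.9, 0.48, 3.2)),
    kcat_TX_s70  = list(c(0.7, 0.1, 4),    c(0.5, 0.2, 1.6),  c(0.7, 0.25, 1.37), c(0.5, 0.25, 1.56)),
    kd_s19       = list(c(636.3, 9, 1250), c(627.4, 143, 1250), c(627.4, 168, 1188), c(794.4, 151, 1245)),
    kcat_TL_TetR_RiboJ = list(c(1.6, 0.1, 4), c(2.8, 0.76, 4), c(2.5, 1.2, 4), c(2.0, 0.83, 4)),
    kcat_TL_CymR_RiboJ = list(c(1.5, 0.1, 4), c(1.6, 0.4, 4),  c(1.2, 0.65, 3.6), c(1.4, 0.5, 3.5)),
    kcat_TL_PhlF_RiboJ = list(c(0.6, 0.1, 4), c(2.3, 0.7, 4),  c(2.2, 1.1, 3.8), c(2.4, 0.75, 3.5)),
    kcat_TL_sigma19    = list(c(0.7, 0.1, 4), c(0.2, 0.1, 1.3), c(0.2, 0.1, 1), c(0.2, 0.1, 0.76)),
    kcat_TL_deGFP_RiboJ = list(c(1.8, 0.125, 4), c(1.0, 0.3, 2.5), c(0.7, 0.3, 2.1), c(1.3, 0.33, 2.3)),
    kcat_TL_mmCherry   = list(NULL, c(0.5, 0.13, 1.5), c(0.4, 0.18, 1.3), c(0.5, 0.17, 0.85)),
    kd_TetR = list(c(200.1, 1, 1250), c(27.0, 4, 93),   c(26.5, 7, 81),   c(22.3, 5, 53)),
    kd_CymR = list(c(207.8, 1, 1250), c(6.4, 0.6, 80),  c(4.6, 0.8, 55),  c(5.7, 0.57, 36)),
    # step-column bracket as printed (39-1250) contradicts its printed mean
    # 3.1; lower bound widened to the 1 nM used for the other repressor kd's
    kd_PhlF = list(c(3.1, 1, 1250),   c(486.2, 110, 1230), c(689.5, 133, 1183), c(545.4, 157, 1083)),
    n_TetR  = list(c(2.7, 1, 4), c(1.5, 1, 4),   c(1.3, 1, 3),   c(1.2, 1, 1.6)),
    n_CymR  = list(c(2.7, 1, 4), c(1.9, 1, 4),   c(2.0, 1, 4),   c(1.4, 1, 2)),
    n_PhlF  = list(c(3.1, 1, 4), c(3.3, 1.2, 4), c(3.5, 2.1, 4), c(3.9, 1.75, 4)),
    kdeg_TetR = list(c(0.07, 0.008, 0.125), c(0.04, 0.008, 0.11), c(0.05, 0.01, 0.11), c(0.04, 0.01, 0.1)),
    kdeg_CymR = list(c(0.08, 0.008, 0.125), c(0.04, 0.008, 0.125), c(0.06, 0.008, 1.21), c(0.04, 0.009, 0.12)),
    kdeg_PhlF = list(c(0.09, 0.025, 0.125), c(0.06, 0.015, 0.125), c(0.06, 0.02, 0.125), c(0.06, 0.018, 0.12)),
    kdeg_sigma19 = list(c(0.11, 0.008, 0.125), c(0.09, 0.033, 0.125), c(0.09, 0.04, 1.2), c(0.09, 0.05, 0.12)),
    kdeg_deGFP = list(c(0.09, 0.025, 0.125), c(0.05, 0.008, 0.125), c(0.04, 0.01, 0.1), c(0.05, 0.02, 0.1)),
    kdeg_mmCherry = list(NULL, c(0.07, 0.008, 0.11), c(0.08, 0.04, 0.125), c(0.07, 0.03, 1.2)))
  t1
}

#' Packaged reference parameter databases
#'
#' Returns the shipped characterization database for one of the four fitting
#' rounds: `"step"` (individual step calibrations), `"database"` (pooled flow
#' database), `"database_pulse"` (database updated with the pulse-decoder
#' experiments) and `"database_switch"` (database updated with the
#' bistable-switch experiments). Each parameter carries its mean value and
#' its bracketed \[lower, upper\] range, interpreted as hard fitting bounds.
#'
#' No-RiboJ translation rates for the three repressors are package-derived
#' defaults equal to the RiboJ value (and bounds) divided by the default
#' RiboJ factor 2; the mmCherry rate is stored as the plain (no-RiboJ) rate,
#' with [apply_riboj_factor()] available to extrapolate to RiboJ variants.
#' Maturation rates are appended as fixed constants.
#'
#' @param column which fitting round; see Details.
#' @param riboj_factor enhancement factor used to derive no-RiboJ repressor
#'   translation rates from the RiboJ entries (default 2).
#' @return a `cfps_params` object.
#' @export
reference_params <- function(column = c("database", "step", "database_pulse",
                                        "database_switch"),
                             riboj_factor = 2) {
  column <- match.arg(column)
  idx <- match(column, c("step", "database", "database_pulse",
                         "database_switch"))
  tab <- .ref_table()
  vals <- c(); lo <- c(); hi <- c()
  for (nm in names(tab)) {
    e <- tab[[nm]][[idx]]
    if (is.null(e)) next
    vals[nm] <- e[1]; lo[nm] <- e[2]; hi[nm] <- e[3]
  }
  # derived plain-ORF translation rates for the repressors
  for (r in .REPRESSORS) {
    rj <- paste0("kcat_TL_", r, "_RiboJ")
    if (rj %in% names(vals)) {
      pl <- paste0("kcat_TL_", r)
      vals[pl] <- vals[rj] / riboj_factor
      lo[pl] <- lo[rj] / riboj_factor
      hi[pl] <- hi[rj] / riboj_factor
    }
  }
  vals <- c(vals, .KMAT_DEFAULTS)
  lo <- c(lo, .KMAT_DEFAULTS); hi <- c(hi, .KMAT_DEFAULTS)
  parameter_set(vals, cbind(lower = lo, upper = hi))
}

#' Extrapolate translation rates across the RiboJ insulator
#'
#' Adds (or replaces) the RiboJ-variant translation rate of `orf` by
#' multiplying its plain rate by `factor` (typically the output of
#' [riboj_factor()]). Used to predict circuits containing parts never
#' characterized with RiboJ.
#'
#' @param params a `cfps_params` object.
#' @param orf ORF name, e.g. `"mmCherry"`.
#' @param factor multiplicative RiboJ enhancement factor (> 0).
#' @return updated `cfps_params`.
#' @export
apply_riboj_factor <- function(params, orf, factor) {
  stopifnot(factor > 0)
  plain <- paste0("kcat_TL_", orf)
  if (!plain %in% names(params))
    stop("no plain translation rate for ORF ", orf)
  rj <- paste0(plain, "_RiboJ")
  b <- attr(params, "bounds")
  v <- as.numeric(params); names(v) <- names(params)
  v[rj] <- v[plain] * factor
  nb <- rbind(b, matrix(b[plain, ] * factor, 1, dimnames = list(rj)))
  nb <- nb[unique(rownames(nb)), , drop = FALSE]
  nb[rj, ] <- b[plain, ] * factor
  parameter_set(v, nb[names(v), , drop = FALSE])
}

#' Replace parameter values, keeping bounds
#' @param params a `cfps_params` object.
#' @param values named numeric vector of replacements (subset of names).
#' @param validate revalidate against bounds (default TRUE).
#' @return updated `cfps_params`.
#' @export
update_params <- function(params, values, validate = TRUE) {
  v <- as.numeric(params); names(v) <- names(params)
  stopifnot(all(names(values) %in% names(v)))
  v[names(values)] <- values
  parameter_set(v, attr(params, "bounds"), validate = validate)
}

#' Write / read a parameter set as JSON
#'
#' The JSON schema stores values, bounds and the list of fixed (never-fitted)
#' parameters, plus provenance fields.
#' @param params a `cfps_params` object.
#' @param path file path.
#' @return `read_params_json` returns a `cfps_params`.
#' @export
write_params_json <- function(params, path) {
  b <- attr(params, "bounds")
  obj <- list(
    tool = paste0("cfpsflow ", as.character(utils::packageVersion("cfpsflow"))),
    values = as.list(stats::setNames(as.numeric(params), names(params))),
    bounds = stats::setNames(lapply(seq_len(nrow(b)), function(i)
      as.numeric(b[i, ])), rownames(b)),
    fixed = grep("^kmat_", names(params), value = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- unlist(obj$values)
  b <- do.call(rbind, obj$bounds)
  colnames(b) <- c("lower", "upper")
  parameter_set(v, b[names(v), , drop = FALSE])
}
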