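# Coarse-grained CFPS kinetics ------------------------------------------
#
# Per construct i, under dilution rate lambda(t) and DNA inflow k_in,i(t):
#   d DNA_i /dt  = k_in,i(t) - lambda * DNA_i
#   d mRNA_i/dt  = TX_i - (kdeg_orf + lambda) * mRNA_i
#   d P_i   /dt  = kcat_TL[orf, riboj] * mRNA_i - lambda * P_i
# with TX_i = kcat_TX_s70 * DNA_i for p70a promoters (sigma70 saturating,
# linear) and kcat_TX_s19 * DNA_i * S19/(kd_s19 + S19) for p19a promoters,
# multiplied by a Hill repression factor when an operator is present.
# Reporters split their protein into a dark pool (translated) maturing
# first-order (kmat) into the observable mature pool; both pools are diluted.
# Protein proteolysis is neglected (half-life >> dilution) but chemostat
# outflow still removes protein.

#' Hill repression factor
#'
#' Fraction of transcription remaining at repressor concentration `R`:
#' `1 / (1 + (R/kd)^n)`. Equals 1 with no repressor and 1/2 at `R = kd`.
#'
#' @param repressor_conc repressor concentration (nM, >= 0).
#' @param kd dissociation constant (nM, > 0).
#' @param n Hill coefficient (>= 1).
#' @return fraction in \[0, 1\], monotone decreasing in `repressor_conc`.
#' @export
hill_repression <- function(repressor_conc, kd, n) {
  if (any(repressor_conc < 0)) stop("repressor concentration must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(n < 1)) stop("Hill coefficient must be >= 1")
  1 / (1 + (repressor_conc / kd)^n)
}

#' Transcription rate of a construct
#'
#' p70a promoters transcribe linearly (`kcat_TX_s70 * dna`); p19a promoters
#' follow Michaelis-Menten activation by sigma19 with the same `kd_s19` for
#' bare and hybrid (operator-bearing) promoters. An operator multiplies the
#' rate by [hill_repression()] evaluated at its repressor's concentration.
#'
#' @param construct a [gene_construct()].
#' @param dna template concentration (nM).
#' @param sigma19 free sigma19 protein concentration (nM).
#' @param repressor concentration of the construct's repressor (nM); ignored
#'   when the construct has no operator.
#' @param params a `cfps_params`.
#' @return transcription rate in nM/min.
#' @export
transcription_rate <- function(construct, dna, sigma19, repressor, params) {
  stopifnot(dna >= 0, sigma19 >= 0)
  rate <- switch(construct$promoter,
    p70a = params[["kcat_TX_s70"]] * dna,
    p19a = params[["kcat_TX_s19"]] * dna *
      sigma19 / (params[["kd_s19"]] + sigma19),
    stop("unknown promoter: ", construct$promoter))
  if (!is.null(construct$operator)) {
    r <- .OPERATORS[[construct$operator]]
    rate <- rate * hill_repression(repressor, params[[paste0("kd_", r)]],
                                   params[[paste0("n_", r)]])
  }
  rate
}

tl_param_name <- function(construct)
  paste0("kcat_TL_", construct$orf, if (construct$riboj) "_RiboJ")

# Resolve all parameter positions and species indices once per network.
# Returns a compiled structure consumed by the rhs evaluator.
compile_network <- function(network, params) {
  ks <- network$constructs
  n <- length(ks)
  sp <- network$species
  idx <- function(p, nm) match(paste0(p, nm), sp)
  nm <- network$names
  pn <- names(params)
  need <- function(key, what) {
    i <- match(key, pn)
    if (is.na(i))
      stop("uncharacterized part: parameter '", key, "' required for ",
           what, " is missing from the parameter set", call. = FALSE)
    i
  }
  comp <- list(n = n, species = sp,
               iDNA = idx("DNA_", nm), iRNA = idx("mRNA_", nm),
               reporter = vapply(ks, is_reporter, TRUE))
  comp$iP <- ifelse(comp$reporter, idx("Pdark_", nm), idx("P_", nm))
  comp$iPm <- ifelse(comp$reporter, idx("Pmat_", nm), NA_integer_)
  comp$p19 <- vapply(ks, function(k) k$promoter == "p19a", TRUE)
  comp$i_kcatTX <- ifelse(comp$p19, need("kcat_TX_s19", "p19a promoters"),
                          need("kcat_TX_s70", "p70a promoters"))
  comp$i_kd19 <- if (any(comp$p19)) need("kd_s19", "p19a promoters") else NA
  comp$i_kcatTL <- vapply(seq_len(n), function(i)
    need(tl_param_name(ks[[i]]), paste0("construct '", nm[i], "'")), 0L)
  comp$i_kdeg <- vapply(seq_len(n), function(i)
    need(paste0("kdeg_", ks[[i]]$orf), paste0("construct '", nm[i], "'")), 0L)
  comp$i_kmat <- vapply(seq_len(n), function(i) {
    if (comp$reporter[i]) need(paste0("kmat_", ks[[i]]$orf),
                               paste0("reporter '", nm[i], "'")) else NA_integer_
  }, 0L)
  # regulation: for each construct, the protein species indices whose sum is
  # the acting repressor concentration, plus kd/n positions
  comp$reg_species <- vector("list", n)
  comp$i_kdrep <- rep(NA_integer_, n); comp$i_nrep <- rep(NA_integer_, n)
  orf_of <- vapply(ks, `[[`, "", "orf")
  prot_idx_of_orf <- function(orf) {
    j <- which(orf_of == orf & !comp$reporter)
    comp$iP[j]
  }
  for (i in seq_len(n)) {
    op <- ks[[i]]$operator
    if (!is.null(op)) {
      r <- .OPERATORS[[op]]
      comp$reg_species[[i]] <- prot_idx_of_orf(r)  # may be empty: absent, 0
      comp$i_kdrep[i] <- need(paste0("kd_", r), paste0("operator ", op))
      comp$i_nrep[i] <- need(paste0("n_", r), paste0("operator ", op))
    }
  }
  comp$i_s19 <- prot_idx_of_orf("sigma19")
  comp
}

# rhs evaluator for a compiled network; kin is the per-construct inflow rate
# vector (nM/min) and lambda the dilution rate (1/min), both constant over
# one integration segment.  p is the bare numeric parameter vector.
make_rhs <- function(comp, p, kin, lambda) {
  force(comp); force(p); force(kin); force(lambda)
  function(t, y, parms) {
    y <- pmax(y, 0)
    S19 <- if (length(comp$i_s19)) sum(y[comp$i_s19]) else 0
    dna <- y[comp$iDNA]; rna <- y[comp$iRNA]
    act <- p[comp$i_kcatTX]
    if (any(comp$p19)) {
      f19 <- S19 / (p[comp$i_kd19] + S19)
      act[comp$p19] <- act[comp$p19] * f19
    }
    tx <- act * dna
    for (i in seq_len(comp$n)) {
      if (!is.na(comp$i_kdrep[i])) {
        R <- if (length(comp$reg_species[[i]])) sum(y[comp$reg_species[[i]]]) else 0
        tx[i] <- tx[i] / (1 + (R / p[comp$i_kdrep[i]])^p[comp$i_nrep[i]])
      }
    }
    tl <- p[comp$i_kcatTL] * rna
    dy <- numeric(length(y))
    dy[comp$iDNA] <- kin - lambda * dna
    dy[comp$iRNA] <- tx - (p[comp$i_kdeg] + lambda) * rna
    rep <- comp$reporter
    if (any(!rep))
      dy[comp$iP[!rep]] <- tl[!rep] - lambda * y[comp$iP[!rep]]
    if (any(rep)) {
      km <- p[comp$i_kmat[rep]]
      dark <- y[comp$iP[rep]]; mat <- y[comp$iPm[rep]]
      dy[comp$iP[rep]] <- tl[rep] - (km + lambda) * dark
      dy[comp$iPm[rep]] <- km * dark - lambda * mat
    }
    list(dy)
  }
}

#' Assemble the ODE system for a network
#'
#' Binds a network and a parameter set into an integrable system: state order
#' is the network's species list; the right-hand side takes per-construct
#' inflow rates (nM/min) and a global dilution rate lambda (1/min) as control
#' channels. A missing `kcat_TL` entry for an (ORF, RiboJ) combination raises
#' an "uncharacterized part" error (resolved via [apply_riboj_factor()]).
#'
#' @param network a `cfps_network`.
#' @param params a `cfps_params` covering every part the network uses.
#' @return object of class `cfps_ode`: list with `network`, `params`,
#'   `species`, and `rhs(t, state, kin, lambda)` returning the derivative
#'   vector.
#' @export
build_ode_system <- function(network, params) {
  comp <- compile_network(network, params)
  p <- as.numeric(params); names(p) <- names(params)
  sys <- list(network = network, params = params, species = network$species,
              comp = comp, p = p)
  sys$rhs <- function(t, state, kin, lambda) {
    make_rhs(comp, p, kin, lambda)(t, state, NULL)[[1]]
  }
  structure(sys, class = "cfps_ode")
}

#' @export
print.cfps_ode <- function(x, ...) {
  cat("CFPS ODE system:", length(x$species), "species,",
      x$comp$n, "constructs\n")
  invisible(x)
}

#' Steady-state mRNA to DNA ratio of an activated construct
#'
#' Under constant inflow and dilution `lambda`, the fully activated,
#' unrepressed steady state obeys `mRNA_ss / DNA_ss =
#' kcat_TX_eff / (kdeg_mRNA + lambda)` where `kcat_TX_eff` is the promoter's
#' catalytic rate (sigma19 saturating for p19a). The ensemble fitter's soft
#' biophysical constraint requires this ratio to lie in (2, 500).
#'
#' @param construct a [gene_construct()].
#' @param params a `cfps_params`.
#' @param lambda dilution rate (1/min, >= 0).
#' @return dimensionless ratio.
#' @export
steady_state_mrna_ratio <- function(construct, params, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  kcat <- switch(construct$promoter,
                 p70a = params[["kcat_TX_s70"]],
                 p19a = params[["kcat_TX_s19"]])
  kdeg <- params[[paste0("kdeg_", construct$orf)]]
  if (kdeg + lambda <= 0)
    stop("degenerate input: kdeg + lambda must be > 0")
  kcat / (kdeg + lambda)
}
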