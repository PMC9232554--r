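# Genetic constructs and networks ---------------------------------------

#' Define a single transcription unit
#'
#' A construct is one linear DNA template: a sigma-factor promoter (`p70a`,
#' sigma70-driven, or `p19a`, sigma19-driven), an optional repressor operator
#' downstream of the transcriptional start (`TetRO1`, `CymRO1`, `PhlFO1`), an
#' optional RiboJ insulator between operator and RBS, and an ORF.
#'
#' @param name unique identifier within a network.
#' @param promoter `"p70a"` or `"p19a"`.
#' @param orf one of `"sigma19"`, `"TetR"`, `"CymR"`, `"PhlF"`, `"deGFP"`,
#'   `"mmCherry"`.
#' @param operator optional operator site; `NULL` for none.
#' @param riboj logical, RiboJ insulator present.
#' @return object of class `cfps_construct`.
#' @export
gene_construct <- function(name, promoter, orf, operator = NULL,
                           riboj = FALSE) {
  promoter <- match.arg(promoter, .PROMOTERS)
  orf <- match.arg(orf, .ORFS)
  if (!is.null(operator)) operator <- match.arg(operator, names(.OPERATORS))
  stopifnot(is.character(name), nchar(name) > 0, is.logical(riboj))
  structure(list(name = name, promoter = promoter, operator = operator,
                 riboj = riboj, orf = orf),
            class = "cfps_construct")
}

#' @export
print.cfps_construct <- function(x, ...) {
  cat(sprintf("<%s> %s%s%s-%s\n", x$name, x$promoter,
              if (is.null(x$operator)) "" else paste0(x$operator),
              if (x$riboj) "-RiboJ" else "", x$orf))
  invisible(x)
}

is_reporter <- function(construct) construct$orf %in% .REPORTERS

#' Assemble constructs into a network
#'
#' Derives the deterministic species list (per construct: DNA, mRNA and
#' protein; reporters carry a dark and a mature protein pool) and checks that
#' every operator's repressor is either produced by some construct in the
#' network or explicitly declared absent via `external_absent`.
#'
#' @param constructs list of [gene_construct()] objects (unique names).
#' @param external_absent character vector of repressor ORFs that are
#'   declared externally absent (treated as concentration 0).
#' @return object of class `cfps_network` with elements `constructs`,
#'   `species` (named character vector) and `reporters`.
#' @export
network_spec <- function(constructs, external_absent = character()) {
  if (inherits(constructs, "cfps_construct")) constructs <- list(constructs)
  stopifnot(length(constructs) > 0,
            all(vapply(constructs, inherits, TRUE, "cfps_construct")))
  nm <- vapply(constructs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("construct names must be unique")
  produced <- vapply(constructs, `[[`, "", "orf")
  for (k in constructs) {
    if (!is.null(k$operator)) {
      rep_orf <- .OPERATORS[[k$operator]]
      if (!(rep_orf %in% produced) && !(rep_orf %in% external_absent))
        stop("operator ", k$operator, " on construct '", k$name,
             "' requires repressor ", rep_orf,
             " to be produced or declared externally absent")
    }
  }
  species <- character()
  for (k in constructs) {
    species <- c(species, paste0(c("DNA_", "mRNA_"), k$name))
    if (is_reporter(k))
      species <- c(species, paste0(c("Pdark_", "Pmat_"), k$name))
    else
      species <- c(species, paste0("P_", k$name))
  }
  structure(list(constructs = constructs,
                 names = nm,
                 species = species,
                 reporters = nm[vapply(constructs, is_reporter, TRUE)],
                 external_absent = external_absent),
            class = "cfps_network")
}

#' @export
print.cfps_network <- function(x, ...) {
  cat("CFPS network:", length(x$constructs), "constructs,",
      length(x$species), "species\n")
  for (k in x$constructs) print(k)
  invisible(x)
}

#' Species names of a network
#' @param network a `cfps_network`.
#' @return character vector in canonical state order.
#' @export
species_names <- function(network) network$species

# YAML (de)serialization -------------------------------------------------

#' Serialize a network to / from YAML
#' @param network a `cfps_network`.
#' @param path file path.
#' @return `network_from_yaml` returns a `cfps_network`.
#' @export
network_to_yaml <- function(network, path) {
  obj <- list(constructs = lapply(network$constructs, function(k)
    list(name = k$name, promoter = k$promoter,
         operator = if (is.null(k$operator)) NULL else k$operator,
         riboj = k$riboj, orf = k$orf)),
    external_absent = as.list(network$external_absent))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname network_to_yaml
#' @export
network_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ks <- lapply(obj$constructs, function(k)
    gene_construct(k$name, k$promoter, k$orf, operator = k$operator,
                   riboj = isTRUE(k$riboj)))
  network_spec(ks, external_absent = unlist(obj$external_absent) %||%
                 character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Circuit library ---------------------------------------------------------

#' The shared sigma19 activator construct
#' @return a `cfps_construct` (p70a-sigma19).
#' @export
activator_construct <- function() {
  gene_construct("p70a-S19", "p70a", "sigma19")
}

#' Build one of the six incoherent feed-forward loop variants
#'
#' Every IFFL shares the p70a-sigma19 activator; the repressor construct is
#' p19a(-RiboJ)-`repressor` and the reporter is p19a + matching operator +
#' RiboJ + deGFP.
#'
#' @param repressor `"TetR"`, `"CymR"` or `"PhlF"`.
#' @param riboj does the repressor construct carry the RiboJ insulator.
#' @return a `cfps_network` with three constructs.
#' @export
make_iffl <- function(repressor = c("TetR", "CymR", "PhlF"), riboj = TRUE) {
  repressor <- match.arg(repressor)
  op <- names(.OPERATORS)[match(repressor, .OPERATORS)]
  network_spec(list(
    activator_construct(),
    gene_construct(paste0("p19a", if (riboj) "-RiboJ", "-", repressor),
                   "p19a", repressor, riboj = riboj),
    gene_construct(paste0("p19a", op, "-RiboJ-deGFP"),
                   "p19a", "deGFP", operator = op, riboj = TRUE)))
}

#' The sigma19 expression model
#'
#' Activator plus an unregulated p19a-RiboJ-deGFP reporter; used for the
#' sigma19 activation pulse experiment.
#' @return a `cfps_network`.
#' @export
make_sigma19_model <- function() {
  network_spec(list(
    activator_construct(),
    gene_construct("p19a-RiboJ-deGFP", "p19a", "deGFP", riboj = TRUE)))
}

#' Build the pulse-decoder cascade
#'
#' sigma19 drives a three-repressor cascade PhlF -| CymR -| TetR -| deGFP:
#' p19a-RiboJ-PhlF (pulsed), p19aPhlFO1-CymR, p19aCymRO1-TetR and the
#' reporter p19aTetRO1-RiboJ-deGFP.
#' @return a `cfps_network` with five constructs.
#' @export
make_pulse_decoder <- function() {
  network_spec(list(
    activator_construct(),
    gene_construct("p19a-RiboJ-PhlF", "p19a", "PhlF", riboj = TRUE),
    gene_construct("p19aPhlFO1-CymR", "p19a", "CymR", operator = "PhlFO1"),
    gene_construct("p19aCymRO1-TetR", "p19a", "TetR", operator = "CymRO1"),
    gene_construct("p19aTetRO1-RiboJ-deGFP", "p19a", "deGFP",
                   operator = "TetRO1", riboj = TRUE)))
}

#' Build the bistable switch
#'
#' Mutual repression between p19aTetRO1-CymR and p19aCymRO1-TetR, driven by
#' sigma19, with two operator-gated reporters: p19aTetRO1-RiboJ-deGFP
#' (repressed by TetR, reads out the CymR state) and p19aCymRO1-mmCherry
#' (repressed by CymR, reads out the TetR state).
#' @return a `cfps_network` with five constructs.
#' @export
make_bistable_switch <- function() {
  network_spec(list(
    activator_construct(),
    gene_construct("p19aTetRO1-CymR", "p19a", "CymR", operator = "TetRO1"),
    gene_construct("p19aCymRO1-TetR", "p19a", "TetR", operator = "CymRO1"),
    gene_construct("p19aTetRO1-RiboJ-deGFP", "p19a", "deGFP",
                   operator = "TetRO1", riboj = TRUE),
    gene_construct("p19aCymRO1-mmCherry", "p19a", "mmCherry",
                   operator = "CymRO1")))
}
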