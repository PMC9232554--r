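# Collinearity-index identifiability analysis ---------------------------
#
# For a subset of parameters, columns of the relative sensitivity matrix are
# unit-normalized (flattened over time x observables) and the collinearity
# index is gamma = 1 / sigma_min, the inverse of the smallest singular value
# of the normalized submatrix.  gamma = 1 for orthogonal columns; gamma grows
# without bound as columns become linearly dependent (capped at a ceiling).

#' Collinearity index of a parameter subset
#'
#' @param S a sensitivity matrix (rows = time x observables, columns =
#'   parameters), e.g. from [forward_sensitivities()] or
#'   [pool_experiments()].
#' @param subset column names (or indices) of the parameter subset
#'   (length >= 2).
#' @param ceiling cap for perfect collinearity (default 1e6).
#' @return the index gamma (>= 1 for non-degenerate subsets). If any column
#'   is all-zero the parameter is structurally unidentifiable: the ceiling is
#'   returned with attribute `structural` naming the offending parameters.
#' @export
collinearity_index <- function(S, subset = colnames(S), ceiling = 1e6) {
  sub <- S[, subset, drop = FALSE]
  if (ncol(sub) < 2) stop("subset must contain at least 2 parameters")
  nrm <- sqrt(colSums(sub^2))
  zero <- nrm == 0
  if (any(zero)) {
    out <- ceiling
    attr(out, "structural") <- colnames(sub)[zero]
    return(out)
  }
  subn <- sweep(sub, 2, nrm, "/")
  smin <- min(svd(subn, nu = 0, nv = 0)$d)
  min(if (smin <= 0) Inf else 1 / smin, ceiling)
}

#' Pairwise collinearity matrix
#'
#' gamma over every 2-subset of parameters; the diagonal is 1 by convention.
#'
#' @inheritParams collinearity_index
#' @param par_names columns to analyse (default all).
#' @return object of class `cfps_collinearity`: a symmetric matrix of
#'   pairwise indices.
#' @export
pairwise_collinearity <- function(S, par_names = colnames(S),
                                  ceiling = 1e6) {
  k <- length(par_names)
  G <- matrix(1, k, k, dimnames = list(par_names, par_names))
  if (k >= 2) for (a in 1:(k - 1)) for (b in (a + 1):k) {
    g <- collinearity_index(S, par_names[c(a, b)], ceiling)
    G[a, b] <- G[b, a] <- as.numeric(g)
  }
  structure(G, class = c("cfps_collinearity", "matrix"))
}

#' @export
print.cfps_collinearity <- function(x, ...) {
  cat("Pairwise collinearity indices (", ncol(x), " parameters)\n", sep = "")
  print(unclass(round(x, 2)))
  invisible(x)
}

#' @export
plot.cfps_collinearity <- function(x, main = "collinearity index", ...) {
  k <- ncol(x)
  graphics::image(1:k, 1:k, t(log10(unclass(x)))[, k:1],
                  axes = FALSE, xlab = "", ylab = "",
                  main = main, col = grDevices::hcl.colors(64, "YlOrRd",
                                                           rev = TRUE), ...)
  graphics::axis(1, 1:k, colnames(x), las = 2, cex.axis = 0.7)
  graphics::axis(2, 1:k, rev(rownames(x)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Pool sensitivity matrices from several experiments
#'
#' Row-wise stacking on a common global parameter ordering: shared
#' parameters share a column and accumulate rows from every experiment that
#' contains them; parameters absent from an experiment contribute zero rows
#' for that block.
#'
#' @param S_list list of sensitivity matrices with named columns.
#' @return pooled matrix whose columns are the union of all parameter
#'   labels.
#' @export
pool_experiments <- function(S_list) {
  stopifnot(length(S_list) >= 1)
  all_par <- unique(unlist(lapply(S_list, colnames)))
  if (is.null(all_par)) stop("sensitivity matrices must have column labels")
  blocks <- lapply(S_list, function(S) {
    M <- matrix(0, nrow(S), length(all_par),
                dimnames = list(NULL, all_par))
    M[, colnames(S)] <- S
    M
  })
  out <- do.call(rbind, blocks)
  structure(out, class = c("cfps_sensitivity", "matrix"))
}

#' Category-lumped collinearity matrix
#'
#' Averages the pairwise indices within each pair of parameter categories
#' (K_TX, K_TL, K_reg, K_deg); within-category entries average over pairs of
#' distinct parameters. Optionally normalizes to the maximum entry of a
#' reference scenario's lumped matrix (conventionally the batch design).
#'
#' @param G a [pairwise_collinearity()] matrix.
#' @param mapping named character vector parameter -> category (default
#'   [param_categories()] of the column names).
#' @param reference optional lumped matrix whose maximum is the
#'   normalization constant.
#' @return square matrix over the categories present; categories with no
#'   parameters are absent (with a `dropped` attribute naming them).
#' @export
lumped_collinearity <- function(G, mapping = NULL, reference = NULL) {
  par <- colnames(G)
  if (is.null(mapping)) mapping <- param_categories(par)
  mapping <- mapping[par]
  if (anyNA(mapping))
    stop("unmapped parameter(s): ", paste(par[is.na(mapping)],
                                          collapse = ", "))
  cats <- c("K_TX", "K_TL", "K_reg", "K_deg")
  present <- cats[cats %in% mapping]
  L <- matrix(NA_real_, length(present), length(present),
              dimnames = list(present, present))
  for (a in present) for (b in present) {
    ia <- which(mapping == a); ib <- which(mapping == b)
    vals <- G[ia, ib, drop = FALSE]
    if (a == b) {
      if (length(ia) < 2) { L[a, b] <- NA; next }
      vals <- vals[upper.tri(vals)]
    }
    L[a, b] <- mean(vals, na.rm = TRUE)
  }
  if (!is.null(reference))
    L <- L / max(reference, na.rm = TRUE)
  dropped <- setdiff(cats, present)
  if (length(dropped)) attr(L, "dropped") <- dropped
  L
}

#' Mean lumped collinearity of a scenario
#'
#' Scalar summary used to rank experimental designs: the mean of the unique
#' entries of the category-lumped matrix.
#' @param L a [lumped_collinearity()] matrix.
#' @return scalar.
#' @export
mean_lumped_index <- function(L) {
  mean(L[upper.tri(L, diag = TRUE)], na.rm = TRUE)
}
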