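# Optimal experimental design of inflow patterns ------------------------
#
# A design is an inflow-fraction matrix (and optionally per-construct stock
# concentrations).  Designs are scored by the information they carry about
# the kinetic parameters at a nominal estimate: D-optimality maximizes
# log det(FIM) with FIM = S^T S on relative sensitivities; the collinearity
# criterion minimizes the mean category-lumped collinearity index.  Both are
# returned so that higher is better.

#' Define a design problem
#'
#' @param network a `cfps_network`.
#' @param params nominal `cfps_params` (or a list of sets for the robust,
#'   ensemble-averaged score).
#' @param stocks named stock concentrations (nM) for the designable
#'   constructs.
#' @param n_cycles number of refresh cycles in the design.
#' @param levels admissible inflow-fraction levels (default the 5%-step grid
#'   `seq(0, 1, 0.05)` mirroring load-step hardware granularity).
#' @param stock_bounds optional matrix `[construct x 2]` to co-optimize
#'   stocks within bounds; `NULL` keeps `stocks` fixed.
#' @param criterion `"D"` (log-determinant of the FIM, ridge 1e-12) or
#'   `"collinearity"` (minus the mean lumped index).
#' @param par_names parameters scored (default: all the network uses).
#' @param config chemostat configuration.
#' @param designable which constructs get optimized inflow columns
#'   (default: all in `stocks`).
#' @return object of class `cfps_design_problem`.
#' @export
design_problem <- function(network, params, stocks, n_cycles = 24,
                           levels = seq(0, 1, by = 0.05),
                           stock_bounds = NULL,
                           criterion = c("D", "collinearity"),
                           par_names = NULL,
                           config = chemostat_config(),
                           designable = names(stocks)) {
  criterion <- match.arg(criterion)
  stopifnot(n_cycles >= 1, length(levels) >= 2,
            all(levels >= 0 & levels <= 1))
  first <- if (inherits(params, "cfps_params")) params else params[[1]]
  if (is.null(par_names)) par_names <- used_parameters(network, first)
  if (length(designable) * max(levels) > 1 && max(levels) * 1 > 1) {
    # rows are clipped at score time; nothing to do here
  }
  structure(list(network = network, params = params, stocks = unlist(stocks),
                 n_cycles = n_cycles, levels = sort(levels),
                 stock_bounds = stock_bounds, criterion = criterion,
                 par_names = par_names, config = config,
                 designable = designable),
            class = "cfps_design_problem")
}

problem_protocol <- function(problem, fractions, stocks = NULL) {
  if (is.null(stocks)) stocks <- problem$stocks
  inflow_protocol(fractions, stocks, problem$config)
}

#' Score an inflow design
#'
#' @param protocol a `cfps_protocol` within the problem's design space.
#' @param problem a [design_problem()].
#' @return scalar score (higher is better); `-Inf` with a `diagnostic`
#'   attribute on integration failure.
#' @export
score_design <- function(protocol, problem) {
  sets <- if (inherits(problem$params, "cfps_params"))
    list(problem$params) else problem$params
  scores <- vapply(sets, function(ps) {
    S <- try(forward_sensitivities(
      experiment(problem$network, protocol), ps,
      par_names = problem$par_names), silent = TRUE)
    if (inherits(S, "try-error")) return(-Inf)
    if (problem$criterion == "D") {
      FIM <- crossprod(S) + diag(1e-12, ncol(S))
      as.numeric(determinant(FIM, logarithm = TRUE)$modulus)
    } else {
      G <- pairwise_collinearity(S, problem$par_names)
      -mean_lumped_index(lumped_collinearity(G))
    }
  }, 0.0)
  if (any(!is.finite(scores))) {
    out <- -Inf
    attr(out, "diagnostic") <- "integration failure during scoring"
    return(out)
  }
  mean(scores)
}

random_design <- function(problem) {
  k <- length(problem$designable)
  fr <- matrix(sample(problem$levels, problem$n_cycles * k, replace = TRUE),
               problem$n_cycles, k,
               dimnames = list(NULL, problem$designable))
  # renormalize rows that exceed the DNA/MQ share
  s <- rowSums(fr)
  over <- s > 1
  if (any(over)) fr[over, ] <- fr[over, ] / s[over]
  fr <- snap_levels(fr, problem$levels)
  st <- problem$stocks
  if (!is.null(problem$stock_bounds)) {
    b <- problem$stock_bounds
    st[rownames(b)] <- exp(stats::runif(nrow(b), log(b[, 1]), log(b[, 2])))
  }
  list(fractions = fr, stocks = st)
}

snap_levels <- function(fr, levels) {
  snapped <- vapply(as.numeric(fr), function(v)
    levels[which.min(abs(levels - v))], 0.0)
  out <- matrix(snapped, nrow(fr), ncol(fr), dimnames = dimnames(fr))
  s <- rowSums(out)
  bad <- s > 1 + 1e-12
  while (any(bad)) {  # lower the largest entry of offending rows one level
    for (r in which(bad)) {
      j <- which.max(out[r, ])
      li <- match(out[r, j], levels)
      out[r, j] <- levels[max(li - 1, 1)]
    }
    s <- rowSums(out); bad <- s > 1 + 1e-12
  }
  out
}

mutate_design <- function(d, problem, rate = 0.15) {
  fr <- d$fractions
  mask <- matrix(stats::runif(length(fr)) < rate, nrow(fr), ncol(fr))
  fr[mask] <- sample(problem$levels, sum(mask), replace = TRUE)
  fr <- snap_levels(fr, problem$levels)
  st <- d$stocks
  if (!is.null(problem$stock_bounds)) {
    b <- problem$stock_bounds
    pick <- stats::runif(nrow(b)) < rate
    if (any(pick))
      st[rownames(b)[pick]] <- exp(stats::runif(sum(pick),
                                                log(b[pick, 1]),
                                                log(b[pick, 2])))
  }
  list(fractions = fr, stocks = st)
}

crossover_design <- function(a, b, problem) {
  fr <- a$fractions
  pick <- stats::runif(nrow(fr)) < 0.5   # row-wise (per-cycle) exchange
  fr[pick, ] <- b$fractions[pick, , drop = FALSE]
  st <- a$stocks
  if (!is.null(problem$stock_bounds)) {
    sw <- stats::runif(length(st)) < 0.5
    st[sw] <- b$stocks[sw]
  }
  list(fractions = snap_levels(fr, problem$levels), stocks = st)
}

#' Search for an information-maximizing inflow pattern
#'
#' Elitist population search over the inflow-fraction matrix (row-wise
#' crossover plus random-reset mutation on the admissible level grid), with
#' optional co-optimization of stock concentrations within bounds.
#' Reproducible given `seed`; the returned protocol never scores below any
#' member of the initial population.
#'
#' @param problem a [design_problem()].
#' @param budget total number of design evaluations (>= `pop_size`).
#' @param seed RNG seed.
#' @param pop_size population size (default 12).
#' @param elite number of elites kept per generation (default 2).
#' @return the best-scoring `cfps_protocol`, with attributes `score` and
#'   `history` (data frame of generation, best score).
#' @export
optimize_design <- function(problem, budget = 60, seed = 1, pop_size = 12,
                            elite = 2) {
  if (budget < pop_size)
    stop("budget must be at least the population size")
  if (length(problem$designable) < 1 || problem$n_cycles < 1)
    stop("infeasible design space")
  set.seed(seed)
  pop <- replicate(pop_size, random_design(problem), simplify = FALSE)
  scores <- vapply(pop, function(d)
    as.numeric(score_design(problem_protocol(problem, d$fractions, d$stocks),
                            problem)), 0.0)
  evals <- pop_size
  hist <- data.frame(generation = 0, best = max(scores))
  gen <- 0
  while (evals < budget) {
    gen <- gen + 1
    ord <- order(scores, decreasing = TRUE)
    pop <- pop[ord]; scores <- scores[ord]
    n_off <- min(pop_size - elite, budget - evals)
    offspring <- lapply(seq_len(n_off), function(i) {
      pa <- pop[[sample(max(2, ceiling(pop_size / 2)), 1)]]
      pb <- pop[[sample(pop_size, 1)]]
      mutate_design(crossover_design(pa, pb, problem), problem)
    })
    off_scores <- vapply(offspring, function(d)
      as.numeric(score_design(problem_protocol(problem, d$fractions,
                                               d$stocks), problem)), 0.0)
    evals <- evals + n_off
    pop <- c(pop[seq_len(elite)], offspring)
    scores <- c(scores[seq_len(elite)], off_scores)
    hist <- rbind(hist, data.frame(generation = gen, best = max(scores)))
  }
  best <- pop[[which.max(scores)]]
  out <- problem_protocol(problem, best$fractions, best$stocks)
  attr(out, "score") <- max(scores)
  attr(out, "history") <- hist
  out
}
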