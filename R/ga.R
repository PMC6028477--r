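# Real-coded genetic algorithm over the ion-concentration box.
#
# The trained network is the fitness function; the search space is the box
# spanned by the observed ion concentrations (the models are not trusted to
# extrapolate). Individuals are real 5-vectors in mM. Selection is
# fitness-proportionate (roulette wheel); crossover is an arithmetic blend;
# mutation adds Gaussian noise scaled to the box width and clips to bounds;
# one elite individual survives unchanged each generation, which makes the
# best-fitness trajectory non-decreasing.

#' Genetic-algorithm configuration
#'
#' Defaults follow the source study's settings: population 50, 500
#' generations, crossover rate 0.85, mutation rate 0.1, roulette-wheel
#' selection. Operator forms (arithmetic blend crossover; Gaussian mutation
#' with SD `mutation_scale` x box width, clipped to bounds) and single-
#' individual elitism are this package's choices.
#'
#' @param population_size Number of individuals (>= 2).
#' @param generations Number of fitness-evaluation rounds (>= 1); evolution
#'   happens between rounds, so `generations = 1` evaluates only the
#'   initial population.
#' @param crossover_rate Per-pair probability of blending (default 0.85).
#' @param mutation_rate Per-gene probability of perturbation (default 0.1).
#' @param mutation_scale Mutation SD as a fraction of box width (default 0.1).
#' @param elitism_count Individuals copied unchanged into the next
#'   generation (default 1).
#' @return A list of class `"ga_control"`.
#' @export
ga_control <- function(population_size = 50L, generations = 500L,
                       crossover_rate = 0.85, mutation_rate = 0.1,
                       mutation_scale = 0.1, elitism_count = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_scale > 0, elitism_count >= 0L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 elitism_count = as.integer(elitism_count)),
            class = "ga_control")
}

#' Roulette-wheel (fitness-proportionate) selection
#'
#' Samples `k` indices with probability proportional to fitness. Fitness
#' vectors whose minimum is non-positive are first shifted so the minimum
#' maps to a small positive floor (`floor_frac` of the fitness spread);
#' an all-equal vector selects uniformly. Consumes the current RNG stream,
#' so results are deterministic given the RNG state.
#'
#' @param fitness Numeric vector; non-finite entries are floored.
#' @param k Number of draws (with replacement).
#' @param floor_frac Relative floor applied when shifting (default 1e-6).
#' @return Integer vector of `k` selected indices.
#' @examples
#' set.seed(1)
#' table(roulette_select(c(1, 3), 1000)) / 1000  # ~ 0.25 / 0.75
#' @export
roulette_select <- function(fitness, k, floor_frac = 1e-6) {
  stopifnot(k >= 1L, length(fitness) >= 1L)
  f <- fitness
  if (!any(is.finite(f))) stop("at least one finite fitness is required",
                               call. = FALSE)
  f[!is.finite(f)] <- min(f[is.finite(f)])
  spread <- max(f) - min(f)
  if (spread == 0) {
    return(sample.int(length(f), k, replace = TRUE))
  }
  if (min(f) <= 0) f <- f - min(f) + floor_frac * spread
  sample.int(length(f), k, replace = TRUE, prob = f / sum(f))
}

#' Real-coded variation operators
#'
#' `ga_crossover()` blends a pair of parent vectors arithmetically with
#' probability `rate`: offspring are `a*p1 + (1-a)*p2` and its mirror with
#' `a ~ Uniform(0,1)`; otherwise the parents are copied. `ga_mutate()`
#' perturbs each gene with probability `rate` by Gaussian noise with SD
#' `scale` x box width, then clips to the bounds, so offspring never leave
#' the box. Both consume the current RNG stream.
#'
#' @param parent_a,parent_b,individual Numeric gene vectors (ion mM).
#' @param rate Operator probability.
#' @param scale Mutation SD as a fraction of box width.
#' @param bounds 2 x p matrix, rows `lower` and `upper`.
#' @return `ga_crossover()`: list of two offspring; `ga_mutate()`: one
#'   vector within bounds.
#' @export
ga_crossover <- function(parent_a, parent_b, rate) {
  stopifnot(length(parent_a) == length(parent_b))
  if (stats::runif(1) < rate) {
    alpha <- stats::runif(1)
    list(alpha * parent_a + (1 - alpha) * parent_b,
         alpha * parent_b + (1 - alpha) * parent_a)
  } else {
    list(parent_a, parent_b)
  }
}

#' @rdname ga_crossover
#' @export
ga_mutate <- function(individual, rate, scale, bounds) {
  p <- length(individual)
  stopifnot(ncol(bounds) == p)
  width <- bounds[2L, ] - bounds[1L, ]
  hit <- stats::runif(p) < rate
  if (any(hit)) {
    individual[hit] <- individual[hit] +
      stats::rnorm(sum(hit), 0, scale * width[hit])
  }
  pmin(pmax(individual, bounds[1L, ]), bounds[2L, ])
}

#' Maximize a response model over the ion box with a genetic algorithm
#'
#' Runs a real-coded GA whose fitness is the model's predicted response on
#' the original scale. Candidates with non-finite predictions are assigned
#' the worst finite fitness of their generation and flagged in the result.
#'
#' @param object A `"rootnet"` fit, or a function mapping an `n x p` matrix
#'   of candidates to `n` fitness values (for benchmarking the optimizer
#'   against analytic surfaces).
#' @param bounds 2 x p numeric matrix (rows lower/upper). For a `"rootnet"`
#'   object the default is the fit's normalization range of each predictor,
#'   i.e. the box spanned by the data.
#' @param control A [ga_control()] list.
#' @param seed Integer seed; the run is deterministic given it.
#' @param ... Unused.
#' @return Object of class `"rootnet_ga"`: list with `par` (named optimal
#'   ion vector), `value` (predicted response at the optimum), `trajectory`
#'   (best-ever fitness per generation), `n_nonfinite`, `control`, `bounds`,
#'   `seed`.
#' @examples
#' sphere <- function(X) -rowSums((X - 2)^2)
#' b <- rbind(lower = c(0, 0), upper = c(5, 5))
#' ga_optimize(sphere, bounds = b, control = ga_control(20, 50), seed = 1)$par
#' @export
ga_optimize <- function(object, bounds = NULL, control = ga_control(),
                        seed = 1L, ...) {
  stopifnot(inherits(control, "ga_control"))
  if (inherits(object, "rootnet")) {
    if (is.null(bounds)) {
      rng <- object$norm
      bounds <- rbind(lower = rng$min[object$var_names],
                      upper = rng$max[object$var_names])
    }
    fitness_fn <- function(X) {
      df <- as.data.frame(X)
      names(df) <- object$var_names
      predict(object, df)
    }
    gene_names <- object$var_names
  } else if (is.function(object)) {
    if (is.null(bounds)) stop("'bounds' is required for a function objective",
                              call. = FALSE)
    fitness_fn <- object
    gene_names <- colnames(bounds) %||% paste0("x", seq_len(ncol(bounds)))
  } else {
    stop("'object' must be a rootnet fit or a function", call. = FALSE)
  }
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(bounds[1L, ] >= bounds[2L, ])) {
    stop("'bounds' must be a 2 x p matrix with lower < upper", call. = FALSE)
  }
  p <- ncol(bounds)
  np <- control$population_size

  with_seed(seed, {
    pop <- sapply(seq_len(p), function(j)
      stats::runif(np, bounds[1L, j], bounds[2L, j]))
    pop <- matrix(pop, nrow = np)
    best_par <- NULL
    best_val <- -Inf
    trajectory <- numeric(control$generations)
    n_nonfinite <- 0L
    for (gen in seq_len(control$generations)) {
      fit <- fitness_fn(pop)
      bad <- !is.finite(fit)
      if (any(bad)) {
        n_nonfinite <- n_nonfinite + sum(bad)
        fit[bad] <- if (all(bad)) 0 else min(fit[!bad])
      }
      gi <- which.max(fit)
      if (fit[gi] > best_val) {
        best_val <- fit[gi]
        best_par <- pop[gi, ]
      }
      trajectory[gen] <- best_val
      if (gen == control$generations) break
      elite_n <- min(control$elitism_count, np)
      elite <- pop[order(-fit)[seq_len(elite_n)], , drop = FALSE]
      children <- matrix(NA_real_, 0L, p)
      while (nrow(children) < np - elite_n) {
        pair <- roulette_select(fit, 2L)
        off <- ga_crossover(pop[pair[1L], ], pop[pair[2L], ],
                            control$crossover_rate)
        off <- lapply(off, ga_mutate, rate = control$mutation_rate,
                      scale = control$mutation_scale, bounds = bounds)
        children <- rbind(children, off[[1L]], off[[2L]])
      }
      pop <- rbind(elite, children[seq_len(np - elite_n), , drop = FALSE])
    }
    structure(list(par = stats::setNames(best_par, gene_names),
                   value = best_val, trajectory = trajectory,
                   n_nonfinite = n_nonfinite, control = control,
                   bounds = bounds, seed = seed),
              class = "rootnet_ga")
  })
}

#' @export
print.rootnet_ga <- function(x, digits = 3, ...) {
  cat(sprintf("GA optimum after %d generations (population %d, seed %d)\n",
              x$control$generations, x$control$population_size, x$seed))
  cat("Optimal inputs:\n")
  print(round(x$par, digits))
  cat("Predicted response at optimum:", format(x$value, digits = digits + 1), "\n")
  if (x$n_nonfinite > 0L) {
    cat("note:", x$n_nonfinite, "candidate(s) had non-finite fitness\n")
  }
  invisible(x)
}

#' Optimize the medium in salt space
#'
#' Searches over the four macronutrient salt masses (within their data
#' ranges) rather than directly over ion concentrations, mapping each
#' candidate through the salt-to-ion stoichiometry before evaluating the
#' trained network. Because the ions are determined by four salts, the data
#' lie on a 4-D manifold inside the 5-D ion box; constraining the search to
#' salt space keeps every candidate on that manifold, where the surrogate
#' is supported by data, instead of letting the optimizer exploit
#' extrapolation artifacts in unexplored corners of the ion box.
#'
#' @param object A `"rootnet"` fit whose predictors are the five ions.
#' @param formulations Salt table used to derive the per-salt search
#'   ranges (default the packaged 36 media).
#' @param masses,cl_convention Stoichiometry options, see
#'   [ions_from_salts()].
#' @param control A [ga_control()] list.
#' @param seed Integer seed.
#' @return Object of classes `"rootnet_medium"` and `"rootnet_ga"`; as
#'   [ga_optimize()] plus `salts` (named optimal salt masses, mg/L), with
#'   `par` holding the induced ion concentrations.
#' @seealso [ga_optimize()] for the plain ion-box search.
#' @export
optimize_medium <- function(object, formulations = gn15_media(),
                            masses = macronutrient_molar_masses(),
                            cl_convention = "per_salt",
                            control = ga_control(), seed = 1L) {
  stopifnot(inherits(object, "rootnet"))
  stopifnot_cols(formulations, salt_cols(), "formulations")
  sb <- rbind(lower = vapply(formulations[salt_cols()], min, numeric(1)),
              upper = vapply(formulations[salt_cols()], max, numeric(1)))
  # a salt fixed at one level in the data contributes no searchable range
  fixed <- sb[1L, ] >= sb[2L, ]
  if (all(fixed)) stop("no salt varies in 'formulations'", call. = FALSE)
  sb_search <- sb[, !fixed, drop = FALSE]
  to_ions <- function(S) {
    full <- matrix(sb[1L, ], nrow(S), 4L, byrow = TRUE,
                   dimnames = list(NULL, salt_cols()))
    full[, colnames(sb_search)] <- S
    fdf <- data.frame(code = seq_len(nrow(S)), full, check.names = FALSE)
    ions_from_salts(fdf, masses = masses, cl_convention = cl_convention)
  }
  fitness <- function(S) {
    predict(object, to_ions(S))
  }
  res <- ga_optimize(fitness, bounds = sb_search, control = control,
                     seed = seed)
  salts <- stats::setNames(sb[1L, ], salt_cols())
  salts[colnames(sb_search)] <- res$par
  ions <- to_ions(matrix(res$par, 1L, dimnames = list(NULL, colnames(sb_search))))
  res$salts <- salts
  res$par <- stats::setNames(as.numeric(ions[1L, ion_names()]), ion_names())
  class(res) <- c("rootnet_medium", class(res))
  res
}

#' @export
print.rootnet_medium <- function(x, digits = 3, ...) {
  cat("Salt-space GA optimum (mapped through stoichiometry)\n")
  cat("Optimal salt masses (mg/L):\n")
  print(round(x$salts, 1))
  cat("Induced ion concentrations (mM):\n")
  print(round(x$par, digits))
  cat("Predicted response at optimum:", format(x$value, digits = digits + 1), "\n")
  invisible(x)
}
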