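#' Genetic-algorithm configuration
#'
#' Settings for the bounded real-coded genetic algorithm used to minimize the
#' least-squares distance between observed fermentation data and simulated
#' trajectories. Defaults are robust for bounded problems of up to about 15
#' dimensions.
#'
#' @param bounds named list of `c(low, high)` pairs, one per free parameter;
#'   names define the search-vector layout.
#' @param population_size number of individuals per generation.
#' @param generations number of generations.
#' @param crossover_prob probability that an offspring is produced by blend
#'   crossover rather than copied from a parent.
#' @param mutation_prob per-gene mutation probability.
#' @param mutation_scale Gaussian mutation standard deviation as a fraction of
#'   each parameter's bound range.
#' @param elite_count individuals copied unchanged into the next generation.
#' @param tournament_size tournament size for parent selection.
#' @param seed integer seed; the whole run is reproducible given it.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(bounds,
                      population_size = 80,
                      generations = 200,
                      crossover_prob = 0.9,
                      mutation_prob = 0.1,
                      mutation_scale = 0.1,
                      elite_count = 2,
                      tournament_size = 3,
                      seed = 1L) {
  if (!is.list(bounds) || is.null(names(bounds)) || any(names(bounds) == "")) {
    stop("bounds must be a named list of c(low, high) pairs", call. = FALSE)
  }
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stop("every bound pair must satisfy low < high (zero-measure bounds rejected)",
         call. = FALSE)
  }
  if (population_size < elite_count + 2) {
    stop("population_size must be >= elite_count + 2", call. = FALSE)
  }
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_scale > 0, tournament_size >= 1, generations >= 1)
  structure(list(bounds = bounds, lower = lo, upper = hi,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_scale = mutation_scale,
                 elite_count = as.integer(elite_count),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Minimize an objective with a real-coded genetic algorithm
#'
#' Bounded real-coded GA with tournament selection, blend (BLX-type)
#' crossover, Gaussian mutation clipped to the bounds, and elitism. Fully
#' reproducible given `config$seed`; non-finite objective values are treated
#' as `+Inf` (penalty).
#'
#' @param objective function taking a named numeric vector (layout given by
#'   `config$bounds`) and returning a scalar to minimize.
#' @param config a [ga_config()].
#' @return object of class `ga_fit`: `best_params` (named numeric),
#'   `best_value`, `history` (per-generation best objective, non-increasing
#'   by elitism), `evaluations`, `seed`.
#' @export
ga_minimize <- function(objective, config) {
  stopifnot(inherits(config, "ga_config"))
  lo <- config$lower
  hi <- config$upper
  d <- length(lo)
  np <- config$population_size
  nm <- names(config$bounds)
  mut_sd <- config$mutation_scale * (hi - lo)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  eval1 <- function(x) {
    names(x) <- nm
    v <- tryCatch(objective(x), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  pop <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                nrow = np, ncol = d)
  fit <- apply(pop, 1L, eval1)
  evals <- np
  history <- numeric(config$generations)

  pick <- function() {
    idx <- sample.int(np, config$tournament_size, replace = TRUE)
    idx[which.min(fit[idx])]
  }

  for (g in seq_len(config$generations)) {
    ord <- order(fit)
    newpop <- matrix(NA_real_, nrow = np, ncol = d)
    elite <- seq_len(config$elite_count)
    newpop[elite, ] <- pop[ord[elite], , drop = FALSE]
    for (k in (config$elite_count + 1L):np) {
      p1 <- pop[pick(), ]
      if (stats::runif(1) < config$crossover_prob) {
        p2 <- pop[pick(), ]
        u <- stats::runif(d, -0.25, 1.25)
        child <- p1 + u * (p2 - p1)
      } else {
        child <- p1
      }
      mut <- stats::runif(d) < config$mutation_prob
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mut_sd[mut])
      }
      newpop[k, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    keep <- fit[ord[elite]]
    fit <- c(keep, apply(pop[-elite, , drop = FALSE], 1L, eval1))
    evals <- evals + (np - config$elite_count)
    history[g] <- min(fit)
  }

  best <- which.min(fit)
  bp <- pop[best, ]
  names(bp) <- nm
  structure(list(best_params = bp, best_value = fit[best],
                 history = history, evaluations = evals,
                 seed = config$seed, config = config),
            class = "ga_fit")
}

#' Weighted least-squares objective for fermentation data
#'
#' Simulates the cofermentation model at the observed time points and returns
#' the weighted sum of squared residuals pooled over state variables.
#' Missing observations (`NA`) are skipped. By default each variable is
#' weighted by the inverse of its observed range squared, so biomass on a
#' 5 g/L scale and lactate on a 70 g/L scale contribute comparably.
#'
#' @param observed data.frame with column `t_h` and any of
#'   `X_gL, glc_gL, xyl_gL, ara_gL, la_gL`; at least 2 time points.
#' @param params a [monod_params()].
#' @param weights optional named non-negative weights per variable; default
#'   inverse squared observed range.
#' @param init optional [ferment_state()]; defaults to the first observed row
#'   (missing fields taken as 0).
#' @return scalar objective; `+Inf` (with a warning) on simulation failure.
#' @export
sse_objective <- function(observed, params, weights = NULL, init = NULL) {
  vars <- intersect(c("X_gL", "glc_gL", "xyl_gL", "ara_gL", "la_gL"),
                    names(observed))
  stopifnot(nrow(observed) >= 2, length(vars) >= 1)
  if (is.null(weights)) {
    weights <- vapply(vars, function(v) {
      r <- diff(range(observed[[v]], na.rm = TRUE))
      if (r > 0) 1 / r^2 else 1
    }, numeric(1))
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  weights <- weights[vars]
  weights[is.na(weights)] <- 0
  if (is.null(init)) {
    g <- function(v) if (v %in% names(observed) && is.finite(observed[[v]][1]))
      observed[[v]][1] else 0
    lg <- if ("lignin_gL" %in% names(observed)) observed$lignin_gL[1] else 0
    init <- ferment_state(X = g("X_gL"), S_glc = g("glc_gL"),
                          S_xyl = g("xyl_gL"), S_ara = g("ara_gL"),
                          P_la = g("la_gL"), L = lg, t = observed$t_h[1])
  }
  sim <- tryCatch(
    simulate_fermentation(params, init, observed$t_h),
    error = function(e) {
      warning("simulation failed in objective: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  if (is.null(sim)) return(Inf)
  total <- 0
  for (v in vars) {
    res <- observed[[v]] - sim[[v]]
    total <- total + weights[[v]] * sum(res^2, na.rm = TRUE)
  }
  total
}

#' Fit kinetic parameters to an observed fermentation series
#'
#' Genetic-algorithm least-squares estimation of selected Monod parameters,
#' all other parameters held at `start_params`. Free parameters are named with
#' a `.` separating vector fields, e.g. `"mu_max.glc"`, `"Y_XS.xyl"`,
#' `"K_rep"`.
#'
#' @param observed observed series as in [sse_objective()].
#' @param start_params full [monod_params()] supplying the fixed values.
#' @param config a [ga_config()] whose bounds name the free parameters.
#' @param weights,init passed to [sse_objective()].
#' @return a `ga_fit` with an extra element `best_monod`, the full parameter
#'   object with the fitted values substituted.
#' @export
fit_kinetics <- function(observed, start_params, config,
                         weights = NULL, init = NULL) {
  stopifnot(inherits(start_params, "monod_params"))
  free <- names(config$bounds)
  obj <- function(x) {
    sse_objective(observed, set_monod(start_params, x),
                  weights = weights, init = init)
  }
  fit <- ga_minimize(obj, config)
  fit$best_monod <- set_monod(start_params, fit$best_params)
  fit
}

## Substitute named free parameters ("mu_max.glc", "K_rep", ...) into a
## monod_params object, revalidating.
set_monod <- function(params, x) {
  p <- unclass(params)
  for (nm in names(x)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      p[[parts[1]]][[parts[2]]] <- x[[nm]]
    } else {
      p[[nm]] <- x[[nm]]
    }
  }
  do.call(monod_params, p)
}
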