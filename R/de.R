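#' Differential evolution minimizer
#'
#' Self-contained rand/1/bin differential evolution within box bounds: the
#' population is initialized uniformly inside the bounds from the seed, each
#' generation builds mutants `a + F (b - c)` from three distinct random
#' members (with the scale factor F dithered uniformly per candidate in
#' `mutation`), applies binomial crossover with rate `recombination` (one
#' coordinate always taken from the mutant), clips candidates to the bounds
#' and keeps them only if they do not worsen the cost. Candidates whose
#' objective comes back non-finite are assigned `+Inf` and counted. The run
#' ends at the generation budget or when the finite population cost spread
#' falls below `tol`.
#'
#' @param objective Function mapping a parameter vector to a scalar cost.
#' @param lower,upper Finite bound vectors (equal length, `lower < upper`).
#' @param popsize Population size (>= 4); default 10, the protocol used for
#'   the validation runs.
#' @param generations Generation budget.
#' @param mutation Length-2 dither range for the mutation factor, in
#'   `[0.5, 1)`.
#' @param recombination Crossover probability in (0, 1].
#' @param seed Integer seed; identical seeds give identical runs.
#' @param tol Population-spread termination tolerance (0 disables).
#' @param init Optional matrix (rows = members) injected over the start of
#'   the initial population, e.g. the model's default parameter vector.
#' @param param_names Optional names for the parameter vector.
#' @param run_id Label stored on the result.
#' @return An object of class `de_run`: best parameters, best cost, the
#'   per-generation best-cost trace (non-increasing), and bookkeeping
#'   (seed, popsize, evaluations, non-finite count).
#' @examples
#' run <- differential_evolution(function(x) sum(x^2),
#'                               lower = rep(-5, 3), upper = rep(5, 3),
#'                               popsize = 15, generations = 50, seed = 1)
#' run$best_cost
#' @export
differential_evolution <- function(objective, lower, upper,
                                   popsize = 10, generations = 100,
                                   mutation = c(0.5, 1),
                                   recombination = 0.7,
                                   seed = NULL, tol = 0,
                                   init = NULL, param_names = NULL,
                                   run_id = "de") {
  d <- length(lower)
  stopifnot(length(upper) == d, d >= 1)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  if (popsize < 4) stop("popsize must be >= 4", call. = FALSE)
  if (is.null(param_names)) param_names <- names(lower)

  safe_obj <- function(x) {
    v <- tryCatch(objective(x), error = function(e) Inf)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
  }

  runner <- function() {
    pop <- matrix(stats::runif(popsize * d, rep(lower, each = popsize),
                               rep(upper, each = popsize)),
                  popsize, d)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      k <- min(nrow(init), popsize)
      pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                     rep(lower, each = k)),
                                rep(upper, each = k))
    }
    cost <- apply(pop, 1, safe_obj)
    n_eval <- popsize
    n_nonfinite <- sum(!is.finite(cost))
    trace <- numeric(generations)
    gens_run <- 0L
    for (g in seq_len(generations)) {
      for (i in seq_len(popsize)) {
        idx <- sample(seq_len(popsize)[-i], 3L)
        Fm <- stats::runif(1, mutation[1], mutation[2])
        mutant <- pop[idx[1], ] + Fm * (pop[idx[2], ] - pop[idx[3], ])
        cross <- stats::runif(d) < recombination
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        v <- safe_obj(trial)
        n_eval <- n_eval + 1L
        if (!is.finite(v)) n_nonfinite <- n_nonfinite + 1L
        if (v <= cost[i]) {
          pop[i, ] <- trial
          cost[i] <- v
        }
      }
      gens_run <- g
      trace[g] <- min(cost)
      fin <- cost[is.finite(cost)]
      if (tol > 0 && length(fin) == popsize &&
          (max(fin) - min(fin)) < tol) break
    }
    best <- which.min(cost)
    list(pop = pop, cost = cost, best = best,
         trace = trace[seq_len(gens_run)],
         n_eval = n_eval, n_nonfinite = n_nonfinite,
         gens_run = gens_run)
  }

  res <- if (is.null(seed)) runner() else with_seed(seed, runner())
  best_params <- stats::setNames(res$pop[res$best, ], param_names)
  structure(list(
    run_id = run_id, algorithm = "rand/1/bin",
    seed = seed, popsize = popsize,
    generations = res$gens_run,
    best_params = best_params,
    best_cost = res$cost[res$best],
    trace = res$trace,
    n_eval = res$n_eval, n_nonfinite = res$n_nonfinite,
    lower = lower, upper = upper),
    class = "de_run")
}

#' @export
print.de_run <- function(x, ...) {
  cat(sprintf("<de_run> %s: best cost %.6g after %d generations (seed %s)\n",
              x$run_id, x$best_cost, x$generations,
              if (is.null(x$seed)) "none" else x$seed))
  print(round(x$best_params, 6))
  invisible(x)
}

#' Tidy a differential-evolution run
#'
#' @param x A `de_run`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `lower`, `upper`.
#' @method tidy de_run
#' @export
tidy.de_run <- function(x, ...) {
  nm <- names(x$best_params)
  if (is.null(nm)) nm <- paste0("p", seq_along(x$best_params))
  tibble::tibble(term = nm, estimate = unname(x$best_params),
                 lower = x$lower, upper = x$upper)
}

#' @rdname tidy.de_run
#' @method glance de_run
#' @export
glance.de_run <- function(x, ...) {
  tibble::tibble(run_id = x$run_id, best_cost = x$best_cost,
                 generations = x$generations, n_eval = x$n_eval,
                 n_nonfinite = x$n_nonfinite,
                 popsize = x$popsize,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @method autoplot de_run
#' @export
autoplot.de_run <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$trace),
                       best_cost = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                   y = .data$best_cost)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best cost so far")
}
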