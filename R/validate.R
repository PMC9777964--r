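#' Cost-evaluation configuration
#'
#' Bundles the knobs shared by every validation run: the cost convention,
#' integrator tolerances, and the pre-roll (burn-in) simulated before the
#' first data point so the state reaches the periodic attractor of the
#' circadian drive before the stressor arrives.
#'
#' @param normalization,averaging Cost convention, see [sse_cost()].
#' @param cost Which cost statistic drives the optimization.
#' @param rtol,atol Integration tolerances.
#' @param burn_in Minutes of pre-roll before the first sample (default one
#'   simulated day).
#' @return A list of class `cost_config`.
#' @export
cost_config <- function(normalization = c("data", "shape"),
                        averaging = c("mean", "printed"),
                        cost = c("sse", "max_max", "mean_max"),
                        rtol = 1e-6, atol = 1e-9, burn_in = 1440) {
  structure(list(normalization = match.arg(normalization),
                 averaging = match.arg(averaging),
                 cost = match.arg(cost),
                 rtol = rtol, atol = atol, burn_in = burn_in),
            class = "cost_config")
}

#' Evaluate a parameter set against one subject
#'
#' Initializes the model at its flat-driver steady state, integrates from
#' `burn_in` minutes before the subject's first sample to the last sample
#' with the model's declared drivers (including the canonical stress
#' episode), and computes the configured cost on the subject's grid.
#' Parameters outside the declared bounds produce a warning, not an error
#' (generalization runs legitimately carry parameters across datasets).
#' Integration failures yield a breakdown with `total = Inf` and the failure
#' message in `$failure`.
#'
#' @param model An `hpa_model`.
#' @param params Named parameter overrides (may be a free subset).
#' @param subject Subject record tibble (`time_min` plus hormone columns).
#' @param config A [cost_config()].
#' @return A `cost_breakdown`.
#' @export
evaluate_params <- function(model, params = NULL, subject,
                            config = cost_config()) {
  p <- full_params(model, params)
  tb <- model$params
  out_of_bounds <- p < stats::setNames(tb$lower, tb$name)[names(p)] |
    p > stats::setNames(tb$upper, tb$name)[names(p)]
  if (any(out_of_bounds))
    warning("parameters outside declared bounds: ",
            paste(names(p)[out_of_bounds], collapse = ", "), call. = FALSE)
  span <- c(min(subject$time_min) - config$burn_in, max(subject$time_min))
  res <- tryCatch({
    sol <- simulate_model(model, p, span = span,
                          rtol = config$rtol, atol = config$atol)
    switch(config$cost,
           sse = sse_cost(sol, model, subject,
                          normalization = config$normalization,
                          averaging = config$averaging),
           max_max = , mean_max = {
             v <- if (config$cost == "max_max")
               max_max_cost(sol, model, subject, config$normalization)
             else
               mean_max_cost(sol, model, subject, config$normalization)
             structure(list(residuals = NULL, per_hormone = NULL,
                            n_points = length(subject$time_min),
                            n_hormones = NA_integer_, total = v,
                            convention = list(
                              normalization = config$normalization,
                              averaging = config$cost)),
                       class = "cost_breakdown")
           })
  }, error = function(e) {
    structure(list(residuals = NULL, per_hormone = NULL,
                   n_points = length(subject$time_min),
                   n_hormones = NA_integer_, total = Inf,
                   failure = conditionMessage(e),
                   convention = list(normalization = config$normalization,
                                     averaging = config$averaging)),
              class = "cost_breakdown")
  })
  res
}

#' Free parameters of a model
#'
#' @param model An `hpa_model`.
#' @return Names of parameters flagged optimizable.
#' @export
free_params <- function(model) model$params$name[model$params$optimize]

#' Repeated calibration of a model against one dataset
#'
#' Runs `repeats` independent differential-evolution optimizations of
#' [evaluate_params()] over the free-parameter subspace (all other
#' parameters held at their defaults), one distinct seed per repeat. The
#' model's default free-parameter vector is injected into each initial
#' population, so an optimized cost can never exceed the default-parameter
#' cost. With an empty free set the dataset is evaluated once at the
#' defaults and no optimization happens.
#'
#' @param model An `hpa_model`.
#' @param subject Subject record tibble (or [cohort_mean()] profile).
#' @param free Free parameter names; default the model's optimizable flags.
#' @param repeats Number of independent optimizer repeats.
#' @param popsize,generations Differential-evolution protocol.
#' @param seeds Integer seeds, one per repeat (must be distinct).
#' @param config A [cost_config()].
#' @param dataset_id Label for reporting.
#' @return An object of class `validation_runs`: the list of `de_run`
#'   objects, the default-parameter cost, and labels.
#' @export
run_validation <- function(model, subject, free = free_params(model),
                           repeats = 5, popsize = 10, generations = 40,
                           seeds = seq_len(repeats),
                           config = cost_config(),
                           dataset_id = subject$subject_id[1]) {
  if (length(seeds) != repeats || anyDuplicated(seeds))
    stop("supply one distinct seed per repeat", call. = FALSE)
  defaults <- param_defaults(model)
  default_cost <- evaluate_params(model, NULL, subject, config)$total

  if (length(free) == 0L) {
    runs <- list(structure(list(
      run_id = paste0(dataset_id, "-defaults"), algorithm = "none",
      seed = NA_integer_, popsize = 0L, generations = 0L,
      best_params = defaults[character(0)], best_cost = default_cost,
      trace = numeric(0), n_eval = 1L, n_nonfinite = 0L,
      lower = numeric(0), upper = numeric(0)), class = "de_run"))
  } else {
    unknown <- setdiff(free, model$params$name)
    if (length(unknown))
      stop("free parameters not in the model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    flagged <- model$params$name[model$params$optimize]
    tb <- model$params[match(free, model$params$name), ]
    objective <- function(theta) {
      evaluate_params(model, stats::setNames(theta, free), subject,
                      config)$total
    }
    runs <- purrr::map(seq_len(repeats), function(r) {
      differential_evolution(
        objective, lower = stats::setNames(tb$lower, free),
        upper = stats::setNames(tb$upper, free),
        popsize = popsize, generations = generations,
        seed = seeds[r], init = matrix(defaults[free], 1),
        param_names = free,
        run_id = sprintf("%s-r%d", dataset_id, r))
    })
  }
  structure(list(runs = runs, dataset_id = dataset_id,
                 model_name = model$name, free = free,
                 default_cost = default_cost, config = config,
                 seeds = seeds),
            class = "validation_runs")
}

#' Summarize repeated runs of one dataset
#'
#' Mean, sample standard deviation and best of the repeat best-costs.
#'
#' @param x A `validation_runs` object or a numeric vector of costs.
#' @return A one-row tibble: `n_runs`, `mean_cost`, `sd_cost`, `best_cost`.
#' @export
summarize_runs <- function(x) {
  costs <- if (inherits(x, "validation_runs"))
    vapply(x$runs, function(r) r$best_cost, numeric(1)) else as.numeric(x)
  tibble::tibble(
    n_runs = length(costs),
    mean_cost = mean(costs),
    sd_cost = if (length(costs) > 1L) stats::sd(costs) else 0,
    best_cost = min(costs))
}

#' Aggregate per-dataset costs into an overall score
#'
#' The overall suitability of a model is the mean of its per-dataset mean
#' costs; datasets therefore weigh equally regardless of repeat count.
#'
#' @param cost_table Tibble with columns `dataset` and `cost` (one row per
#'   run).
#' @return List with `per_dataset` (mean/SD/best per dataset) and `overall`
#'   (mean and SD of the per-dataset means).
#' @export
aggregate_costs <- function(cost_table) {
  per <- cost_table |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_cost = mean(.data$cost),
      sd_cost = if (dplyr::n() > 1L) stats::sd(.data$cost) else 0,
      best_cost = min(.data$cost),
      .groups = "drop")
  list(per_dataset = per,
       overall = tibble::tibble(
         overall_mean = mean(per$mean_cost),
         overall_sd = if (nrow(per) > 1L) stats::sd(per$mean_cost) else 0))
}

#' Validate a model across several subjects of a cohort
#'
#' Runs the repeated-optimization protocol on each selected dataset (subject
#' ids plus optionally `"mean"` for the cohort mean profile) and aggregates:
#' per-dataset mean ± SD and best single cost, and the overall score as the
#' mean of per-dataset means. Seeds are derived deterministically from
#' `base_seed` and are distinct across datasets and repeats.
#'
#' @param model An `hpa_model`.
#' @param cohort An `hpa_cohort`.
#' @param subjects Dataset selection; default subjects 1, 10, 20, 30, 40,
#'   50 and the cohort mean (the seven-dataset protocol).
#' @param repeats,popsize,generations Optimization protocol per dataset.
#' @param base_seed Integer from which all run seeds derive.
#' @param free Free parameter names (default: the model's optimizable flags).
#' @param config A [cost_config()].
#' @return An object of class `validation_report`.
#' @export
batch_over_subjects <- function(model, cohort,
                                subjects = c("1", "10", "20", "30", "40",
                                             "50", "mean"),
                                repeats = 5, popsize = 10,
                                generations = 40, base_seed = 1,
                                free = free_params(model),
                                config = cost_config()) {
  ids <- cohort_subjects(cohort)
  unknown <- setdiff(subjects, c(ids, "mean"))
  if (length(unknown))
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  all_runs <- purrr::imap(stats::setNames(subjects, subjects),
                          function(id, nm) {
    j <- match(id, subjects)
    seeds <- base_seed + (j - 1L) * repeats + seq_len(repeats)
    run_validation(model, cohort_subject(cohort, id), free = free,
                   repeats = repeats, popsize = popsize,
                   generations = generations, seeds = seeds,
                   config = config, dataset_id = id)
  })
  cost_table <- purrr::map_dfr(all_runs, function(vr)
    tibble::tibble(dataset = vr$dataset_id,
                   cost = vapply(vr$runs, function(r) r$best_cost,
                                 numeric(1))))
  agg <- aggregate_costs(cost_table)
  per <- agg$per_dataset |>
    dplyr::left_join(
      purrr::map_dfr(all_runs, function(vr)
        tibble::tibble(dataset = vr$dataset_id,
                       default_cost = vr$default_cost)),
      by = "dataset")
  structure(list(model_name = model$name,
                 per_dataset = per[match(subjects, per$dataset), ],
                 overall = agg$overall,
                 runs = all_runs,
                 protocol = list(subjects = subjects, repeats = repeats,
                                 popsize = popsize,
                                 generations = generations,
                                 base_seed = base_seed, free = free)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> model '%s': overall mean cost %.6g (SD %.3g)\n",
              x$model_name, x$overall$overall_mean, x$overall$overall_sd))
  print(x$per_dataset)
  invisible(x)
}

#' Tidy / glance a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-dataset table; `glance()`: one row with the
#'   overall mean-of-means, its SD and the best single cost.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$per_dataset

#' @rdname tidy.validation_report
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(model = x$model_name,
                 overall_mean = x$overall$overall_mean,
                 overall_sd = x$overall$overall_sd,
                 best_single = min(x$per_dataset$best_cost),
                 n_datasets = nrow(x$per_dataset),
                 n_runs = sum(x$per_dataset$n_runs))
}

#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- object$per_dataset
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$mean_cost)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_cost - .data$sd_cost,
                                        ymax = .data$mean_cost + .data$sd_cost),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$default_cost), shape = 4,
                        colour = "red") +
    ggplot2::labs(x = "dataset", y = "cost (mean ± SD; x = defaults)")
}

#' Rank models by overall validation score
#'
#' @param reports A list of `validation_report` objects.
#' @return A tibble sorted ascending by overall mean cost (ties broken by
#'   model name).
#' @export
rank_models <- function(reports) {
  purrr::map_dfr(reports, glance.validation_report) |>
    dplyr::arrange(.data$overall_mean, .data$model)
}

#' Cross-dataset generalization matrix
#'
#' Evaluates each saved parameter set against every subject of a cohort,
#' answering whether parameters optimized on one dataset transfer to others.
#' Failures are recorded as `Inf` cells, never aborts. Group-wise mean costs
#' summarize transfer within and across clinical groups.
#'
#' @param model An `hpa_model`.
#' @param param_sets Tibble with a `run_id` column plus one column per
#'   (free) parameter, e.g. `load_results()$parameters`.
#' @param cohort An `hpa_cohort`.
#' @param config A [cost_config()].
#' @return An object of class `generalization_result`: `matrix` (parameter
#'   set x subject), `by_group` tibble of group-wise mean costs, and the
#'   subject/group table.
#' @export
generalization_matrix <- function(model, param_sets, cohort,
                                  config = cost_config()) {
  pnames <- intersect(names(param_sets), model$params$name)
  if (length(pnames) == 0L)
    stop("param_sets contains no parameter of the model", call. = FALSE)
  ids <- cohort_subjects(cohort)
  m <- matrix(NA_real_, nrow(param_sets), length(ids),
              dimnames = list(param_sets$run_id, ids))
  groups <- tibble::as_tibble(cohort) |>
    dplyr::distinct(.data$subject_id, .data$group)
  for (i in seq_len(nrow(param_sets))) {
    p <- unlist(param_sets[i, pnames])
    for (j in seq_along(ids)) {
      subject <- cohort_subject(cohort, ids[j])
      bd <- suppressWarnings(evaluate_params(model, p, subject, config))
      m[i, j] <- bd$total
    }
  }
  by_group <- tibble::tibble(
    run_id = rep(rownames(m), times = length(unique(groups$group))),
    group = rep(sort(unique(groups$group)), each = nrow(m)))
  by_group$mean_cost <- purrr::map2_dbl(by_group$run_id, by_group$group,
    function(rid, g) {
      cols <- groups$subject_id[groups$group == g]
      mean(m[rid, cols])
    })
  structure(list(matrix = m, by_group = by_group, subjects = groups),
            class = "generalization_result")
}

#' @export
print.generalization_result <- function(x, ...) {
  cat(sprintf("<generalization_result> %d parameter sets x %d subjects\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(x$by_group)
  invisible(x)
}

#' @method tidy generalization_result
#' @export
tidy.generalization_result <- function(x, ...) {
  tibble::as_tibble(as.table(x$matrix), .name_repair = "minimal") |>
    stats::setNames(c("run_id", "subject_id", "cost")) |>
    dplyr::left_join(x$subjects, by = "subject_id")
}
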