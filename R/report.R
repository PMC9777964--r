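# Command layer: the verify / validate / generalize / synth front-ends used
# by the Rscript CLI (inst/cli/hpavv). Every command resolves its inputs up
# front, writes its outputs plus a manifest (config copy, seeds, versions,
# file hashes) into the output directory, and renders figures only from the
# same sampled tables it saves.

.config_defaults <- list(
  command = NULL, model = "minimal", dataset = NULL,
  schema = "tsst", subjects = c("1", "10", "20", "30", "40", "50", "mean"),
  repeats = 5, popsize = 10, generations = 40, seed = 1,
  span = c(-30, 110), sample_step = 10,
  cost = list(normalization = "data", averaging = "mean", cost = "sse",
              rtol = 1e-6, atol = 1e-9, burn_in = 1440),
  synth = list(n_subjects = 58, anomaly_fraction = 1 / 58),
  results = NULL, out_dir = ".", log_level = "info")

#' Build a run configuration
#'
#' Reads a YAML config file (or takes a list) and fills defaults. All
#' referenced names (model, dataset path, results store) must resolve before
#' execution; a serialized copy of the effective configuration is written
#' next to every command's outputs.
#'
#' @param x Path to a YAML file, or a named list of settings.
#' @param ... Named overrides applied on top.
#' @return A list of class `run_config`.
#' @export
run_config <- function(x = list(), ...) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  cfg <- utils::modifyList(.config_defaults, cfg)
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  cfg <- utils::modifyList(cfg, dots)
  if (!is.null(cfg$command) &&
      !cfg$command %in% c("verify", "validate", "generalize", "synth"))
    stop("unknown command: ", cfg$command, call. = FALSE)
  get_model(cfg$model)  # must resolve
  if (!is.null(cfg$dataset) && !file.exists(cfg$dataset))
    stop("dataset file not found: ", cfg$dataset, call. = FALSE)
  if (!is.null(cfg$results) && !dir.exists(cfg$results))
    stop("results directory not found: ", cfg$results, call. = FALSE)
  structure(cfg, class = "run_config")
}

cfg_cost <- function(cfg) {
  do.call(cost_config, cfg$cost)
}

write_manifest <- function(cfg, files, out_dir) {
  files <- files[file.exists(files)]
  manifest <- list(
    config = unclass(cfg),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hpavv")),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  path <- file.path(out_dir, "manifest.yml")
  yaml::write_yaml(manifest, path)
  path
}

.resolve_cohort <- function(cfg) {
  if (!is.null(cfg$dataset)) {
    load_cohort(cfg$dataset, schema = cfg$schema)
  } else {
    synth_tsst_cohort(cfg$synth$n_subjects,
                      group_mix = cfg$synth$group_mix,
                      anomaly_fraction = cfg$synth$anomaly_fraction,
                      seed = cfg$seed)
  }
}

save_plot <- function(p, path, width = 6, height = 4) {
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
  path
}

#' Verify a model: simulate with fixed parameters and render each state
#'
#' Integrates the model once with its default (or supplied) parameters over
#' the configured span, writes the sampled solution table, and renders one
#' time-series figure per state variable from that same table.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the written file paths.
#' @export
cmd_verify <- function(cfg) {
  cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- get_model(cfg$model)
  span <- as.numeric(cfg$span)
  sol <- simulate_model(model, span = span,
                        rtol = cfg$cost$rtol, atol = cfg$cost$atol)
  grid <- seq(span[1], span[2], by = cfg$sample_step)
  tab <- tibble::as_tibble(cbind(time = grid, sample_solution(sol, grid)))
  tfile <- file.path(cfg$out_dir,
                     sprintf("verify_%s_solution.csv", model$name))
  readr::write_csv(tab, tfile)
  figs <- vapply(model$state_names, function(st) {
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$time,
                                           y = .data[[st]])) +
      ggplot2::geom_line() +
      ggplot2::labs(title = sprintf("%s: %s", model$name, st),
                    x = "time (min)", y = st)
    save_plot(p, file.path(cfg$out_dir,
                           sprintf("verify_%s_%s.png", model$name, st)))
  }, character(1))
  files <- c(tfile, figs)
  write_manifest(cfg, files, cfg$out_dir)
  invisible(files)
}

#' Validate a model against a cohort
#'
#' Runs the repeated-optimization protocol over the configured datasets,
#' saves every run and the sampled simulated curves, writes the per-dataset
#' report (the ranking rows), and renders per-hormone overlays of the
#' across-repeat mean simulated curve against the data.
#'
#' @param cfg A [run_config()].
#' @return The `validation_report`, invisibly; files land in `out_dir`.
#' @export
cmd_validate <- function(cfg) {
  cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- get_model(cfg$model)
  cohort <- .resolve_cohort(cfg)
  config <- cfg_cost(cfg)
  subjects <- intersect(as.character(cfg$subjects),
                        c(cohort_subjects(cohort), "mean"))
  report <- batch_over_subjects(model, cohort, subjects = subjects,
                                repeats = cfg$repeats,
                                popsize = cfg$popsize,
                                generations = cfg$generations,
                                base_seed = cfg$seed, config = config)

  # sampled simulated curve per run, on a fine grid over the data span
  grid <- seq(min(tsst_time_grid()), max(tsst_time_grid()), by = 2)
  solutions <- purrr::map_dfr(report$runs, function(vr) {
    purrr::map_dfr(vr$runs, function(r) {
      out <- tryCatch({
        sol <- simulate_model(model, r$best_params,
                              span = c(grid[1] - config$burn_in,
                                       grid[length(grid)]),
                              rtol = config$rtol, atol = config$atol)
        model_outputs(sol, times = grid)
      }, error = function(e) NULL)
      if (is.null(out)) return(NULL)
      dplyr::mutate(out, run_id = r$run_id, dataset = vr$dataset_id,
                    .before = 1)
    })
  })
  files <- save_results(report$runs, solutions, cfg$out_dir,
                        prefix = paste0("validate_", model$name))
  rfile <- file.path(cfg$out_dir,
                     sprintf("validate_%s_report.csv", model$name))
  readr::write_csv(
    dplyr::mutate(report$per_dataset, model = model$name,
                  overall_mean = report$overall$overall_mean), rfile)
  files <- c(files, report = rfile)

  # overlays from the saved solutions table: mean across repeats vs data
  figs <- character(0)
  for (id in subjects) {
    dat <- cohort_subject(cohort, id)
    sims <- dplyr::filter(solutions, .data$dataset == id)
    if (nrow(sims) == 0L) next
    for (h in c("acth", "cortisol")) {
      if (!all(is.finite(dat[[h]]))) next
      msim <- sims |>
        dplyr::group_by(.data$time) |>
        dplyr::summarise(value = mean(.data[[h]]), .groups = "drop")
      p <- ggplot2::ggplot() +
        ggplot2::geom_line(data = msim,
                           ggplot2::aes(x = .data$time, y = .data$value),
                           colour = "blue") +
        ggplot2::geom_point(data = dat,
                            ggplot2::aes(x = .data$time_min,
                                         y = .data[[h]])) +
        ggplot2::labs(title = sprintf("%s vs dataset %s (%s)",
                                      model$name, id, h),
                      x = "time (min)", y = h)
      figs <- c(figs, save_plot(
        p, file.path(cfg$out_dir,
                     sprintf("overlay_%s_%s_%s.png", model$name, id, h))))
    }
  }
  write_manifest(cfg, c(files, figs), cfg$out_dir)
  invisible(report)
}

#' Generalization test: saved parameter sets against every subject
#'
#' @param cfg A [run_config()] whose `results` names a directory written by
#'   [cmd_validate()] / [save_results()].
#' @return The `generalization_result`, invisibly.
#' @export
cmd_generalize <- function(cfg) {
  cfg <- run_config(cfg)
  if (is.null(cfg$results))
    stop("cmd_generalize needs a 'results' directory", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- get_model(cfg$model)
  saved <- load_results(cfg$results)
  cohort <- .resolve_cohort(cfg)
  gen <- generalization_matrix(model, saved$parameters, cohort,
                               config = cfg_cost(cfg))
  mfile <- file.path(cfg$out_dir,
                     sprintf("generalize_%s_matrix.csv", model$name))
  readr::write_csv(tidy.generalization_result(gen), mfile)
  gfile <- file.path(cfg$out_dir,
                     sprintf("generalize_%s_groups.csv", model$name))
  readr::write_csv(gen$by_group, gfile)
  write_manifest(cfg, c(mfile, gfile), cfg$out_dir)
  invisible(gen)
}

#' Generate and persist a synthetic TSST cohort
#'
#' Writes the cohort CSV plus a metadata file (seed and generator settings)
#' sufficient to regenerate the identical file.
#'
#' @param cfg A [run_config()] with a `synth` block.
#' @return Invisibly, the written file paths.
#' @export
cmd_synth <- function(cfg) {
  cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$synth$n_subjects) || cfg$synth$n_subjects < 1)
    stop("synth config needs n_subjects >= 1", call. = FALSE)
  cohort <- .resolve_cohort(cfg)
  cfile <- file.path(cfg$out_dir,
                     sprintf("synth_cohort_n%d_seed%d.csv",
                             as.integer(cfg$synth$n_subjects),
                             as.integer(cfg$seed)))
  write_cohort(cohort, cfile)
  meta <- file.path(cfg$out_dir, "synth_metadata.yml")
  yaml::write_yaml(list(seed = cfg$seed, synth = cfg$synth,
                        schema = attr(cohort, "schema"),
                        n_rows = nrow(cohort)), meta)
  write_manifest(cfg, c(cfile, meta), cfg$out_dir)
  invisible(c(cohort = cfile, metadata = meta))
}
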