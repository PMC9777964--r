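#' Save optimization results to a delimited result store
#'
#' Persists every optimizer repeat and the accompanying sampled solution
#' arrays as plain CSV tables inside a directory: `<prefix>_parameters.csv`
#' (one row per run: ids, seed, protocol, best cost, one column per
#' parameter) and `<prefix>_solutions.csv` (long table of sampled simulated
#' outputs per run). Plain delimited text opens directly in any spreadsheet
#' program and reloads losslessly via [load_results()].
#'
#' @param runs A `validation_runs` object or list of them.
#' @param solutions Optional tibble of sampled solutions with a `run_id`
#'   column (e.g. stacked [model_outputs()] results).
#' @param path Directory to write into (created if needed).
#' @param prefix File prefix; default derived from the dataset ids.
#' @return Named character vector of written file paths, invisibly.
#' @export
save_results <- function(runs, solutions = NULL, path, prefix = NULL) {
  if (inherits(runs, "validation_runs")) runs <- list(runs)
  if (length(runs) == 0L) stop("no runs to save", call. = FALSE)
  stopifnot(all(vapply(runs, inherits, logical(1), "validation_runs")))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (is.null(prefix))
    prefix <- paste(vapply(runs, function(v) v$dataset_id, character(1)),
                    collapse = "-")

  params_tb <- purrr::map_dfr(runs, function(vr) {
    purrr::map_dfr(vr$runs, function(r) {
      row <- tibble::tibble(run_id = r$run_id, dataset = vr$dataset_id,
                            model = vr$model_name, algorithm = r$algorithm,
                            seed = as.integer(r$seed), popsize = r$popsize,
                            generations = r$generations,
                            best_cost = r$best_cost)
      for (nm in names(r$best_params)) row[[nm]] <- unname(r$best_params[nm])
      row
    })
  })
  pfile <- file.path(path, paste0(prefix, "_parameters.csv"))
  readr::write_csv(params_tb, pfile)
  files <- c(parameters = pfile)

  if (!is.null(solutions)) {
    sfile <- file.path(path, paste0(prefix, "_solutions.csv"))
    readr::write_csv(tibble::as_tibble(solutions), sfile)
    files <- c(files, solutions = sfile)
  }
  invisible(files)
}

#' Reload a saved result store
#'
#' @param path Directory written by [save_results()].
#' @param prefix Optional prefix filter when several stores share the
#'   directory.
#' @return List with tibbles `parameters` and (if present) `solutions`.
#' @export
load_results <- function(path, prefix = NULL) {
  pat <- if (is.null(prefix)) "_parameters\\.csv$"
         else paste0("^", prefix, "_parameters\\.csv$")
  pfiles <- list.files(path, pattern = pat, full.names = TRUE)
  if (length(pfiles) == 0L)
    stop("no saved parameter table under ", path, call. = FALSE)
  # base-R parsing round-trips the written doubles exactly
  read_exact <- function(f) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    for (nm in intersect(c("run_id", "dataset", "model", "algorithm"),
                         names(df)))
      df[[nm]] <- as.character(df[[nm]])
    tibble::as_tibble(df)
  }
  parameters <- purrr::map_dfr(pfiles, read_exact)
  out <- list(parameters = parameters)
  sfiles <- sub("_parameters\\.csv$", "_solutions.csv", pfiles)
  sfiles <- sfiles[file.exists(sfiles)]
  if (length(sfiles))
    out$solutions <- purrr::map_dfr(sfiles, read_exact)
  out
}
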