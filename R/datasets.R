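#' The TSST sampling grid
#'
#' Blood-draw schedule around a 20-minute Trier Social Stress Test, in
#' minutes relative to the start of the test: 30 and 15 min before, at the
#' start, 10 and 20 min into the test, then every 15 min for the 90 min after
#' the test ends.
#'
#' @return Numeric vector of 11 times: -30, -15, 0, 10, 20, 35, ..., 110.
#' @export
tsst_time_grid <- function() {
  c(-30, -15, 0, 10, 20, 35, 50, 65, 80, 95, 110)
}

.cohort_groups <- c("control", "MDD-melancholic", "MDD-atypical",
                    "MDD-neither", "mean")

new_cohort <- function(data, schema = "tsst",
                       reference_event = c(start = 0, duration = 20),
                       excluded = character()) {
  data <- tibble::as_tibble(data)
  structure(data,
            class = c("hpa_cohort", class(data)),
            schema = schema, reference_event = reference_event,
            excluded = excluded)
}

#' Load a hormone cohort from a delimited text file
#'
#' Reads a CSV with columns `subject_id`, `group`, `time_min`, `acth`,
#' `cortisol` (the basal schema may omit `acth` or leave it empty). All
#' subjects must share one time grid; a subject missing any grid point is
#' excluded with a logged reason, mirroring the rule that subjects with any
#' missing data point are dropped. A non-numeric cell is a hard parse failure
#' reported with its row number.
#'
#' @param path CSV file path.
#' @param schema `"tsst"` (times relative to stressor start) or `"basal"`
#'   (clock minutes).
#' @return An `hpa_cohort` tibble; excluded subject ids are in
#'   `attr(, "excluded")`.
#' @export
load_cohort <- function(path, schema = c("tsst", "basal")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # read everything as text, then convert numerics with the base-R parser:
  # exact double round-trips plus parse failures reported by row
  raw <- tibble::as_tibble(
    utils::read.csv(path, colClasses = "character",
                    stringsAsFactors = FALSE, check.names = TRUE))
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  need <- c("subject_id", "group", "time_min", "cortisol")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!("acth" %in% names(raw))) raw$acth <- NA_character_
  for (nm in c("time_min", "acth", "cortisol")) {
    txt <- trimws(raw[[nm]])
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) & !(txt == "" | toupper(txt) == "NA"))
    if (length(bad))
      stop(sprintf("parse failure at row %d, column '%s': got '%s'",
                   bad[1], nm, txt[bad[1]]), call. = FALSE)
    raw[[nm]] <- num
  }

  # the reference grid is the union of observed times; subjects must cover it
  grid <- sort(unique(raw$time_min))
  ok <- raw |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      complete = length(.data$time_min) == length(grid) &&
        all(sort(.data$time_min) == grid) &&
        all(is.finite(.data$cortisol)) &&
        (all(is.finite(.data$acth)) || all(is.na(.data$acth))),
      .groups = "drop")
  excluded <- ok$subject_id[!ok$complete]
  if (length(excluded))
    rlang::inform(paste0("excluding subjects with missing data points: ",
                         paste(excluded, collapse = ", ")))
  kept <- raw |>
    dplyr::filter(!(.data$subject_id %in% excluded)) |>
    dplyr::arrange(.data$subject_id, .data$time_min)
  if (nrow(kept) == 0L)
    stop("no complete subjects in ", path, call. = FALSE)
  new_cohort(kept, schema = schema,
             reference_event = if (schema == "tsst")
               c(start = 0, duration = 20) else NULL,
             excluded = excluded)
}

#' Write a cohort to CSV
#'
#' Plain delimited mirror of the cohort table; [load_cohort()] round-trips it.
#'
#' @param cohort An `hpa_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' Subjects of a cohort
#'
#' @param cohort An `hpa_cohort`.
#' @return Character vector of subject ids.
#' @export
cohort_subjects <- function(cohort) {
  unique(cohort$subject_id)
}

#' Extract one subject's record
#'
#' @param cohort An `hpa_cohort`.
#' @param id A subject id, or `"mean"` for the cohort mean profile.
#' @return A tibble with columns `subject_id`, `group`, `time_min`, `acth`,
#'   `cortisol` (plus SD columns for the mean profile).
#' @export
cohort_subject <- function(cohort, id) {
  if (identical(id, "mean")) return(cohort_mean(cohort))
  rec <- dplyr::filter(tibble::as_tibble(cohort), .data$subject_id == id)
  if (nrow(rec) == 0L) stop("unknown subject id: ", id, call. = FALSE)
  dplyr::arrange(rec, .data$time_min)
}

#' Cohort mean profile with per-point standard deviations
#'
#' Pointwise arithmetic mean and sample standard deviation (denominator
#' n - 1; defined as 0 for a single subject) per hormone per time point.
#'
#' @param cohort An `hpa_cohort` with at least one subject.
#' @return A subject-shaped tibble (`subject_id = "mean"`) with columns
#'   `time_min`, `acth`, `cortisol`, `acth_sd`, `cortisol_sd`, `n_subjects`.
#' @export
cohort_mean <- function(cohort) {
  tb <- tibble::as_tibble(cohort)
  if (nrow(tb) == 0L) stop("empty cohort", call. = FALSE)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  tb |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      acth_sd = sd0(.data$acth),
      cortisol_sd = sd0(.data$cortisol),
      acth = mean(.data$acth),
      cortisol = mean(.data$cortisol),
      .groups = "drop") |>
    dplyr::mutate(subject_id = "mean", group = "mean") |>
    dplyr::select("subject_id", "group", "time_min", "acth", "cortisol",
                  "acth_sd", "cortisol_sd", "n_subjects") |>
    dplyr::arrange(.data$time_min)
}

#' @export
print.hpa_cohort <- function(x, ...) {
  cat(sprintf("<hpa_cohort> %d subjects, schema '%s'\n",
              length(cohort_subjects(x)), attr(x, "schema")))
  if (length(attr(x, "excluded")))
    cat("  excluded:", paste(attr(x, "excluded"), collapse = ", "), "\n")
  NextMethod()
}

#' @method autoplot hpa_cohort
#' @export
autoplot.hpa_cohort <- function(object, hormone = "cortisol", ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time_min,
                                   y = .data[[hormone]],
                                   group = .data$subject_id,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (min)", y = hormone)
}
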