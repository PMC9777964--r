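#' Parameter table for a model
#'
#' Every model carries a table of named parameters with default values and
#' finite optimization bounds, plus a flag marking which parameters the
#' calibration harness may vary. Bounds must bracket the default; parameters
#' flagged for optimization must have finite bounds.
#'
#' @param name Character vector of unique parameter names.
#' @param default Numeric defaults.
#' @param lower,upper Numeric bounds with `lower <= default <= upper`.
#' @param optimize Logical; whether the parameter is free during calibration.
#' @return A tibble of class `parameter_table`.
#' @export
parameter_table <- function(name, default, lower = -Inf, upper = Inf,
                            optimize = FALSE) {
  tb <- tibble::tibble(name = as.character(name),
                       default = as.numeric(default),
                       lower = as.numeric(lower),
                       upper = as.numeric(upper),
                       optimize = as.logical(optimize))
  if (anyDuplicated(tb$name))
    stop("parameter names must be unique", call. = FALSE)
  if (any(tb$lower > tb$default | tb$default > tb$upper))
    stop("bounds must satisfy lower <= default <= upper", call. = FALSE)
  bad <- tb$optimize & (!is.finite(tb$lower) | !is.finite(tb$upper))
  if (any(bad))
    stop("optimizable parameters need finite bounds: ",
         paste(tb$name[bad], collapse = ", "), call. = FALSE)
  class(tb) <- c("parameter_table", class(tb))
  tb
}

#' Model specification (plugin contract)
#'
#' A model is registered by declaring its states, parameter table, delays,
#' derivative function, drivers and an output map linking observable hormones
#' to state variables. The derivative function has signature
#' `rhs(t, y, params, lagged, drivers)` where `lagged(name)` returns the full
#' state vector lagged by the declared delay `name` (only declared delays may
#' be looked up; a zero lag returns the current state), and `drivers` is a
#' list of functions `circ(t)` and `stress(t)`.
#'
#' @param name Model name.
#' @param state_names Character vector of state variable names.
#' @param params A [parameter_table()].
#' @param rhs Derivative function, see Details.
#' @param output_map Named list mapping hormone labels (must include
#'   `"cortisol"`) to `list(state = <state name>, scale = <factor>)`.
#' @param delays Optional tibble with columns `name` and `lag` (minutes >= 0).
#' @param initial_state Optional numeric start state; if `NULL` the
#'   flat-driver steady state is used.
#' @param drivers List with elements `circadian` ([circadian_drive()]) and
#'   `stress` ([stress_protocol()]).
#' @param time_unit Declared time unit of the equations, `"min"` or `"hr"`.
#'   Models written in hours are integrated in minutes by scaling derivatives
#'   and lags at registration.
#' @param steady_guess Optional function `(params) -> state` giving a starting
#'   point for the steady-state solver.
#' @return An object of class `hpa_model`.
#' @export
model_spec <- function(name, state_names, params, rhs, output_map,
                       delays = NULL, initial_state = NULL,
                       drivers = list(circadian = circadian_drive(),
                                      stress = stress_protocol()),
                       time_unit = c("min", "hr"),
                       steady_guess = NULL) {
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(params, "parameter_table"), is.function(rhs))
  state_names <- as.character(state_names)
  if (anyDuplicated(state_names))
    stop("state names must be unique", call. = FALSE)
  if (is.null(delays)) {
    delays <- tibble::tibble(name = character(), lag = numeric())
  } else {
    delays <- tibble::as_tibble(delays)[, c("name", "lag")]
    if (any(delays$lag < 0)) stop("lags must be >= 0", call. = FALSE)
  }
  if (!("cortisol" %in% names(output_map)))
    stop("output_map must cover at least cortisol", call. = FALSE)
  for (om in output_map) {
    if (!(om$state %in% state_names))
      stop("output_map references unknown state: ", om$state, call. = FALSE)
  }
  if (!is.null(initial_state) &&
      length(initial_state) != length(state_names))
    stop("initial_state length must match state count", call. = FALSE)
  if (time_unit == "hr") {
    # internal clock is minutes: dy/dmin = dy/dhr / 60, lags in minutes
    rhs_hr <- rhs
    rhs <- function(t, y, params, lagged, drivers) {
      rhs_hr(t, y, params, lagged, drivers) / 60
    }
    delays$lag <- delays$lag * 60
  }
  structure(list(name = name, state_names = state_names, params = params,
                 rhs = rhs, output_map = output_map, delays = delays,
                 initial_state = initial_state, drivers = drivers,
                 time_unit = "min", steady_guess = steady_guess),
            class = "hpa_model")
}

#' @export
print.hpa_model <- function(x, ...) {
  cat("<hpa_model> ", x$name, "\n", sep = "")
  cat("  states: ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", nrow(x$params),
      " (", sum(x$params$optimize), " optimizable)\n", sep = "")
  if (nrow(x$delays) > 0L)
    cat("  delays: ", paste(sprintf("%s=%g min", x$delays$name, x$delays$lag),
                            collapse = ", "), "\n", sep = "")
  cat("  outputs: ", paste(names(x$output_map), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Default parameter vector of a model
#'
#' @param model An [model_spec()] object.
#' @return Named numeric vector of defaults.
#' @export
param_defaults <- function(model) {
  stats::setNames(model$params$default, model$params$name)
}

# Merge a (possibly partial, named) parameter vector over the defaults.
full_params <- function(model, params = NULL) {
  p <- param_defaults(model)
  if (!is.null(params)) {
    if (is.null(names(params)) && length(params) == length(p)) {
      p[] <- params
    } else {
      unknown <- setdiff(names(params), names(p))
      if (length(unknown))
        stop("unknown parameters: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      p[names(params)] <- params
    }
  }
  p
}

lag_of <- function(model, nm) {
  i <- match(nm, model$delays$name)
  if (is.na(i))
    stop("delayed lookup for undeclared delay '", nm, "'", call. = FALSE)
  model$delays$lag[i]
}

#' Write / read a model registration file
#'
#' Serializes the declarative part of a model (name, states, parameter table,
#' delays, initial state, output map, drivers, time unit) to YAML. The
#' derivative function itself is code and is re-attached on load by name from
#' the built-in model registry, so round-trips are lossless for registered
#' models.
#'
#' @param model An `hpa_model`.
#' @param path File path.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   returns the registration list, and `hpa_model_from_registration`
#'   rebuilds a full model for built-in derivative functions.
#' @export
write_model_spec <- function(model, path) {
  reg <- list(
    name = model$name,
    state_names = as.list(model$state_names),
    params = lapply(seq_len(nrow(model$params)), function(i)
      as.list(model$params[i, ])),
    delays = lapply(seq_len(nrow(model$delays)), function(i)
      as.list(model$delays[i, ])),
    initial_state = if (is.null(model$initial_state)) NULL
                    else as.list(model$initial_state),
    output_map = model$output_map,
    time_unit = model$time_unit,
    drivers = list(
      circadian = unclass(model$drivers$circadian),
      stress = list(baseline = model$drivers$stress$baseline,
                    episodes = lapply(
                      seq_len(nrow(model$drivers$stress$episodes)),
                      function(i) as.list(model$drivers$stress$episodes[i, ])))
    ))
  yaml::write_yaml(reg, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname write_model_spec
#' @export
hpa_model_from_registration <- function(reg) {
  ptab <- dplyr::bind_rows(lapply(reg$params, tibble::as_tibble))
  pt <- parameter_table(ptab$name, ptab$default, ptab$lower, ptab$upper,
                        ptab$optimize)
  delays <- if (length(reg$delays))
    dplyr::bind_rows(lapply(reg$delays, tibble::as_tibble)) else NULL
  drv <- list(
    circadian = do.call(circadian_drive, reg$drivers$circadian),
    stress = stress_protocol(
      if (length(reg$drivers$stress$episodes))
        dplyr::bind_rows(lapply(reg$drivers$stress$episodes,
                                tibble::as_tibble))
      else NULL,
      baseline = reg$drivers$stress$baseline))
  base <- get_model(reg$name)
  model_spec(reg$name, unlist(reg$state_names), pt, base$rhs, reg$output_map,
             delays = delays,
             initial_state = if (is.null(reg$initial_state)) NULL
                             else unlist(reg$initial_state),
             drivers = drv, time_unit = reg$time_unit,
             steady_guess = base$steady_guess)
}
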