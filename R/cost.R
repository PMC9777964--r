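#' Cubic interpolating spline
#'
#' Interpolates simulated output between solver mesh points so the simulation
#' can be read off at the exact data sampling times, whatever step sequence
#' the adaptive solver chose. Uses a cubic interpolating spline with
#' exact-cubic end conditions (Forsythe-Malcolm-Moler), which reproduces
#' affine and cubic polynomials exactly and is exact at every knot.
#'
#' @param times Strictly increasing knot times (>= 2).
#' @param values Knot values, same length.
#' @return An object of class `hpa_spline`; evaluate with [eval_spline()] or
#'   `predict()`.
#' @export
fit_spline <- function(times, values) {
  if (length(times) < 2L)
    stop("at least 2 knots are required", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("knot times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("knot values must be finite", call. = FALSE)
  f <- stats::splinefun(times, values, method = "fmm")
  structure(list(times = times, values = values, fun = f),
            class = "hpa_spline")
}

#' Evaluate a fitted spline
#'
#' @param spline An `hpa_spline`.
#' @param t Times within `[min(knots), max(knots)]`.
#' @return Numeric vector of interpolated values.
#' @export
eval_spline <- function(spline, t) {
  stopifnot(inherits(spline, "hpa_spline"))
  rng <- range(spline$times)
  if (any(t < rng[1] | t > rng[2]))
    stop("spline evaluated outside its knot span", call. = FALSE)
  spline$fun(t)
}

#' @export
predict.hpa_spline <- function(object, t, ...) eval_spline(object, t)

# Shared residual computation for all three costs. Returns one row per
# hormone/time with the normalized data and simulation values.
#   normalization "data":  both sides divided by the data mean (the literal
#                          convention; absolute scale is compared)
#   normalization "shape": each side divided by its own mean (scale-free
#                          shape comparison across models on different
#                          concentration scales)
normalized_residuals <- function(solution, model, subject,
                                 normalization = c("data", "shape")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(solution, "hpa_solution"),
            inherits(model, "hpa_model"))
  hormones <- intersect(names(model$output_map),
                        names(subject)[vapply(subject, is.numeric,
                                              logical(1))])
  hormones <- hormones[vapply(hormones, function(h)
    all(is.finite(subject[[h]])), logical(1))]
  if (length(hormones) == 0L)
    stop("no hormone shared between output_map and subject data",
         call. = FALSE)
  ti <- subject$time_min
  if (any(ti < solution$span[1] | ti > solution$span[2]))
    stop("subject grid outside the integrated span", call. = FALSE)
  mesh_out <- model_outputs(solution, model)
  purrr::map_dfr(hormones, function(h) {
    d <- subject[[h]]
    dbar <- mean(d)
    if (dbar <= 0)
      stop("data mean must be positive for normalization (", h, ")",
           call. = FALSE)
    sp <- fit_spline(mesh_out$time, mesh_out[[h]])
    s <- eval_spline(sp, ti)
    sref <- switch(normalization, data = dbar, shape = mean(s))
    if (normalization == "shape" && sref <= 0)
      stop("simulated mean must be positive under the shape convention (",
           h, ")", call. = FALSE)
    tibble::tibble(hormone = h, time = ti,
                   data = d, sim = s,
                   data_norm = d / dbar, sim_norm = s / sref,
                   resid = d / dbar - s / sref,
                   data_mean = dbar, sim_ref = sref)
  })
}

#' Spline-interpolated mean-normalized squared-error cost
#'
#' The validation cost: simulated ACTH and cortisol are splined over the
#' solver mesh, read off at the data times, both simulation and data are
#' normalized (by the data mean under the default convention), and squared
#' residuals are accumulated. Under `averaging = "mean"` (default) the sum of
#' squared normalized residuals is divided by both the number of time points
#' N and the number of hormones H, giving a dataset-size-free mean; under
#' `averaging = "printed"` the sum over points is divided by H only.
#'
#' @param solution An `hpa_solution` covering the subject's grid.
#' @param model The `hpa_model` whose output map links states to hormones.
#' @param subject A subject record tibble (`time_min` plus hormone columns).
#' @param normalization `"data"` (both sides over the data mean) or
#'   `"shape"` (each side over its own mean).
#' @param averaging `"mean"` (divide by N*H) or `"printed"` (divide by H).
#' @return A `cost_breakdown` object; the scalar cost is `$total`.
#' @export
sse_cost <- function(solution, model, subject,
                     normalization = c("data", "shape"),
                     averaging = c("mean", "printed")) {
  normalization <- match.arg(normalization)
  averaging <- match.arg(averaging)
  res <- normalized_residuals(solution, model, subject, normalization)
  n_points <- length(unique(res$time))
  n_h <- length(unique(res$hormone))
  ss <- sum(res$resid^2)
  total <- switch(averaging,
                  mean = ss / (n_points * n_h),
                  printed = ss / n_h)
  structure(list(
    residuals = res,
    per_hormone = res |>
      dplyr::group_by(.data$hormone) |>
      dplyr::summarise(norm_mean = .data$data_mean[1],
                       sim_ref = .data$sim_ref[1],
                       ss_resid = sum(.data$resid^2), .groups = "drop"),
    n_points = n_points, n_hormones = n_h, total = total,
    convention = list(normalization = normalization,
                      averaging = averaging)),
    class = "cost_breakdown")
}

#' Recompute the total of a cost breakdown from its stored residuals
#'
#' @param breakdown A `cost_breakdown`.
#' @return The total, recomputed under the stored convention.
#' @export
cost_total <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  ss <- sum(breakdown$residuals$resid^2)
  switch(breakdown$convention$averaging,
         mean = ss / (breakdown$n_points * breakdown$n_hormones),
         printed = ss / breakdown$n_hormones)
}

#' Maximum-of-maxima and mean-of-maxima alternative costs
#'
#' Per hormone, the maximum absolute normalized residual over the data
#' times; `max_max_cost` returns the worst hormone, `mean_max_cost` the mean
#' across hormones. These were the alternative distance measures considered
#' alongside the squared-error cost.
#'
#' @inheritParams sse_cost
#' @return A single nonnegative number.
#' @export
max_max_cost <- function(solution, model, subject,
                         normalization = c("data", "shape")) {
  res <- normalized_residuals(solution, model, subject,
                              match.arg(normalization))
  max(vapply(split(res$resid, res$hormone),
             function(r) max(abs(r)), numeric(1)))
}

#' @rdname max_max_cost
#' @export
mean_max_cost <- function(solution, model, subject,
                          normalization = c("data", "shape")) {
  res <- normalized_residuals(solution, model, subject,
                              match.arg(normalization))
  mean(vapply(split(res$resid, res$hormone),
              function(r) max(abs(r)), numeric(1)))
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> total = %.6g (%s normalization, %s averaging)\n",
              x$total, x$convention$normalization, x$convention$averaging))
  cat(sprintf("  %d time points x %d hormone(s)\n", x$n_points, x$n_hormones))
  print(x$per_hormone)
  invisible(x)
}

#' @method tidy cost_breakdown
#' @export
tidy.cost_breakdown <- function(x, ...) x$residuals

#' @method glance cost_breakdown
#' @export
glance.cost_breakdown <- function(x, ...) {
  tibble::tibble(total = x$total, n_points = x$n_points,
                 n_hormones = x$n_hormones,
                 normalization = x$convention$normalization,
                 averaging = x$convention$averaging)
}
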