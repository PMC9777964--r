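#' Stress protocol driver
#'
#' A step-function driver encoding one or more acute stress episodes, such as
#' the 20-minute Trier Social Stress Test (TSST). The driver evaluates to
#' `baseline` outside every episode and to `baseline + amplitude` inside the
#' half-open interval `[start, end)` of an episode. Half-open intervals make
#' the on/off switching deterministic at the boundaries.
#'
#' @param episodes A data frame (or tibble) with columns `start`, `end`
#'   (minutes) and `amplitude` (dimensionless, non-negative). May have zero
#'   rows for a stress-free driver.
#' @param baseline Dimensionless background drive, default 1.
#'
#' @return An object of class `stress_protocol`.
#' @examples
#' tsst <- stress_protocol(tibble::tibble(start = 0, end = 20, amplitude = 2))
#' eval_stress(tsst, 10)  # 3
#' eval_stress(tsst, 20)  # 1 (half-open)
#' @export
stress_protocol <- function(episodes = NULL, baseline = 1) {
  if (is.null(episodes) || nrow(as.data.frame(episodes)) == 0L) {
    episodes <- tibble::tibble(start = numeric(), end = numeric(),
                               amplitude = numeric())
  }
  episodes <- tibble::as_tibble(episodes)[, c("start", "end", "amplitude")]
  stopifnot(is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  if (nrow(episodes) > 0L) {
    if (any(!is.finite(episodes$start)) || any(!is.finite(episodes$end)))
      stop("episode boundaries must be finite", call. = FALSE)
    if (any(episodes$end <= episodes$start))
      stop("each episode must satisfy start < end", call. = FALSE)
    if (any(episodes$amplitude < 0))
      stop("episode amplitudes must be >= 0", call. = FALSE)
    episodes <- dplyr::arrange(episodes, .data$start)
    if (nrow(episodes) > 1L &&
        any(episodes$start[-1L] < episodes$end[-nrow(episodes)]))
      stop("stress episodes must not overlap", call. = FALSE)
  }
  structure(list(episodes = episodes, baseline = baseline),
            class = "stress_protocol")
}

#' Evaluate a stress protocol at given times
#'
#' @param protocol A [stress_protocol()].
#' @param t Numeric vector of times in minutes.
#' @return Numeric vector of drive values.
#' @export
eval_stress <- function(protocol, t) {
  stopifnot(inherits(protocol, "stress_protocol"))
  out <- rep(protocol$baseline, length(t))
  ep <- protocol$episodes
  if (nrow(ep) > 0L) {
    for (i in seq_len(nrow(ep))) {
      inside <- t >= ep$start[i] & t < ep$end[i]
      out[inside] <- out[inside] + ep$amplitude[i]
    }
  }
  out
}

#' @export
print.stress_protocol <- function(x, ...) {
  cat("<stress_protocol> baseline =", x$baseline, "\n")
  if (nrow(x$episodes) == 0L) cat("  (no episodes)\n") else print(x$episodes)
  invisible(x)
}

#' Circadian (SCN) drive
#'
#' Sinusoidal circadian forcing used as the suprachiasmatic-nucleus input to
#' the CRH equation: `drive(t) = mesor + amplitude * cos(2*pi*(t - peak_time) /
#' period)`. The drive attains its maximum at `peak_time` (modulo the period).
#' Requiring `mesor > amplitude >= 0` keeps the drive strictly positive, which
#' the HPA production terms need.
#'
#' @param mesor Midline level (dimensionless), must exceed `amplitude`.
#' @param amplitude Oscillation amplitude, non-negative.
#' @param peak_time Clock time of the maximum, in minutes (480 = 8 AM).
#' @param period Period in minutes, default 1440 (one day).
#' @return An object of class `circadian_drive`.
#' @examples
#' scn <- circadian_drive(mesor = 1, amplitude = 0.5, peak_time = 480)
#' eval_circadian(scn, 480)        # 1.5, the morning peak
#' eval_circadian(scn, 480 + 720)  # 0.5, the trough half a day later
#' @export
circadian_drive <- function(mesor = 1, amplitude = 0, peak_time = 480,
                            period = 1440) {
  stopifnot(is.numeric(mesor), is.numeric(amplitude), is.numeric(peak_time),
            is.numeric(period), period > 0, amplitude >= 0)
  if (mesor <= amplitude)
    stop("mesor must exceed amplitude so the drive stays positive",
         call. = FALSE)
  structure(list(mesor = mesor, amplitude = amplitude,
                 peak_time = peak_time, period = period),
            class = "circadian_drive")
}

#' Evaluate a circadian drive at given times
#'
#' @param drive A [circadian_drive()].
#' @param t Numeric vector of times in minutes.
#' @return Numeric vector of drive values.
#' @export
eval_circadian <- function(drive, t) {
  stopifnot(inherits(drive, "circadian_drive"))
  drive$mesor +
    drive$amplitude * cos(2 * pi * (t - drive$peak_time) / drive$period)
}

#' @export
print.circadian_drive <- function(x, ...) {
  cat("<circadian_drive> mesor =", x$mesor, "amplitude =", x$amplitude,
      "peak_time =", x$peak_time, "min, period =", x$period, "min\n")
  invisible(x)
}

# Flat counterparts used for steady-state initialization: the circadian drive
# frozen at its mesor and the stress protocol at its baseline.
flat_drivers <- function(drivers) {
  m <- drivers$circadian$mesor
  b <- drivers$stress$baseline
  list(circ = function(t) m, stress = function(t) b)
}

# Compiled scalar-time driver closures for the integration hot path; the
# vectorized eval_* functions remain the public interface.
driver_funs <- function(drivers) {
  cd <- drivers$circadian
  mes <- cd$mesor; amp <- cd$amplitude; pk <- cd$peak_time
  w <- 2 * pi / cd$period
  circ <- if (amp == 0) function(t) mes else
    function(t) mes + amp * cos(w * (t - pk))
  ep <- drivers$stress$episodes
  base <- drivers$stress$baseline
  s0 <- ep$start; s1 <- ep$end; sa <- ep$amplitude
  stress <- if (length(s0) == 0L) function(t) base else function(t) {
    out <- base
    for (j in seq_along(s0)) if (t >= s0[j] && t < s1[j]) out <- out + sa[j]
    out
  }
  list(circ = circ, stress = stress)
}
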