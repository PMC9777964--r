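# Synthetic endocrine cohorts. These generators stand in for clinical TSST
# and 24-h basal data: they emulate the sampling schedules, the
# baseline -> sharp rise -> return-to-baseline stress shape with
# inter-subject variability (including patient-1-style anomalous responders),
# and circadian/ultradian structure of basal series. Values are synthetic;
# units are metadata only (pg/mL for ACTH, ug/dL for cortisol) since the
# mean-normalized cost makes all downstream numbers unit-free.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default profile parameters for the synthetic TSST generator
#'
#' Baselines are log-normal across subjects; the stress response multiplies
#' the baseline by `1 + amplitude * g(t)` where `g` rises smoothly from the
#' start of the 20-min stressor to a subject-specific peak inside 10-35
#' min (the ACTH peak drawn first, the cortisol peak 5-10 min later) and
#' decays exponentially at a rate chosen so the 110-min sample lands within a
#' drawn fraction (3-12%) of baseline. Group effects encode blunted cortisol
#' responses in atypical depression and elevated baseline cortisol with
#' larger responses in melancholic depression. Measurement noise is
#' multiplicative log-normal with coefficient of variation `noise_cv`.
#'
#' @return A named list of generator settings.
#' @export
synth_profile_params <- function() {
  list(
    acth_baseline = 20,      # pg/mL, log-normal median across subjects
    cortisol_baseline = 8,   # ug/dL
    baseline_sdlog = 0.3,
    acth_amp_meanlog = log(2), acth_amp_sdlog = 0.35,
    cort_amp_meanlog = log(1.2), cort_amp_sdlog = 0.3,
    amp_min = 0.4,
    noise_cv = 0.12,
    resid_range = c(0.03, 0.12),  # fractional distance from baseline at 110
    group_effects = list(
      control = list(base_mult = 1, amp_mult = 1),
      `MDD-melancholic` = list(base_mult = 1.2, amp_mult = 1.25),
      `MDD-atypical` = list(base_mult = 0.95, amp_mult = 0.6),
      `MDD-neither` = list(base_mult = 1, amp_mult = 1)))
}

.default_group_mix <- c(control = 15, `MDD-melancholic` = 15,
                        `MDD-atypical` = 14, `MDD-neither` = 14)

.assign_groups <- function(n, group_mix) {
  if (is.null(group_mix)) group_mix <- .default_group_mix
  w <- group_mix / sum(group_mix)
  counts <- floor(w * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- w * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  rep(names(group_mix), times = counts)
}

#' Generate a synthetic TSST cohort
#'
#' Draws `n_subjects` subjects on the canonical 11-point TSST grid (see
#' [tsst_time_grid()]). Regular responders follow the expected shape: flat
#' baseline before the test, a sharp rise during the 20-min stressor with the
#' ACTH peak preceding the cortisol peak, and exponential return toward
#' baseline over the following 90 min. A fraction of subjects are anomalous
#' responders (patient-1 style): monotonically decreasing ACTH across the
#' whole grid with the cortisol peak 30 min after the end of the test
#' (grid point +50). Anomalous subjects are the first ids, so with the
#' default fraction subject "1" is the anomalous one in a 58-subject cohort.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param group_mix Named vector of group weights; default 15 control and
#'   43 MDD split across the three subtypes, the composition of the study
#'   design this schedule emulates.
#' @param profile_params Settings from [synth_profile_params()] (partial
#'   overrides allowed).
#' @param anomaly_fraction Fraction (between 0 and 1) of anomalous responders.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return An `hpa_cohort` tibble.
#' @export
synth_tsst_cohort <- function(n_subjects, group_mix = NULL,
                              profile_params = list(),
                              anomaly_fraction = 1 / 58, seed) {
  stopifnot(n_subjects >= 1)
  if (!is.numeric(anomaly_fraction) || anomaly_fraction < 0 ||
      anomaly_fraction > 1)
    stop("anomaly_fraction must lie in [0, 1]", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  pp <- utils::modifyList(synth_profile_params(), profile_params)
  grid <- tsst_time_grid()
  groups <- .assign_groups(n_subjects, group_mix)
  n_anom <- if (anomaly_fraction == 0) 0L else
    max(1L, floor(anomaly_fraction * n_subjects + 1e-9))
  n_anom <- min(n_anom, n_subjects)
  sdlog_noise <- sqrt(log(1 + pp$noise_cv^2))

  rise_decay <- function(t, tp, amp, resid) {
    r <- log(amp / resid) / (110 - tp)
    g <- numeric(length(t))
    up <- t > 0 & t <= tp
    g[up] <- 0.5 * (1 - cos(pi * t[up] / tp))
    post <- t > tp
    g[post] <- exp(-r * (t[post] - tp))
    g
  }
  noise <- function(k) exp(stats::rnorm(k, -sdlog_noise^2 / 2, sdlog_noise))

  with_seed(seed, {
    recs <- purrr::map(seq_len(n_subjects), function(i) {
      ge <- pp$group_effects[[groups[i]]]
      b_a <- stats::rlnorm(1, log(pp$acth_baseline), pp$baseline_sdlog)
      b_f <- stats::rlnorm(1, log(pp$cortisol_baseline), pp$baseline_sdlog) *
        ge$base_mult
      if (i <= n_anom) {
        k_dec <- stats::runif(1, 0.004, 0.009)
        acth <- sort(b_a * exp(-k_dec * (grid + 30)) * noise(length(grid)),
                     decreasing = TRUE)
        amp_f <- max(1, stats::rlnorm(1, log(1.3), 0.2))
        cort <- b_f * (1 + amp_f * exp(-((grid - 50) / 15)^2)) *
          noise(length(grid))
      } else {
        amp_a <- max(pp$amp_min,
                     stats::rlnorm(1, pp$acth_amp_meanlog, pp$acth_amp_sdlog))
        amp_f <- max(pp$amp_min,
                     stats::rlnorm(1, pp$cort_amp_meanlog,
                                   pp$cort_amp_sdlog) * ge$amp_mult)
        tp_a <- stats::runif(1, 10, 25)
        tp_f <- min(35, tp_a + stats::runif(1, 5, 10))
        resid <- stats::runif(2, pp$resid_range[1], pp$resid_range[2])
        acth <- b_a * (1 + amp_a * rise_decay(grid, tp_a, amp_a, resid[1])) *
          noise(length(grid))
        cort <- b_f * (1 + amp_f * rise_decay(grid, tp_f, amp_f, resid[2])) *
          noise(length(grid))
      }
      tibble::tibble(subject_id = as.character(i), group = groups[i],
                     time_min = grid, acth = acth, cortisol = cort)
    })
    new_cohort(dplyr::bind_rows(recs), schema = "tsst")
  })
}

#' Generate a synthetic 24-hour basal hormone series
#'
#' A circadian envelope peaking near 8 AM (clock minute 480) modulates
#' discrete ultradian secretory pulses: 12-18 episodes per day with
#' inter-pulse spacing proportional to draws from the 60-90 min period
#' range, Gaussian pulse shapes, and little secretion between pulses.
#' ACTH pulses lead the cortisol pulses by about 10 min. Sampled at 10-min
#' intervals, matching the basal blood-draw schedule.
#'
#' @param duration Length of the series in minutes (default one day).
#' @param circadian_params A [circadian_drive()] for the envelope; default
#'   mesor 1, amplitude 0.7, peak at clock 480.
#' @param n_pulses Number of secretory episodes; default drawn uniformly
#'   from 12:18.
#' @param pulse_period_range Ultradian period range in minutes.
#' @param pulse_width SD of the Gaussian pulse shape (minutes).
#' @param basal_fraction Inter-pulse secretion relative to pulse height.
#' @param seed Integer seed.
#' @return A tibble with columns `time_min`, `acth`, `cortisol` and unit
#'   metadata in attributes `units`.
#' @export
synth_basal_series <- function(duration = 1440,
                               circadian_params = circadian_drive(
                                 mesor = 1, amplitude = 0.7,
                                 peak_time = 480),
                               n_pulses = NULL,
                               pulse_period_range = c(60, 90),
                               pulse_width = 8,
                               basal_fraction = 0.15,
                               seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(duration > 0, pulse_period_range[1] > 0,
            pulse_period_range[2] >= pulse_period_range[1])
  with_seed(seed, {
    if (is.null(n_pulses)) n_pulses <- sample(12:18, 1)
    if (n_pulses < 0) stop("n_pulses must be >= 0", call. = FALSE)
    tgrid <- seq(0, duration, by = 10)
    env <- eval_circadian(circadian_params, tgrid)
    series <- function(centers, heights) {
      v <- rep(basal_fraction, length(tgrid))
      for (j in seq_along(centers))
        v <- v + heights[j] * exp(-((tgrid - centers[j]) / pulse_width)^2)
      v * env
    }
    if (n_pulses == 0) {
      cort <- series(numeric(0), numeric(0))
      acth <- series(numeric(0), numeric(0))
    } else {
      gaps <- stats::runif(n_pulses, pulse_period_range[1],
                           pulse_period_range[2])
      centers <- (cumsum(gaps) - gaps / 2) / sum(gaps) * duration
      heights <- stats::rlnorm(n_pulses, 0, 0.25)
      cort <- series(centers, heights)
      acth <- series(pmax(centers - 10, 0), heights)
    }
    out <- tibble::tibble(time_min = tgrid,
                          acth = 25 * acth, cortisol = 6 * cort)
    attr(out, "units") <- c(acth = "pg/mL", cortisol = "ug/dL")
    attr(out, "n_pulses") <- n_pulses
    out
  })
}

#' Count local maxima of a sampled series
#'
#' Interior points strictly greater than the previous sample and at least as
#' large as the next; used to count ultradian secretory episodes.
#'
#' @param x Numeric vector.
#' @return Integer count.
#' @export
count_local_maxima <- function(x) {
  if (length(x) < 3L) return(0L)
  i <- 2:(length(x) - 1L)
  sum(x[i] > x[i - 1L] & x[i] >= x[i + 1L])
}
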