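# Demonstration HPA-axis models. All three share the canonical cascade
# CRH (C) -> ACTH (A) -> cortisol (F) with negative glucocorticoid feedback;
# they differ in how feedback is sensed (free cortisol vs bound receptor
# complex) and whether signalling delays are present. Default parameter
# values are implementation constants documented here: they are chosen so
# that the flat-driver steady state is strictly positive and the canonical
# 20-min stress episode produces a peak-and-return cortisol response;
# none of them is a literature estimate.

#' Right-hand side of the minimal HPA model
#'
#' Three states (CRH `C`, ACTH `A`, cortisol `F`) with Hill-type repression
#' of CRH and ACTH synthesis by cortisol:
#' \deqn{dC/dt = k_c \, circ(t) \, stress(t) / (1 + (F/K_i)^n) - w_c C}
#' \deqn{dA/dt = k_a C / (1 + (F/K_{i2})^m) - w_a A}
#' \deqn{dF/dt = k_f A - w_f F}
#' At the origin all derivatives reduce to the positive production terms, so
#' the nonnegative orthant is forward-invariant.
#'
#' @param t Time (minutes).
#' @param y State vector `c(C, A, F)`.
#' @param params Named parameter vector.
#' @param lagged Delay lookup (unused here).
#' @param drivers List of driver functions `circ(t)`, `stress(t)`.
#' @return Derivative vector.
#' @export
minimal_hpa_rhs <- function(t, y, params, lagged, drivers) {
  p <- params
  if (p[["K_i"]] <= 0 || p[["K_i2"]] <= 0)
    stop("feedback constants K_i, K_i2 must be positive", call. = FALSE)
  C <- y[1]; A <- y[2]; F <- y[3]
  c(p[["k_c"]] * drivers$circ(t) * drivers$stress(t) /
      (1 + (F / p[["K_i"]])^p[["n"]]) - p[["w_c"]] * C,
    p[["k_a"]] * C / (1 + (F / p[["K_i2"]])^p[["m"]]) - p[["w_a"]] * A,
    p[["k_f"]] * A - p[["w_f"]] * F)
}

#' Right-hand side of the receptor-feedback HPA model
#'
#' Four states: the cascade of [minimal_hpa_rhs()] plus a glucocorticoid
#' receptor pool `R`. Negative feedback is sensed through the bound-complex
#' proxy `F * R` rather than free cortisol, and receptor production carries a
#' positive feedback loop saturating in `(F R)^2`:
#' \deqn{dR/dt = k_r (FR)^2 / (K + (FR)^2) + k_b - w_r R}
#' With `F = 0` the receptor equation is linear and relaxes to `k_b / w_r`.
#'
#' @inheritParams minimal_hpa_rhs
#' @export
receptor_hpa_rhs <- function(t, y, params, lagged, drivers) {
  p <- params
  if (p[["K_i"]] <= 0) stop("K_i must be positive", call. = FALSE)
  C <- y[1]; A <- y[2]; F <- y[3]; R <- y[4]
  FR <- F * R
  fb <- 1 + FR / p[["K_i"]]
  c(p[["k_c"]] * drivers$circ(t) * drivers$stress(t) / fb - p[["w_c"]] * C,
    p[["k_a"]] * C / fb - p[["w_a"]] * A,
    p[["k_f"]] * A - p[["w_f"]] * F,
    p[["k_r"]] * FR^2 / (p[["K"]] + FR^2) + p[["k_b"]] - p[["w_r"]] * R)
}

#' Right-hand side of the delayed HPA model
#'
#' The minimal cascade with signalling delays: CRH acts on ACTH synthesis
#' after `tau_c`, ACTH on cortisol production after `tau_a`, and the cortisol
#' feedback signal is lagged by `tau_f`. With all lags zero this reduces
#' exactly to [minimal_hpa_rhs()], and any steady state of the non-delayed
#' system is a steady state here.
#'
#' @inheritParams minimal_hpa_rhs
#' @param lagged Function `lagged(name)` returning the state vector lagged by
#'   the declared delay `name` (`"tau_c"`, `"tau_a"`, `"tau_f"`).
#' @export
delayed_hpa_rhs <- function(t, y, params, lagged, drivers) {
  p <- params
  if (p[["K_i"]] <= 0 || p[["K_i2"]] <= 0)
    stop("feedback constants K_i, K_i2 must be positive", call. = FALSE)
  C <- y[1]; A <- y[2]; F <- y[3]
  C_lag <- lagged("tau_c")[1]
  A_lag <- lagged("tau_a")[2]
  F_lag <- lagged("tau_f")[3]
  c(p[["k_c"]] * drivers$circ(t) * drivers$stress(t) /
      (1 + (F_lag / p[["K_i"]])^p[["n"]]) - p[["w_c"]] * C,
    p[["k_a"]] * C_lag / (1 + (F_lag / p[["K_i2"]])^p[["m"]]) - p[["w_a"]] * A,
    p[["k_f"]] * A_lag - p[["w_f"]] * F)
}

# Canonical drivers for TSST simulations: time 0 is the start of the 20-min
# stressor at 17:00 clock time, so the 8 AM circadian peak sits at -540 min.
tsst_drivers <- function(stress_amplitude = 10, circ_amplitude = 0.1) {
  list(
    circadian = circadian_drive(mesor = 1, amplitude = circ_amplitude,
                                peak_time = -540, period = 1440),
    stress = stress_protocol(
      tibble::tibble(start = 0, end = 20, amplitude = stress_amplitude),
      baseline = 1))
}

# Defaults place the resting state below the knee of the CRH feedback
# (F*/K_i ~ 0.55) while the canonical stressor drives cortisol past it
# (peak F/K_i ~ 1.4), and keep the ACTH-equation feedback weak (F*/K_i2 ~
# 0.5). In that regime baseline levels pin k_c, the peak saturation pins
# K_i and the post-test decay pins w_f, so the three free parameters are
# practically identifiable from a single TSST record. The Hill coefficient
# 6 reflects the high feedback cooperativity used in minimal HPA models.
.minimal_param_table <- function() {
  parameter_table(
    name    = c("k_c", "w_c", "K_i", "n", "k_a", "w_a", "K_i2", "m",
                "k_f", "w_f"),
    default = c(0.3,   0.1,   5,     6,   0.1,   0.05,  6,      2,
                0.02,  0.03),
    lower   = c(0.03,  0.01,  0.5,   1,   0.01,  0.005, 0.5,    1,
                0.002, 0.003),
    upper   = c(3,     1,     20,    8,   1,     0.5,   20,     4,
                0.2,   0.3),
    optimize = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, TRUE))
}

#' Demonstration HPA models
#'
#' Three fully specified models exercising the plugin contract: a minimal
#' three-state cascade, a four-state receptor-feedback variant, and a delayed
#' variant of the minimal cascade. Each ships with a positive flat-driver
#' steady state and responds to the canonical 20-min stress episode with a
#' cortisol peak followed by return toward baseline. `ACTH` maps to state `A`
#' and `cortisol` to state `F`, both with unit scale.
#'
#' @param stress_amplitude Amplitude of the canonical stress episode.
#' @param circ_amplitude Amplitude of the circadian (SCN) drive.
#' @return An [model_spec()] object.
#' @export
hpa_model_minimal <- function(stress_amplitude = 10, circ_amplitude = 0.1) {
  model_spec(
    name = "minimal",
    state_names = c("C", "A", "F"),
    params = .minimal_param_table(),
    rhs = minimal_hpa_rhs,
    output_map = list(acth = list(state = "A", scale = 1),
                      cortisol = list(state = "F", scale = 1)),
    drivers = tsst_drivers(stress_amplitude, circ_amplitude),
    steady_guess = function(p) c(1, 1, 1))
}

#' @rdname hpa_model_minimal
#' @export
hpa_model_receptor <- function(stress_amplitude = 10, circ_amplitude = 0.1) {
  params <- parameter_table(
    name    = c("k_c", "w_c", "K_i", "k_a", "w_a", "k_f", "w_f",
                "k_r", "K", "k_b", "w_r"),
    default = c(0.3,   0.1,   1,     0.1,   0.05,  0.05,  0.03,
                0.05,  1,     0.01,  0.02),
    lower   = c(0.03,  0.01,  0.1,   0.01,  0.005, 0.005, 0.003,
                0.005, 0.1,   0.001, 0.002),
    upper   = c(3,     1,     10,    1,     0.5,   0.5,   0.3,
                0.5,   10,    0.1,   0.2),
    optimize = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                 FALSE, FALSE, FALSE, FALSE))
  model_spec(
    name = "receptor",
    state_names = c("C", "A", "F", "R"),
    params = params,
    rhs = receptor_hpa_rhs,
    output_map = list(acth = list(state = "A", scale = 1),
                      cortisol = list(state = "F", scale = 1)),
    drivers = tsst_drivers(stress_amplitude, circ_amplitude),
    steady_guess = function(p) c(1, 1, 1, p[["k_b"]] / p[["w_r"]] + 0.5))
}

#' @rdname hpa_model_minimal
#' @param tau_c,tau_a,tau_f Signalling delays in minutes (>= 0).
#' @export
hpa_model_delayed <- function(tau_c = 5, tau_a = 5, tau_f = 10,
                              stress_amplitude = 10, circ_amplitude = 0.1) {
  model_spec(
    name = "delayed",
    state_names = c("C", "A", "F"),
    params = .minimal_param_table(),
    rhs = delayed_hpa_rhs,
    output_map = list(acth = list(state = "A", scale = 1),
                      cortisol = list(state = "F", scale = 1)),
    delays = tibble::tibble(name = c("tau_c", "tau_a", "tau_f"),
                            lag = c(tau_c, tau_a, tau_f)),
    drivers = tsst_drivers(stress_amplitude, circ_amplitude),
    steady_guess = function(p) c(1, 1, 1))
}

#' Look up a built-in model by name
#'
#' @param name One of `"minimal"`, `"receptor"`, `"delayed"`.
#' @return An [model_spec()] object.
#' @export
get_model <- function(name) {
  switch(name,
         minimal = hpa_model_minimal(),
         receptor = hpa_model_receptor(),
         delayed = hpa_model_delayed(),
         stop("unknown model: ", name, call. = FALSE))
}

#' Flat-driver steady state of a model
#'
#' Solves the algebraic system `rhs = 0` with the circadian drive frozen at
#' its mesor and the stress drive at its baseline, giving the pre-stress
#' resting state used to initialize simulations. A damped Newton iteration
#' with numerical Jacobian is polished until the residual norm drops below
#' `tol`; delayed lookups see the current (equilibrium) state. Falls back to
#' a long relaxation integration if Newton stalls.
#'
#' @param model An `hpa_model`.
#' @param params Optional named parameter overrides.
#' @param tol Residual tolerance (max absolute derivative component).
#' @return Nonnegative steady-state vector (named by state).
#' @export
steady_state <- function(model, params = NULL, tol = 1e-10) {
  p <- full_params(model, params)
  drv <- flat_drivers(model$drivers)
  g <- function(y) {
    lagged <- function(nm) { lag_of(model, nm); y }
    as.numeric(model$rhs(0, y, p, lagged, drv))
  }
  guess <- if (!is.null(model$steady_guess)) model$steady_guess(p) else
    rep(1, length(model$state_names))

  newton <- function(y) {
    for (it in 1:100) {
      r <- g(y)
      if (max(abs(r)) < tol) return(y)
      J <- pracma::jacobian(g, y)
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        ynew <- y - lambda * step
        rnew <- tryCatch(g(ynew), error = function(e) rep(Inf, length(y)))
        if (all(is.finite(rnew)) && max(abs(rnew)) < max(abs(r))) break
        lambda <- lambda / 2
        if (lambda < 1e-8) return(NULL)
      }
      y <- ynew
    }
    NULL
  }

  y <- newton(guess)
  if (is.null(y) || any(y < -1e-12)) {
    # relax toward the attractor, then polish
    relax <- tryCatch({
      sol <- solve_ode(
        function(t, yy, lag) {
          lagged <- function(nm) { lag_of(model, nm); yy }
          model$rhs(t, yy, p, lagged, drv)
        },
        pmax(guess, 1e-6), c(0, 5000), rtol = 1e-8, atol = 1e-10)
      sol$states[nrow(sol$states), ]
    }, error = function(e) NULL)
    if (!is.null(relax)) y <- newton(relax)
  }
  if (is.null(y))
    stop("steady-state solver failed to converge for model '",
         model$name, "'", call. = FALSE)
  if (any(y < -1e-12))
    stop("no nonnegative steady state found for model '", model$name, "'",
         call. = FALSE)
  y <- pmax(y, 0)
  if (max(abs(g(y))) >= tol)
    stop("steady-state residual above tolerance", call. = FALSE)
  stats::setNames(y, model$state_names)
}

#' Simulate a model over a time span
#'
#' Integrates a model with its declared drivers. Stress episode boundaries
#' inside the span are forced mesh points so the driver discontinuities fall
#' on step boundaries. If no initial state is given, the flat-driver steady
#' state is used.
#'
#' @param model An `hpa_model`.
#' @param params Optional named parameter overrides.
#' @param span Length-2 time span in minutes (TSST-relative for the
#'   demonstration models; default covers the TSST window).
#' @param initial Optional initial state; default [steady_state()].
#' @param rtol,atol Integration tolerances.
#' @return An `hpa_solution` with state names attached and the model stored
#'   in attribute `"model"`.
#' @export
simulate_model <- function(model, params = NULL, span = c(-30, 110),
                           initial = NULL, rtol = 1e-6, atol = 1e-9) {
  p <- full_params(model, params)
  drv <- driver_funs(model$drivers)
  if (is.null(initial)) {
    initial <- if (!is.null(model$initial_state)) model$initial_state
               else steady_state(model, p)
  }
  ep <- model$drivers$stress$episodes
  forced <- if (nrow(ep) > 0L) c(ep$start, ep$end) else numeric(0)
  lags <- model$delays$lag
  rhs_fn <- model$rhs
  lag_names <- model$delays$name
  lag_vals <- model$delays$lag
  wrapped <- function(t, y, lagfun) {
    lagged <- function(nm) {
      i <- match(nm, lag_names)
      if (is.na(i))
        stop("delayed lookup for undeclared delay '", nm, "'", call. = FALSE)
      lg <- lag_vals[i]
      if (lg <= 0) y else lagfun(t - lg)
    }
    rhs_fn(t, y, p, lagged, drv)
  }
  sol <- solve_ode(wrapped, initial, span, lags = lags,
                   rtol = rtol, atol = atol, forced_points = forced,
                   state_names = model$state_names)
  attr(sol, "model") <- model
  sol
}

#' Observable hormone outputs of a simulation
#'
#' Applies the model's output map (state index and scale per hormone) to a
#' solution, sampling the dense output on the requested grid.
#'
#' @param solution An `hpa_solution` from [simulate_model()].
#' @param model The model (defaults to the one stored on the solution).
#' @param times Sampling times; default the solution mesh.
#' @return A tibble with column `time` and one column per mapped hormone.
#' @export
model_outputs <- function(solution, model = attr(solution, "model"),
                          times = solution$mesh_times) {
  stopifnot(inherits(model, "hpa_model"))
  st <- sample_solution(solution, times)
  out <- tibble::tibble(time = times)
  for (h in names(model$output_map)) {
    om <- model$output_map[[h]]
    out[[h]] <- st[, match(om$state, model$state_names)] * om$scale
  }
  out
}
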