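# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: steady states come from scalar reductions of
# the equilibrium algebra solved with uniroot, not from the package's
# multivariate Newton solver.

# Minimal cascade equilibrium: eliminate C and A, leaving one equation in F.
oracle_steady_minimal <- function(p, u = 1) {
  gain <- p[["k_f"]] * p[["k_a"]] * p[["k_c"]] * u /
    (p[["w_f"]] * p[["w_a"]] * p[["w_c"]])
  g <- function(F) {
    F * (1 + (F / p[["K_i"]])^p[["n"]]) *
      (1 + (F / p[["K_i2"]])^p[["m"]]) - gain
  }
  F <- stats::uniroot(g, c(0, gain + 1), tol = 1e-14)$root
  C <- p[["k_c"]] * u / (p[["w_c"]] * (1 + (F / p[["K_i"]])^p[["n"]]))
  A <- p[["k_a"]] * C / (p[["w_a"]] * (1 + (F / p[["K_i2"]])^p[["m"]]))
  c(C = C, A = A, F = F)
}

# Receptor model equilibrium: scalar root in the bound-complex product P = F*R.
oracle_steady_receptor <- function(p, u = 1) {
  gain <- p[["k_f"]] * p[["k_a"]] * p[["k_c"]] * u /
    (p[["w_f"]] * p[["w_a"]] * p[["w_c"]])
  Ffun <- function(P) gain / (1 + P / p[["K_i"]])^2
  Rfun <- function(P) (p[["k_r"]] * P^2 / (p[["K"]] + P^2) + p[["k_b"]]) /
    p[["w_r"]]
  h <- function(P) Ffun(P) * Rfun(P) - P
  Pmax <- gain * (p[["k_r"]] + p[["k_b"]]) / p[["w_r"]] + 1
  P <- stats::uniroot(h, c(0, Pmax), tol = 1e-14)$root
  F <- Ffun(P); R <- Rfun(P)
  C <- p[["k_c"]] * u / (p[["w_c"]] * (1 + P / p[["K_i"]]))
  A <- p[["k_a"]] * C / (p[["w_a"]] * (1 + P / p[["K_i"]]))
  c(C = C, A = A, F = F, R = R)
}

# Subject record built from a model's own simulated outputs on the TSST grid
# (optionally with multiplicative log-normal noise), the substrate of the
# self-consistency and recovery tests.
model_subject <- function(model, params = NULL, burn_in = 240,
                          noise_cv = 0, seed = NULL) {
  sol <- simulate_model(model, params,
                        span = c(-30 - burn_in, 110))
  out <- model_outputs(sol, times = tsst_time_grid())
  acth <- out$acth; cort <- out$cortisol
  if (noise_cv > 0) {
    stopifnot(!is.null(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    set.seed(seed)
    acth <- acth * exp(stats::rnorm(length(acth), -sdlog^2 / 2, sdlog))
    cort <- cort * exp(stats::rnorm(length(cort), -sdlog^2 / 2, sdlog))
  }
  tibble::tibble(subject_id = "sim", group = "control",
                 time_min = out$time, acth = acth, cortisol = cort)
}

# A constant-output "model" whose every hormone equals a fixed level; used
# for the hand-computed cost identities.
constant_model <- function(level) {
  model_spec(
    name = "constant",
    state_names = "y",
    params = parameter_table("dummy", 1, 0, 2),
    rhs = function(t, y, params, lagged, drivers) 0,
    output_map = list(acth = list(state = "y", scale = 1),
                      cortisol = list(state = "y", scale = 1)),
    initial_state = level,
    steady_guess = function(p) level)
}

recovery_truth <- c(k_c = 0.4, K_i = 5.75, w_f = 0.04)
recovery_config <- function() cost_config(burn_in = 240)

# compiled scalar drivers, as the integrator sees them
driver_funs_for_test <- function(model) hpavv:::driver_funs(model$drivers)
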