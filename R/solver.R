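# Dormand-Prince 5(4) embedded pair with a quartic continuous extension.
# The dense-output coefficient matrix P gives, per accepted step,
#   y(t0 + theta*h) = y0 + h * K %*% P %*% c(theta, theta^2, theta^3, theta^4)
# with K the (n x 7) stage-derivative matrix; the interpolant is 4th-order
# accurate and exact at both step endpoints.

.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)

.dp_a <- list(
  NULL,
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
)

# b5 - b4: weights of the embedded error estimate
.dp_e <- c(71/57600, 0, -71/16695, 71/1920, -17253/339200, 22/525, -1/40)

.dp_P <- matrix(c(
  1, -8048581381/2820520608, 8663915743/2820520608, -12715105075/11282082432,
  0, 0, 0, 0,
  0, 131558114200/32700410799, -68118460800/10900136933, 87487479700/32700410799,
  0, -1754552775/470086768, 14199869525/1410260304, -10690763975/1880347072,
  0, 127303824393/49829197408, -318862633887/49829197408, 701980252875/199316789632,
  0, -282668133/205662961, 2019193451/616988883, -1453857185/822651844,
  0, 40617522/29380423, -110615467/29380423, 69997945/29380423),
  nrow = 7, byrow = TRUE)

#' Integrate an ODE or DDE system
#'
#' Adaptive explicit Runge-Kutta integration (Dormand-Prince 5(4)) with
#' error-per-step control against the mixed tolerance `atol + rtol * |y|`,
#' continuous 4th-order dense output, and delay support by the method of
#' steps: delayed states are read from the supplied history for query times
#' at or before `span[1]` and from the continuously extended dense output
#' afterwards. When positive lags are declared the step size is capped at the
#' smallest positive lag so delayed lookups always land in already-accepted
#' history. Every forced point (for example stress on/off switching times)
#' becomes a mesh point, so step control never integrates across a driver
#' discontinuity.
#'
#' @param rhs Derivative function `rhs(t, y, lagged)`; `lagged(tq)` returns
#'   the full state vector at time `tq` (only meaningful when `lags` are
#'   declared; plain ODE right-hand sides may ignore the third argument).
#' @param y0 Numeric initial state.
#' @param span Length-2 numeric `c(t0, t1)` with `t1 > t0` (minutes).
#' @param lags Numeric vector of declared delays (minutes, >= 0).
#' @param history Function `t -> state` defined for `t <= t0`; must agree
#'   with `y0` at `t0`. Default: constant equal to `y0`.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param forced_points Times that must appear exactly in the mesh.
#' @param h_max Optional cap on the step size.
#' @param max_steps Step budget before giving up.
#' @param state_names Optional state names attached to the solution.
#' @return An object of class `hpa_solution`: the accepted mesh, the state
#'   matrix on the mesh, the per-step dense-output coefficients, and solver
#'   diagnostics (accepted steps, rejected steps, derivative evaluations).
#' @examples
#' sol <- solve_ode(function(t, y, lag) -y, y0 = 1, span = c(0, 5))
#' dense_eval(sol, 5) - exp(-5)
#' @export
solve_ode <- function(rhs, y0, span, lags = numeric(0), history = NULL,
                      rtol = 1e-6, atol = 1e-9, forced_points = numeric(0),
                      h_max = Inf, max_steps = 500000L, state_names = NULL) {
  t0 <- span[1]; t1 <- span[2]
  if (!(t1 > t0)) stop("span must satisfy t1 > t0", call. = FALSE)
  y0 <- as.numeric(y0)
  n <- length(y0)
  if (is.null(history)) {
    history <- local({y <- y0; function(t) y})
  } else {
    h0v <- as.numeric(history(t0))
    if (length(h0v) != n ||
        max(abs(h0v - y0)) > 1e-8 * max(1, max(abs(y0))))
      stop("history(t0) must equal the initial state", call. = FALSE)
  }
  min_lag <- if (any(lags > 0)) min(lags[lags > 0]) else Inf
  forced <- as.numeric(forced_points)
  if (is.finite(min_lag)) {
    # propagated derivative discontinuities: t0 + k1*tau1 + k2*tau2 + ...
    # up to total order 4, after which the jump is smoother than the method
    disc <- 0
    for (k in 1:4) {
      disc <- unique(as.numeric(outer(disc, lags[lags > 0], `+`)))
      disc <- disc[disc <= (t1 - t0)]
      forced <- c(forced, t0 + disc)
      if (!length(disc)) break
    }
  }
  forced <- sort(unique(forced))
  forced <- forced[forced > t0 & forced < t1]
  bounds <- c(forced, t1)

  nrhs <- 0L; naccept <- 0L; nreject <- 0L

  # growable storage of accepted steps
  cap <- 256L
  ts <- numeric(cap + 1L); ts[1L] <- t0
  ys <- matrix(0, cap + 1L, n); ys[1L, ] <- y0
  hs <- numeric(cap)
  Qs <- vector("list", cap)
  nacc <- 0L  # number of accepted steps stored

  lookup <- function(tq) {
    if (tq <= t0) return(as.numeric(history(tq)))
    tend <- ts[nacc + 1L]
    if (tq > tend) {
      if (tq - tend < 1e-9 * max(1, abs(tend))) {
        tq <- tend
      } else {
        stop(sprintf("delayed lookup at t = %g beyond available history (%g)",
                     tq, tend), call. = FALSE)
      }
    }
    i <- findInterval(tq, ts[seq_len(nacc + 1L)], rightmost.closed = TRUE)
    i <- min(max(i, 1L), nacc)
    theta <- (tq - ts[i]) / hs[i]
    p <- c(theta, theta^2, theta^3, theta^4)
    as.numeric(ys[i, ] + hs[i] * (Qs[[i]] %*% p))
  }

  f <- function(t, y) {
    nrhs <<- nrhs + 1L
    d <- as.numeric(rhs(t, y, lookup))
    if (length(d) != n)
      stop("rhs returned a derivative of wrong length", call. = FALSE)
    d
  }

  # initial step size (Hairer-style heuristic), capped by constraints
  k1 <- f(t0, y0)
  sc <- atol + rtol * abs(y0)
  d0 <- sqrt(mean((y0 / sc)^2)); d1 <- sqrt(mean((k1 / sc)^2))
  h <- if (d0 < 1e-5 || d1 < 1e-5) 1e-6 else 0.01 * d0 / d1
  h <- min(h, (t1 - t0) / 10, h_max, min_lag)
  ytrial <- y0 + h * k1
  f1 <- f(t0 + h, ytrial)
  d2 <- sqrt(mean(((f1 - k1) / sc)^2)) / h
  h1 <- if (max(d1, d2) <= 1e-15) max(1e-6, h * 1e-3) else
    (0.01 / max(d1, d2))^(1/5)
  h <- min(100 * h, h1, t1 - t0, h_max, min_lag)

  t <- t0; y <- y0
  K <- matrix(0, n, 7L)
  ib <- 1L  # index of next boundary (forced point or t1)
  steps <- 0L

  while (t < t1) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop(sprintf("step budget exhausted at t = %g", t), call. = FALSE)
    tb <- bounds[ib]
    h_use <- min(h, h_max, min_lag, t1 - t)
    hit <- FALSE
    if (t + h_use >= tb - 1e-12 * max(1, abs(tb))) {
      h_use <- tb - t
      hit <- TRUE
    }
    if (h_use < 1e-12 * max(1, abs(t)))
      stop(sprintf("step size underflow at t = %g", t), call. = FALSE)

    K[, 1L] <- k1
    for (s in 2:7) {
      acc <- K[, seq_len(s - 1L), drop = FALSE] %*% .dp_a[[s]]
      K[, s] <- f(t + .dp_c[s] * h_use, y + h_use * as.numeric(acc))
    }
    ynew <- y + h_use * as.numeric(K[, 1:6, drop = FALSE] %*% .dp_a[[7]])
    errv <- h_use * as.numeric(K %*% .dp_e)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    errnorm <- sqrt(mean((errv / sc)^2))

    if (errnorm <= 1) {
      naccept <- naccept + 1L
      if (nacc + 1L > cap) {  # grow storage
        cap2 <- cap * 2L
        ts <- c(ts, numeric(cap2 - cap)); hs <- c(hs, numeric(cap2 - cap))
        ys <- rbind(ys, matrix(0, cap2 - cap, n))
        Qs <- c(Qs, vector("list", cap2 - cap))
        cap <- cap2
      }
      nacc <- nacc + 1L
      tnew <- if (hit) tb else t + h_use
      ts[nacc + 1L] <- tnew
      ys[nacc + 1L, ] <- ynew
      hs[nacc] <- h_use
      Qs[[nacc]] <- K %*% .dp_P
      if (hit && tb < t1) ib <- ib + 1L
      t <- tnew; y <- ynew
      k1 <- K[, 7L]  # FSAL; also the derivative at the new point
      fac <- if (errnorm == 0) 5 else min(5, max(0.2, 0.9 * errnorm^(-0.2)))
      h <- h_use * fac
    } else {
      nreject <- nreject + 1L
      h <- h_use * max(0.1, 0.9 * errnorm^(-0.2))
    }
  }

  m <- nacc + 1L
  states <- ys[seq_len(m), , drop = FALSE]
  if (!is.null(state_names)) colnames(states) <- state_names
  structure(list(
    mesh_times = ts[seq_len(m)],
    states = states,
    hs = hs[seq_len(nacc)],
    Qs = Qs[seq_len(nacc)],
    span = c(t0, t1),
    state_names = state_names,
    history = history,
    diagnostics = list(naccept = naccept, nreject = nreject, nrhs = nrhs)),
    class = "hpa_solution")
}

#' Evaluate the dense output of a solution
#'
#' Continuous interpolation of an integrator result at arbitrary times inside
#' the integrated span. Exact (bitwise) at mesh nodes; no extrapolation.
#'
#' @param solution An `hpa_solution`.
#' @param t Numeric vector of times within the span.
#' @return For a single time, the state vector; for several, a matrix with
#'   one row per time.
#' @export
dense_eval <- function(solution, t) {
  stopifnot(inherits(solution, "hpa_solution"))
  t0 <- solution$span[1]; t1 <- solution$span[2]
  if (any(t < t0 | t > t1))
    stop(sprintf("time outside integrated span [%g, %g]", t0, t1),
         call. = FALSE)
  mesh <- solution$mesh_times
  n <- ncol(solution$states)
  out <- matrix(NA_real_, length(t), n)
  colnames(out) <- colnames(solution$states)
  exact <- match(t, mesh)
  hitidx <- which(!is.na(exact))
  if (length(hitidx))
    out[hitidx, ] <- solution$states[exact[hitidx], , drop = FALSE]
  rest <- which(is.na(exact))
  for (j in rest) {
    i <- findInterval(t[j], mesh, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(mesh) - 1L)
    theta <- (t[j] - mesh[i]) / solution$hs[i]
    p <- c(theta, theta^2, theta^3, theta^4)
    out[j, ] <- solution$states[i, ] +
      solution$hs[i] * as.numeric(solution$Qs[[i]] %*% p)
  }
  if (length(t) == 1L) as.numeric(out) else out
}

#' Sample a solution on a time grid
#'
#' @param solution An `hpa_solution`.
#' @param times Numeric vector of times within the span (may be empty).
#' @return Matrix with one row per requested time and one column per state.
#' @export
sample_solution <- function(solution, times) {
  stopifnot(inherits(solution, "hpa_solution"))
  n <- ncol(solution$states)
  if (length(times) == 0L) {
    m <- matrix(numeric(0), 0L, n)
    colnames(m) <- colnames(solution$states)
    return(m)
  }
  out <- dense_eval(solution, times)
  if (length(times) == 1L) out <- matrix(out, 1L, n,
                                         dimnames = list(NULL, colnames(solution$states)))
  out
}

#' @export
print.hpa_solution <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<hpa_solution> span [%g, %g] min, %d states, %d mesh points\n",
              x$span[1], x$span[2], ncol(x$states), length(x$mesh_times)))
  cat(sprintf("  steps: %d accepted, %d rejected; %d rhs evaluations\n",
              d$naccept, d$nreject, d$nrhs))
  invisible(x)
}

#' Tidy a solution into a long tibble
#'
#' @param x An `hpa_solution`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `state`, `value` on the mesh.
#' @method tidy hpa_solution
#' @export
tidy.hpa_solution <- function(x, ...) {
  nms <- colnames(x$states)
  if (is.null(nms)) nms <- paste0("y", seq_len(ncol(x$states)))
  tibble::tibble(
    time = rep(x$mesh_times, times = ncol(x$states)),
    state = factor(rep(nms, each = length(x$mesh_times)), levels = nms),
    value = as.numeric(x$states))
}

#' @method autoplot hpa_solution
#' @export
autoplot.hpa_solution <- function(object, ...) {
  df <- tidy.hpa_solution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (model units)")
}
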