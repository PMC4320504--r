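#' Functional parameters of the thermoregulatory feedback model
#'
#' Bundle the four parameters that identify one skin-temperature recovery
#' response: the lag time `lt` before the active re-warming controller is
#' switched on, the open-loop plant pole `a` (inverse time constant of the
#' first-order plant), the constant disturbance input `d` (passive heat
#' exchange with the environment, on the deviation temperature scale), and
#' the integral controller gain `k` (strength of the active vasodilatory
#' recovery). All times and rates are in sample units (one sample = 10 s at
#' the default 0.1 Hz sampling rate).
#'
#' The plant input gain equals the plant pole (unitary-gain plant), so it is
#' not a free parameter.
#'
#' @param lt Lag time, samples, `>= 0`.
#' @param a Open-loop pole, 1/sample.
#' @param d Disturbance input, deviation temperature units.
#' @param k Integral controller gain, 1/sample.
#' @return An object of class `thermo_params`.
#' @examples
#' model_params(lt = 6, a = 0.1, d = -0.07, k = 0.3)
#' @export
model_params <- function(lt, a, d, k) {
  vals <- c(lt = lt, a = a, d = d, k = k)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("model parameters must be four finite numbers (lt, a, d, k)")
  if (lt < 0)
    stop("lag time `lt` must be non-negative")
  structure(as.list(vals), class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> LT = %g samples, a = %g /sample, d = %g, k = %g /sample\n",
              x$lt, x$a, x$d, x$k))
  invisible(x)
}

#' Extract the parameter vector
#'
#' @param p A `thermo_params`.
#' @return Named numeric vector `(lt, a, d, k)`.
#' @export
params_vector <- function(p) {
  stopifnot(inherits(p, "thermo_params"))
  c(lt = p$lt, a = p$a, d = p$d, k = p$k)
}

#' Uniform sampling grid
#'
#' @param n_samples Number of samples, `>= 2`.
#' @param dt Sample spacing (sample units by default, `dt = 1`).
#' @param t0 Time origin; 0 marks the end of the exercise.
#' @return Object of class `time_grid`.
#' @export
time_grid <- function(n_samples, dt = 1, t0 = 0) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("grid needs at least 2 samples")
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  structure(list(n_samples = n_samples, dt = dt, t0 = t0), class = "time_grid")
}

#' Sample times of a grid
#' @param grid A `time_grid`.
#' @return Numeric vector of length `n_samples`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + grid$dt * (seq_len(grid$n_samples) - 1)
}

#' Temperature deviation series
#'
#' A recovery trace in deviation coordinates: temperature minus the
#' post-exercise temperature `y0`, so the first recovery sample is 0 and the
#' basal reference is `r = T - y0`.
#'
#' @param grid A `time_grid`.
#' @param values Numeric vector, one value per grid sample.
#' @return Object of class `deviation_series`.
#' @export
deviation_series <- function(grid, values) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_samples)
    stop("length of `values` must equal grid$n_samples")
  if (!all(is.finite(values))) stop("deviation values must be finite")
  structure(list(grid = grid, values = values), class = "deviation_series")
}

# Exact propagator factors of the closed-loop 2x2 linear system.
# exp(At) = EC(t) I + ES(t) (A - mu I) with mu = tr(A)/2, om2 = mu^2 - det(A).
# Returns EC, ES evaluated at times t, overflow-clamped so that extreme
# unstable parameter proposals yield huge finite costs rather than NaN.
.phase_factors <- function(mu, om2, t) {
  if (om2 > 1e-12) {          # overdamped: two real poles
    om <- sqrt(om2)
    e1 <- exp(pmin((mu + om) * t, 700))
    e2 <- exp(pmin((mu - om) * t, 700))
    list(ec = (e1 + e2) / 2, es = (e1 - e2) / (2 * om))
  } else if (om2 < -1e-12) {  # underdamped: complex pair
    nu <- sqrt(-om2)
    em <- exp(pmin(mu * t, 700))
    list(ec = em * cos(nu * t), es = em * sin(nu * t) / nu)
  } else {                    # critically damped (repeated pole)
    em <- exp(pmin(mu * t, 700))
    list(ec = em * (1 + om2 * t^2 / 2), es = em * t * (1 + om2 * t^2 / 6))
  }
}

# Exact closed-loop state at times t (vector), from initial state (y0, m0)
# at t = 0. System: dy/dt = a (m + d - y), dm/dt = k (r - y).
.closed_loop_state <- function(a, d, k, r, y0, m0, t) {
  if (k == 0) {
    yinf <- m0 + d
    return(list(y = yinf + (y0 - yinf) * exp(-a * t), m = rep(m0, length(t))))
  }
  # equilibrium: y = r, m = r - d; deviations follow dz/dt = A z
  zy <- y0 - r
  zm <- m0 - (r - d)
  mu <- -a / 2
  om2 <- mu^2 - a * k
  f <- .phase_factors(mu, om2, t)
  az_y <- -a * zy + a * zm          # first row of A %*% z
  az_m <- -k * zy
  list(y = r + f$ec * zy + f$es * (az_y - mu * zy),
       m = (r - d) + f$ec * zm + f$es * (az_m - mu * zm))
}

#' Simulate the open-loop (pre-onset) response
#'
#' Before the lag time the controller is disabled and the plant is driven by
#' the constant disturbance alone: `dy/dt = a (d - y)` with `y(0) = 0`, whose
#' solution is `y(t) = d (1 - exp(-a t))`.
#'
#' @param params A `thermo_params` (only `a` and `d` are used; `a >= 0`).
#' @param grid A `time_grid` with `t0 = 0`.
#' @return A `deviation_series`.
#' @export
simulate_open_loop <- function(params, grid) {
  stopifnot(inherits(params, "thermo_params"), inherits(grid, "time_grid"))
  if (params$a < 0) stop("open-loop pole `a` must be non-negative")
  t <- grid_times(grid)
  deviation_series(grid, params$d * (1 - exp(-params$a * t)))
}

#' Simulate the closed-loop (re-warming) response
#'
#' After the lag time the integral controller closes the loop:
#' `dy/dt = a (m + d - y)`, `dm/dt = k (r - y)`. The solution is evaluated in
#' exact closed form (matrix-exponential of the 2x2 system). For `k > 0` and
#' `a > 0` the output converges to the reference `r` with zero steady-state
#' error, the defining property of integral control.
#'
#' @param params A `thermo_params`; `a > 0` required when `k != 0`.
#' @param r Deviation reference (basal minus post-exercise temperature).
#' @param grid A `time_grid`; times are measured from the regime switch.
#' @param init List with elements `y` and `m`, the plant output and
#'   integrator state at the switch.
#' @return A `deviation_series`.
#' @export
simulate_closed_loop <- function(params, r, grid, init = list(y = 0, m = 0)) {
  stopifnot(inherits(params, "thermo_params"), inherits(grid, "time_grid"))
  if (!is.finite(r)) stop("reference `r` must be finite")
  if (params$a <= 0 && params$k != 0)
    stop("plant pole `a` must be positive in closed loop")
  t <- grid_times(grid) - grid$t0
  st <- .closed_loop_state(params$a, params$d, params$k, r, init$y, init$m, t)
  deviation_series(grid, st$y)
}

#' Simulate the full switched recovery response
#'
#' Piecewise trajectory of the supervised feedback loop: open loop on
#' `[0, lt)`, closed loop from `lt` on. The lag time is continuous (not
#' grid-aligned): the closed-loop phase starts from the open-loop solution
#' evaluated exactly at `t = lt`, with the integrator reset to `m(lt) = 0`.
#' If `lt` is at or beyond the end of the grid the whole response is open
#' loop.
#'
#' @inheritParams simulate_closed_loop
#' @return A `deviation_series` on `grid`.
#' @examples
#' p <- model_params(lt = 6, a = 0.1, d = -0.07, k = 0.3)
#' y <- simulate_response(p, r = 1, time_grid(30))
#' @export
simulate_response <- function(params, r, grid) {
  stopifnot(inherits(params, "thermo_params"), inherits(grid, "time_grid"))
  t <- grid_times(grid)
  y <- numeric(grid$n_samples)
  open <- t < params$lt
  if (any(open))
    y[open] <- params$d * (1 - exp(-params$a * t[open]))
  if (any(!open)) {
    if (params$a <= 0 && params$k != 0)
      stop("plant pole `a` must be positive in closed loop")
    y_lt <- params$d * (1 - exp(-params$a * params$lt))
    st <- .closed_loop_state(params$a, params$d, params$k, r,
                             y0 = y_lt, m0 = 0, t = t[!open] - params$lt)
    y[!open] <- st$y
  }
  deviation_series(grid, y)
}

#' Convert a deviation series back to absolute temperature
#'
#' Inverse of [deviation_transform()]: adds the post-exercise temperature
#' `y0` to every deviation value.
#'
#' @param dev A `deviation_series`.
#' @param y0 Post-exercise temperature, degrees C.
#' @param roi,subject_id,group_label Optional labels for the result.
#' @return A `temperature_series`.
#' @export
to_absolute <- function(dev, y0, roi = NA_character_,
                        subject_id = NA_character_,
                        group_label = "unknown") {
  stopifnot(inherits(dev, "deviation_series"))
  if (!is.finite(y0)) stop("`y0` must be finite")
  temperature_series(dev$grid, dev$values + y0, roi = roi,
                     subject_id = subject_id, group_label = group_label,
                     check_window = FALSE)
}
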