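#' Parameter search space
#'
#' Box bounds for the four model parameters used by the graphical
#' initialisation, the simplex penalty, and the bounded least-squares
#' refinement. Defaults are the standard identification bounds for this
#' model: LT in [0, 22] samples, a in [0.01, 30] /sample, k in [-5, 100]
#' /sample, d in [-5, 10].
#'
#' @param lt,a,k,d Length-2 numeric `c(lower, upper)` for each parameter.
#' @return Object of class `search_space`.
#' @export
search_space <- function(lt = c(0, 22), a = c(0.01, 30),
                         k = c(-5, 100), d = c(-5, 10)) {
  sp <- list(lt = lt, a = a, d = d, k = k)
  for (nm in names(sp)) {
    b <- sp[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds for `", nm, "` must be finite with lower < upper")
  }
  structure(sp, class = "search_space")
}

.space_lower <- function(space) vapply(space, `[`, numeric(1), 1L)
.space_upper <- function(space) vapply(space, `[`, numeric(1), 2L)

.clip_to_space <- function(p, space) {
  th <- if (inherits(p, "thermo_params")) unname(params_vector(p)) else as.numeric(p)
  v <- pmin(pmax(th, .space_lower(space)), .space_upper(space))
  model_params(v[1], v[2], v[3], v[4])
}

#' Mean-squared-error cost of a fit
#'
#' The least-squares criterion between a simulated and an observed recovery
#' curve: `f = (1/NE) * sum((y_sim - y_obs)^2)`, in squared degrees C.
#' Normalising by the number of points NE makes the exclusion threshold of
#' [exclude_poor_fits()] length-independent (cost 1 is about 1 degC RMS
#' misfit).
#'
#' @param observed,simulated `deviation_series` (or numeric vectors) of
#'   equal length `NE >= 4`.
#' @return The scalar cost.
#' @export
cost_function <- function(observed, simulated) {
  yo <- if (inherits(observed, "deviation_series")) observed$values else as.numeric(observed)
  ys <- if (inherits(simulated, "deviation_series")) simulated$values else as.numeric(simulated)
  if (length(yo) != length(ys))
    stop("observed and simulated series must have equal length")
  if (length(yo) < 4L) stop("need at least 4 points to evaluate the cost")
  mean((ys - yo)^2)
}

# Cost of a raw parameter vector th = (lt, a, d, k) against the observed
# deviation curve; proposals outside the box are evaluated at the clipped
# point plus a quadratic penalty (1e3 * squared violation).
.penalised_cost <- function(th, observed, r, space, penalty = 1e3) {
  lo <- .space_lower(space); up <- .space_upper(space)
  viol <- pmax(0, lo - th) + pmax(0, th - up)
  thc <- pmin(pmax(th, lo), up)
  p <- model_params(thc[1], thc[2], thc[3], thc[4])
  sim <- simulate_response(p, r, observed$grid)
  cost_function(observed, sim) + penalty * sum(viol^2)
}

#' Graphical initial estimate of the model parameters
#'
#' Time-domain identification from the shape of the recovery curve, in the
#' classical step-response reading: the lag time is the turning point before
#' the sustained re-warming rise (the undershoot extremum when there is
#' one); the pole `a` is the inverse of the time taken, after the lag, to
#' cover 63% of the remaining distance to the final value; the disturbance
#' `d` is the value at the turning point (open-loop asymptote estimate); and
#' the whole-loop gain (final value over the reference) is bridged to the
#' controller gain as `k0 = gain * a0` because the plant has unit static
#' gain. All estimates are clipped into the search space.
#'
#' @param recovery A `deviation_series` of the recovery phase, length >= 8.
#' @param ref A `reference_signal` (supplies `r`).
#' @param space A [search_space()].
#' @return A `thermo_params` initial guess.
#' @export
graphical_init <- function(recovery, ref, space = search_space()) {
  stopifnot(inherits(recovery, "deviation_series"))
  y <- recovery$values
  t <- grid_times(recovery$grid)
  n <- length(y)
  if (n < 8L) stop("graphical initialisation needs at least 8 samples")
  final <- mean(y[(n - 2):n])
  rng <- diff(range(y))
  centre <- (.space_lower(space) + .space_upper(space)) / 2
  if (rng < 1e-12) {
    warning("flat recovery curve: degenerate initialisation at the search-space centre")
    return(model_params(centre[1], centre[2], centre[3], centre[4]))
  }
  s <- diff(y) / diff(t)
  # onset of sustained re-warming: first slope exceeding 5% of the peak slope
  rise <- which(s > 0.05 * max(s))
  if (max(s) <= 0 || !length(rise)) {
    # monotone cooling: no re-warming onset exists, lag clipped to its upper bound
    i_lt <- n
    lt0 <- .space_upper(space)[["lt"]]
  } else {
    i_lt <- min(rise)               # sample just before the rise starts
    lt0 <- t[i_lt]
  }
  d0 <- y[i_lt]
  # 63% of the remaining distance from the turning point to the final value
  target <- y[i_lt] + (1 - exp(-1)) * (final - y[i_lt])
  after <- seq.int(i_lt, n)
  hit <- if (final >= y[i_lt]) after[y[after] >= target] else after[y[after] <= target]
  a0 <- if (length(hit) && t[hit[1]] > t[i_lt]) 1 / (t[hit[1]] - t[i_lt]) else
    .space_upper(space)[["a"]]
  gain <- if (abs(ref$r) > 1e-12) final / ref$r else 0
  k0 <- gain * a0
  .clip_to_space(c(lt0, a0, d0, k0), space)
}

#' Nelder-Mead refinement of an initial estimate
#'
#' Simplex minimisation of the least-squares cost of the simulated response
#' against the observed recovery. The search itself is unconstrained;
#' proposals outside the search space are evaluated at their clipped point
#' with a quadratic penalty added, and the incumbent is clipped to the box
#' on return. Deterministic: two runs from the same data and start give the
#' same result.
#'
#' @param recovery Observed `deviation_series`.
#' @param ref A `reference_signal`.
#' @param init A `thermo_params` starting point.
#' @param space A [search_space()].
#' @param max_iter Iteration cap (default 500).
#' @return A `thermo_params`.
#' @export
simplex_refine <- function(recovery, ref, init, space = search_space(),
                           max_iter = 500L) {
  stopifnot(inherits(recovery, "deviation_series"),
            inherits(init, "thermo_params"))
  th0 <- unname(params_vector(init))
  opt <- stats::optim(th0, .penalised_cost, observed = recovery, r = ref$r,
                      space = space, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-10))
  best <- if (opt$value <= .penalised_cost(th0, recovery, ref$r, space)) opt$par else th0
  .clip_to_space(best, space)
}

#' Bounded nonlinear least-squares fit
#'
#' Final refinement stage: Levenberg-Marquardt least squares on the residual
#' vector between the simulated and observed recovery, with box constraints
#' from the search space. The basal reference and post-exercise temperature
#' are measured quantities and are never fitted.
#'
#' @inheritParams simplex_refine
#' @param max_iter Iteration cap (default 200).
#' @return A `fit_result`: list with `params`, `cost`, `n_points`,
#'   `converged`, `excluded` (filled by [exclude_poor_fits()]), and
#'   `init_params` (provenance).
#' @export
fit_nls <- function(recovery, ref, init, space = search_space(),
                    max_iter = 200L) {
  stopifnot(inherits(recovery, "deviation_series"),
            inherits(init, "thermo_params"))
  lo <- .space_lower(space); up <- .space_upper(space)
  eps <- 1e-8 * (up - lo)
  th0 <- pmin(pmax(unname(params_vector(init)), lo + eps), up - eps)
  resid_fn <- function(th) {
    p <- model_params(th[1], th[2], th[3], th[4])
    simulate_response(p, ref$r, recovery$grid)$values - recovery$values
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = th0, lower = lo, upper = up, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = 1e-10, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("least-squares refinement failed; returning the starting point")
    params <- .clip_to_space(th0, space)
    conv <- FALSE
  } else {
    params <- .clip_to_space(fit$par, space)
    conv <- fit$info %in% 1:4
    if (!conv) warning("least-squares refinement did not converge: ", fit$message)
  }
  sim <- simulate_response(params, ref$r, recovery$grid)
  structure(list(params = params,
                 cost = cost_function(recovery, sim),
                 n_points = recovery$grid$n_samples,
                 converged = conv,
                 excluded = NA,
                 init_params = init),
            class = "fit_result")
}

#' Full three-stage fit of one recovery curve
#'
#' Graphical initialisation, simplex refinement, then bounded nonlinear
#' least squares. The cost never increases across stages: if a later stage
#' ends worse (possible only in degenerate corners), the better earlier
#' incumbent is kept.
#'
#' @inheritParams simplex_refine
#' @return A `fit_result` (see [fit_nls()]).
#' @examples
#' p <- model_params(lt = 6, a = 0.1, d = -0.07, k = 0.3)
#' obs <- simulate_response(p, r = 1, time_grid(30))
#' ref <- structure(list(T = 31, y0 = 30, r = 1), class = "reference_signal")
#' fit_curve(obs, ref)$params
#' @export
fit_curve <- function(recovery, ref, space = search_space()) {
  init <- graphical_init(recovery, ref, space)
  ref1 <- simplex_refine(recovery, ref, init, space)
  fit <- fit_nls(recovery, ref, ref1, space)
  cost_simplex <- cost_function(
    recovery, simulate_response(ref1, ref$r, recovery$grid))
  if (fit$cost > cost_simplex) {
    fit$params <- ref1
    fit$cost <- cost_simplex
  }
  fit$init_params <- init
  fit
}

#' Drop poorly fitted curves
#'
#' Marks fits with cost strictly greater than the threshold as excluded and
#' returns only the retained ones. The comparison is strict, so a cost of
#' exactly 1 is retained under the default threshold.
#'
#' @param fits List of `fit_result`.
#' @param threshold Cost threshold, default 1 (squared degrees C).
#' @return List of retained `fit_result`s, each with `excluded = FALSE`;
#'   the number excluded is reported via a message.
#' @export
exclude_poor_fits <- function(fits, threshold = 1) {
  if (!length(fits)) return(fits)
  costs <- vapply(fits, function(f) f$cost, numeric(1))
  keep <- costs <= threshold
  fits <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; f$excluded <- !keep[i]; f
  })
  message(sprintf("excluded %d of %d fits (cost > %g)",
                  sum(!keep), length(keep), threshold))
  fits[keep]
}
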