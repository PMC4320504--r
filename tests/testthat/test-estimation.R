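test_that("cost function is the mean squared residual", {
  g <- time_grid(5)
  x <- deviation_series(g, c(0, 0.1, 0.3, 0.6, 1))
  expect_equal(cost_function(x, x), 0)
  y <- deviation_series(g, x$values + 1)
  expect_equal(cost_function(x, y), 1)
  # hand arithmetic: (0.01 + 0.01 + 0.04) / 3
  expect_equal(cost_function(c(0, 0.5, 1, 0), c(0.1, 0.4, 1.2, 0)),
               0.06 / 4)
  expect_equal(cost_function(c(0, 0.5, 1, 9), c(0.1, 0.4, 1.2, 9)),
               0.015, tolerance = 1e-12)
  expect_error(cost_function(1:5, 1:4), "equal length")
  expect_error(cost_function(1:3, 1:3), "at least 4")
})

test_that("graphical initialisation reads lag, pole, disturbance and gain off the curve", {
  g <- time_grid(30)
  ref <- make_ref(31, 30)
  p <- model_params(6, 0.1, -0.07, 0.3)
  init <- graphical_init(simulate_response(p, 1, g), ref)
  iv <- params_vector(init)
  expect_lte(abs(iv[["lt"]] - 6), 2)
  expect_lt(iv[["d"]], 0)
  # monotone cooling curve, no re-warming onset: lag clipped to its upper bound
  cool <- simulate_open_loop(model_params(0, 0.2, -0.9, 0), g)
  init2 <- graphical_init(cool, make_ref(30.2, 30))
  expect_equal(params_vector(init2)[["lt"]], 22)
  # response already at its final value at the turning point: the 63% time
  # is below the grid resolution, so the pole clips to its upper bound
  step <- deviation_series(g, c(0, -0.5, 0.5, rep(-0.5, 27)))
  init3 <- graphical_init(step, ref)
  expect_equal(params_vector(init3)[["a"]], 30)
  # flat curve: degenerate fallback at the search-space centre, with warning
  flat <- deviation_series(g, rep(0, 30))
  expect_warning(init4 <- graphical_init(flat, ref), "degenerate")
  expect_equal(params_vector(init4)[["lt"]], 11)
})

test_that("simplex refinement descends deterministically and respects bounds", {
  g <- time_grid(30)
  ref <- make_ref(31, 30)
  p <- model_params(6, 0.1, -0.07, 0.3)
  obs <- simulate_response(p, 1, g)
  # starting at the optimum stays there
  at_opt <- simplex_refine(obs, ref, p)
  expect_lt(cost_function(obs, simulate_response(at_opt, 1, g)), 1e-10)
  # a perturbed start strictly improves
  pert <- model_params(7.2, 0.12, -0.084, 0.36)
  ref1 <- simplex_refine(obs, ref, pert)
  expect_lt(cost_function(obs, simulate_response(ref1, 1, g)),
            cost_function(obs, simulate_response(pert, 1, g)))
  # deterministic: identical runs give identical parameters
  expect_identical(params_vector(simplex_refine(obs, ref, pert)),
                   params_vector(ref1))
  # incumbent is inside the search box
  sp <- search_space()
  v <- params_vector(ref1)
  expect_true(all(v >= c(0, 0.01, -5, -5) & v <= c(22, 30, 10, 100)))
})

test_that("three-stage pipeline recovers noiseless generating parameters", {
  g <- time_grid(30)
  ref <- make_ref(31, 30)
  for (truth in list(model_params(6, 0.1, -0.07, 0.3),     # undershoot regime
                     model_params(7, 0.8, 0.03, 1.5))) {   # fast no-undershoot regime
    obs <- simulate_response(truth, 1, g)
    fit <- fit_curve(obs, ref)
    th <- params_vector(fit$params)
    tr <- params_vector(truth)
    expect_lt(abs(th[["lt"]] - tr[["lt"]]), 0.2)
    for (nm in c("a", "d", "k"))
      expect_lt(abs(th[[nm]] - tr[[nm]]) / abs(tr[[nm]]), 0.02)
    expect_lt(fit$cost, 1e-8)
    expect_true(fit$converged)
  }
})

test_that("fitting pure noise stays bounded by the irreducible error and does not crash", {
  g <- time_grid(30)
  set.seed(9)
  noise <- rnorm(30, 0, 0.1)
  obs <- deviation_series(g, noise - noise[1])
  fit <- suppressWarnings(fit_curve(obs, make_ref(30.5, 30)))
  expect_true(is.finite(fit$cost))
  # the 4-parameter model cannot absorb white noise: cost stays near sigma^2
  expect_gt(fit$cost, 0.1^2 / 4)
})

test_that("refinement stages never increase the cost", {
  g <- time_grid(30)
  ref <- make_ref(31, 30)
  set.seed(77)
  for (i in 1:5) {
    p <- model_params(runif(1, 1, 12), runif(1, 0.05, 1.5),
                      runif(1, -0.5, 0.5), runif(1, 0.05, 2))
    y <- simulate_response(p, 1, g)$values + rnorm(30, 0, 0.05)
    obs <- deviation_series(g, y - y[1])
    init <- suppressWarnings(graphical_init(obs, ref))
    c_init <- cost_function(obs, simulate_response(init, 1, g))
    s <- suppressWarnings(simplex_refine(obs, ref, init))
    c_simplex <- cost_function(obs, simulate_response(s, 1, g))
    f <- suppressWarnings(fit_nls(obs, ref, s))
    expect_lte(c_simplex, c_init + 1e-12)
    expect_lte(f$cost, c_simplex + 1e-12)
  }
})

test_that("estimates stay inside the search space on adversarial inputs", {
  g <- time_grid(30)
  set.seed(13)
  for (i in 1:5) {
    y <- cumsum(rnorm(30, 0, 0.3))
    obs <- deviation_series(g, y - y[1])
    fit <- suppressWarnings(fit_curve(obs, make_ref(30.8, 30)))
    v <- params_vector(fit$params)
    expect_true(all(v >= c(0, 0.01, -5, -5) - 1e-12 &
                      v <= c(22, 30, 10, 100) + 1e-12))
  }
})

test_that("noiseless recovery is exact in median over the identifiable regime", {
  # parameters drawn from the physiological sub-box the group table occupies;
  # dynamics faster than the sampling rate or lags at the window end are not
  # identifiable from 30 samples and are excluded by construction
  set.seed(55)
  n <- 200
  relerr <- matrix(NA_real_, n, 4)
  ref_t <- 30
  for (i in 1:n) {
    p <- model_params(runif(1, 0, 15), runif(1, 0.05, 2),
                      runif(1, -1, 1), runif(1, 0.05, 3))
    r <- runif(1, 0.3, 1.5)
    obs <- simulate_response(p, r, time_grid(30))
    ref <- structure(list(T = ref_t + r, y0 = ref_t, r = r),
                     class = "reference_signal")
    f <- suppressWarnings(fit_curve(obs, ref))
    relerr[i, ] <- abs(params_vector(f$params) - params_vector(p)) /
      pmax(abs(params_vector(p)), 1e-6)
  }
  expect_true(all(apply(relerr, 2, stats::median) < 0.01))
})

test_that("exclusion threshold is strict: cost exactly 1 is retained", {
  mk <- function(cost) structure(list(params = model_params(1, 1, 0, 1),
                                      cost = cost, n_points = 30,
                                      converged = TRUE, excluded = NA,
                                      init_params = NULL), class = "fit_result")
  fits <- lapply(c(0.2, 1.0, 1.01), mk)
  kept <- suppressMessages(exclude_poor_fits(fits))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(f) f$cost, numeric(1)), c(0.2, 1.0))
  expect_false(any(vapply(kept, function(f) f$excluded, logical(1))))
  expect_length(suppressMessages(exclude_poor_fits(list())), 0)
  all_zero <- lapply(c(0, 0, 0), mk)
  expect_length(suppressMessages(exclude_poor_fits(all_zero)), 3)
})
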