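# Independent brute-force oracle for the switched feedback model.
#
# Fixed-step classical RK4 on the augmented linear state w = (y, m, 1):
# dw/dt = B w, with the controller row zeroed during the open-loop phase and
# the integrator reset at the (continuous, not grid-aligned) switch time.
# For a linear system one RK4 step of size h is exactly the degree-4 Taylor
# matrix R(Bh) = I + Bh + (Bh)^2/2 + (Bh)^3/6 + (Bh)^4/24 applied to the
# state, which lets the fixed-step integration run at tiny steps without an
# R-level loop per substep. This is an independent discretisation: it never
# touches the package's closed-form propagator.
rk4_step_matrix <- function(B, h) {
  Bh <- B * h
  I3 <- diag(nrow(B))
  I3 + Bh + Bh %*% Bh / 2 + Bh %*% Bh %*% Bh / 6 + Bh %*% Bh %*% Bh %*% Bh / 24
}

mat_pow <- function(M, n) {
  R <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) R <- R %*% M
    M <- M %*% M
    n <- n %/% 2
  }
  R
}

# y(t) on the grid by brute-force RK4 with `substeps` steps per sample.
rk4_switched_response <- function(params, r, grid, substeps = 100L) {
  a <- params$a; d <- params$d; k <- params$k; lt <- params$lt
  dt <- grid$dt
  h <- dt / substeps
  B_open <- matrix(c(-a, 0, a * d,
                     0, 0, 0,
                     0, 0, 0), 3, byrow = TRUE)
  B_closed <- matrix(c(-a, a, a * d,
                       -k, 0, k * r,
                       0, 0, 0), 3, byrow = TRUE)
  Mo <- rk4_step_matrix(B_open, h)
  Mc <- rk4_step_matrix(B_closed, h)
  Mo_grid <- mat_pow(Mo, substeps)
  Mc_grid <- mat_pow(Mc, substeps)
  t <- grid_times(grid)
  n <- grid$n_samples
  y <- numeric(n)
  w <- c(0, 0, 1)
  y[1] <- 0
  switched <- lt <= 0
  if (switched) w[2] <- 0
  for (i in 2:n) {
    t_prev <- t[i - 1]; t_next <- t[i]
    if (!switched && lt >= t_next) {
      w <- Mo_grid %*% w
    } else if (switched) {
      w <- Mc_grid %*% w
    } else {
      # the switch falls inside this sample interval: integrate the open
      # phase up to lt (full steps + one partial), reset m, then the closed
      # phase to the grid point
      span1 <- lt - t_prev
      nf <- floor(span1 / h + 1e-9)
      w <- mat_pow(Mo, nf) %*% w
      rem <- span1 - nf * h
      if (rem > 1e-12) w <- rk4_step_matrix(B_open, rem) %*% w
      w[2] <- 0
      span2 <- t_next - lt
      nf2 <- floor(span2 / h + 1e-9)
      rem2 <- span2 - nf2 * h
      if (rem2 > 1e-12) w <- rk4_step_matrix(B_closed, rem2) %*% w
      w <- mat_pow(Mc, nf2) %*% w
      switched <- TRUE
    }
    y[i] <- w[1]
  }
  y
}

# Brute force done properly: start at dt/100 and halve the step until two
# successive refinements agree, so the oracle's own discretisation error is
# far below the comparison tolerance.
rk4_converged_response <- function(params, r, grid, tol = 1e-8,
                                   substeps0 = 100L, max_doublings = 8L) {
  y_prev <- rk4_switched_response(params, r, grid, substeps0)
  s <- substeps0
  for (i in seq_len(max_doublings)) {
    s <- s * 2L
    y_next <- rk4_switched_response(params, r, grid, s)
    if (max(abs(y_next - y_prev)) < tol) return(y_next)
    y_prev <- y_next
  }
  y_prev
}

# Uniform draw of a parameter set from the standard search space, optionally
# restricted to closed-loop-stable dynamics (k >= 0).
draw_space_params <- function(stable = TRUE, space = search_space()) {
  lo <- vapply(space, `[`, numeric(1), 1L)
  up <- vapply(space, `[`, numeric(1), 2L)
  if (stable) lo[["k"]] <- 0
  model_params(lt = stats::runif(1, lo[["lt"]], up[["lt"]]),
               a = stats::runif(1, lo[["a"]], up[["a"]]),
               d = stats::runif(1, lo[["d"]], up[["d"]]),
               k = stats::runif(1, lo[["k"]], up[["k"]]))
}

# Group table tamed to stable, in-window dynamics: recordings drawn from it
# always stay inside the 15-42 degC plausibility window, so I/O round-trip
# properties can be tested independently of the generator's unstable tail.
stable_param_table <- function() {
  tbl <- group_param_table()
  tbl$k_mean <- abs(tbl$k_mean) + 0.5
  tbl$k_sd <- pmin(tbl$k_sd, 0.1)
  tbl$a_sd <- pmin(tbl$a_sd, 0.5)
  tbl$d_sd <- pmin(tbl$d_sd, 0.3)
  tbl
}

make_ref <- function(T_basal = 31, y0 = 30) {
  structure(list(T = T_basal, y0 = y0, r = T_basal - y0),
            class = "reference_signal")
}
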