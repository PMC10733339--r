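#' Runge-Kutta start-up steps
#'
#' Classical fourth-order one-step method used to seed the multistep solver
#' with the first few states. Exposed mainly for testing; k = 0 returns the
#' initial state alone.
#'
#' @param model An \code{ll_model}.
#' @param init Initial state on the unit simplex.
#' @param h Step size, > 0.
#' @param k Number of steps; a 4th-order multistep method needs k >= 3.
#' @param x0 Starting x (default 0).
#' @return Matrix of k + 1 rows (states at x0, x0 + h, ..., x0 + k h).
#' @export
rk4_start <- function(model, init, h, k, x0 = 0) {
  stopifnot(inherits(model, "ll_model"), h > 0, k >= 0)
  check_simplex(init)
  A <- rate_matrix(model)
  states <- matrix(NA_real_, nrow = k + 1L, ncol = 3L)
  states[1L, ] <- init
  y <- init
  for (i in seq_len(k)) {
    k1 <- drop(A %*% y)
    k2 <- drop(A %*% (y + h / 2 * k1))
    k3 <- drop(A %*% (y + h / 2 * k2))
    k4 <- drop(A %*% (y + h * k3))
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    states[i + 1L, ] <- y
  }
  states
}

#' Adams-Bashforth-Moulton reference trajectory
#'
#' Fourth-order predictor-corrector solution on a uniform grid: the 4-step
#' Adams-Bashforth predictor followed by one Adams-Moulton correction per
#' step (PECE mode), started with three classical Runge-Kutta steps. This
#' is the reference solver that generates the training data for the neural
#' surrogate; at the default step 0.01 its global error against the exact
#' matrix-exponential solution is far below the network's approximation
#' error.
#'
#' Grids with fewer than 5 points fall back to the pure one-step
#' Runge-Kutta method (documented behaviour, not an error).
#'
#' @inheritParams rk4_start
#' @param x0,x1 Interval endpoints (defaults 0 and 1).
#' @param h Step size (default 0.01, giving 101 grid points on the unit
#'   interval).
#' @return A tibble with columns \code{x, u, f, m}, attribute
#'   \code{method = "adams"}.
#' @examples
#' solve_adams(make_case(1), h = 0.1)
#' @export
solve_adams <- function(model, init = c(1, 0, 0), x0 = 0, x1 = 1, h = 0.01) {
  stopifnot(inherits(model, "ll_model"), h > 0, x1 > x0)
  check_simplex(init)
  n_steps <- round((x1 - x0) / h)
  xs <- x0 + h * (0:n_steps)
  n <- n_steps + 1L
  if (n < 5L) {
    states <- rk4_start(model, init, h, n_steps, x0 = x0)
    return(new_trajectory(xs, states, method = "adams"))
  }
  A <- rate_matrix(model)
  states <- matrix(NA_real_, nrow = n, ncol = 3L)
  states[1:4, ] <- rk4_start(model, init, h, 3L, x0 = x0)
  derivs <- t(A %*% t(states[1:4, , drop = FALSE]))  # f values at the start-up points
  fs <- matrix(NA_real_, nrow = n, ncol = 3L)
  fs[1:4, ] <- derivs
  for (i in 4:(n - 1L)) {
    yn <- states[i, ]
    # AB4 predict
    yp <- yn + h / 24 * (55 * fs[i, ] - 59 * fs[i - 1L, ] +
                         37 * fs[i - 2L, ] - 9 * fs[i - 3L, ])
    fp <- drop(A %*% yp)
    # AM4 correct (one correction), then re-evaluate
    yc <- yn + h / 24 * (9 * fp + 19 * fs[i, ] - 5 * fs[i - 1L, ] + fs[i - 2L, ])
    states[i + 1L, ] <- yc
    fs[i + 1L, ] <- drop(A %*% yc)
  }
  new_trajectory(xs, states, method = "adams")
}
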