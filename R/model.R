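#' Compartmental language-learning model
#'
#' Constructs the parameter object for the three-compartment model of
#' language acquisition. The state splits a learner's knowledge into the
#' proportions unknown \eqn{u(x)}, familiar \eqn{f(x)} and mastered
#' \eqn{m(x)}, which always sum to one. Knowledge flows
#' unknown -> familiar -> mastered at learning rate \code{alpha}, and decays
#' back (mastered -> familiar -> unknown) at forgetting rates derived from
#' \code{beta}:
#' \deqn{du/dx = \beta f/(1+2\alpha) - \alpha u}
#' \deqn{df/dx = -\alpha f - \beta f/(1+2\alpha) + \alpha u + \beta m/(2+4\alpha)}
#' \deqn{dm/dx = \alpha f - \beta m/(2+4\alpha)}
#' The structure is the same as an SIR-type compartmental model: a linear,
#' constant-coefficient system whose rate matrix has zero column sums
#' (conservation) and Metzler sign pattern (nonnegative off-diagonals).
#'
#' @param alpha Learning-rate constant, strictly inside (0, 1). Dimensionless.
#' @param beta Forgetting-rate constant, strictly inside (0, 1). Dimensionless.
#' @return An object of class \code{ll_model} with fields \code{alpha} and
#'   \code{beta}.
#' @examples
#' m <- ll_model(0.5, 0.1)
#' rate_matrix(m)
#' @export
ll_model <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly in (0, 1), got ", alpha, call. = FALSE)
  }
  if (beta <= 0 || beta >= 1) {
    stop("`beta` must lie strictly in (0, 1), got ", beta, call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "ll_model")
}

#' @export
print.ll_model <- function(x, ...) {
  cat("<ll_model> language-learning compartmental model\n")
  cat(sprintf("  alpha (learning rate)   : %g\n", x$alpha))
  cat(sprintf("  beta  (forgetting rate) : %g\n", x$beta))
  invisible(x)
}

#' Benchmark parameter cases
#'
#' The three reference parameterisations used throughout the package:
#' all share the learning rate \eqn{\alpha = 0.5} and vary the forgetting
#' rate \eqn{\beta} over 0.1, 0.5 and 0.9, moving from near-permanent
#' retention to rapid forgetting.
#'
#' @param case_id Integer 1, 2 or 3.
#' @return An \code{ll_model}.
#' @examples
#' make_case(1)
#' @export
make_case <- function(case_id) {
  if (length(case_id) != 1L || !is.numeric(case_id) ||
      is.na(case_id) || case_id != as.integer(case_id)) {
    stop("`case_id` must be a single integer in {1, 2, 3}", call. = FALSE)
  }
  beta <- switch(as.character(as.integer(case_id)),
                 "1" = 0.1, "2" = 0.5, "3" = 0.9,
                 stop("unknown case id: ", case_id, " (must be 1, 2 or 3)",
                      call. = FALSE))
  ll_model(alpha = 0.5, beta = beta)
}

#' Rate matrix of the model
#'
#' Returns the 3x3 constant-coefficient matrix A such that the system is
#' d(u,f,m)/dx = A (u,f,m). Columns sum to zero exactly (conservation of
#' total proportion) and off-diagonal entries are nonnegative (Metzler
#' structure), so trajectories started on the unit simplex stay there.
#'
#' @param model An \code{ll_model}.
#' @return A 3x3 numeric matrix with dimnames \code{c("u","f","m")}.
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "ll_model"))
  a <- model$alpha
  b <- model$beta
  bf <- b / (1 + 2 * a)   # familiar -> unknown decay rate
  bm <- b / (2 + 4 * a)   # mastered -> familiar decay rate
  # The familiar column must sum to zero exactly, not just to roundoff.
  # Build it as an exactly-cancelling triple: with s = fl(a + bf), the
  # smaller of the two outflow rates is replaced by the Sterbenz-exact
  # difference s minus the larger (a <= 1 ulp perturbation), so
  # p + (-s) + q == 0 holds in floating point in any summation order.
  s <- a + bf
  if (bf <= a) {
    p <- s - a   # f -> u rate, within 1 ulp of bf
    q <- a       # f -> m rate
  } else {
    p <- bf
    q <- s - bf
  }
  matrix(c(-a,      p,            0,
            a,      -s,           bm,
            0,       q,          -bm),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("u", "f", "m"), c("u", "f", "m")))
}

#' Right-hand side of the model ODE
#'
#' @param model An \code{ll_model}.
#' @param state Numeric vector \code{c(u, f, m)}.
#' @return Numeric vector of derivatives \code{c(du, df, dm)}; its components
#'   sum to zero to machine precision.
#' @export
ll_rhs <- function(model, state) {
  stopifnot(inherits(model, "ll_model"), is.numeric(state), length(state) == 3L)
  if (!all(is.finite(state))) {
    stop("`state` must be finite", call. = FALSE)
  }
  drop(rate_matrix(model) %*% state)
}

#' Exact trajectory via the matrix exponential
#'
#' The system is linear with constant coefficients, so the state at x is
#' expm(A x) applied to the initial state. The exponential is computed from
#' the eigendecomposition of the rate matrix (the matrix has simple
#' eigenvalues: one zero and two with negative real part), giving component
#' accuracy well below 1e-12 on the unit interval. Serves as the exact
#' oracle against which the multistep solver and the trained network are
#' judged.
#'
#' @param model An \code{ll_model}.
#' @param xs Strictly increasing numeric grid of evaluation points.
#' @param init Initial state \code{c(u, f, m)} on the unit simplex at
#'   \code{xs[1]}'s origin x = 0. Default \code{c(1, 0, 0)}: everything
#'   starts unknown.
#' @return A tibble with columns \code{x, u, f, m} and attribute
#'   \code{method = "analytic"}.
#' @examples
#' solve_analytic(make_case(1), xs = seq(0, 1, by = 0.25))
#' @export
solve_analytic <- function(model, xs = seq(0, 1, by = 0.01), init = c(1, 0, 0)) {
  stopifnot(inherits(model, "ll_model"))
  check_grid(xs)
  check_simplex(init)
  A <- rate_matrix(model)
  eg <- eigen(A)
  V <- eg$vectors
  c0 <- solve(V, init)
  st <- vapply(xs, function(x) Re(V %*% (exp(eg$values * x) * c0)),
               numeric(3))
  new_trajectory(xs, t(st), method = "analytic")
}

#' Steady state of the model
#'
#' The long-run limit of every trajectory started on the simplex: the unique
#' null-space direction of the rate matrix, normalised to sum one. In closed
#' form the detailed-balance relations give
#' \eqn{u^* = \beta f^*/(\alpha(1+2\alpha))} and
#' \eqn{m^* = \alpha(2+4\alpha) f^*/\beta}.
#'
#' @param model An \code{ll_model}.
#' @return Named numeric vector \code{c(u, f, m)}, all positive, summing to 1.
#' @examples
#' steady_state(make_case(1))
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "ll_model"))
  a <- model$alpha
  b <- model$beta
  # ratios relative to f from zeroing each compartment's flux
  u <- b / (a * (1 + 2 * a))
  m <- a * (2 + 4 * a) / b
  s <- c(u = u, f = 1, m = m)
  s / sum(s)
}

# --- internal helpers -------------------------------------------------------

check_grid <- function(xs) {
  if (length(xs) == 0L) stop("grid `xs` is empty", call. = FALSE)
  if (!is.numeric(xs) || anyNA(xs) || any(!is.finite(xs))) {
    stop("grid `xs` must be finite numeric", call. = FALSE)
  }
  if (length(xs) > 1L && any(diff(xs) <= 0)) {
    stop("grid `xs` must be strictly increasing", call. = FALSE)
  }
  invisible(xs)
}

check_simplex <- function(init, tol = 1e-9) {
  stopifnot(is.numeric(init), length(init) == 3L, all(is.finite(init)))
  if (any(init < -tol) || abs(sum(init) - 1) > tol) {
    stop("`init` must lie on the unit simplex (nonnegative, summing to 1)",
         call. = FALSE)
  }
  invisible(init)
}

new_trajectory <- function(xs, states, method) {
  out <- tibble::tibble(x = as.numeric(xs),
                        u = states[, 1], f = states[, 2], m = states[, 3])
  attr(out, "method") <- method
  out
}

#' Write a trajectory to CSV
#'
#' Full double precision, header \code{x,u,f,m}.
#'
#' @param traj A trajectory tibble (columns \code{x,u,f,m}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(all(c("x", "u", "f", "m") %in% names(traj)))
  df <- as.data.frame(traj)[, c("x", "u", "f", "m")]
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
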