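# Shared fixtures, all generated in code.

# Frozen exact states at x = 1 from an independent high-precision
# (symbolic eigendecomposition) matrix-exponential oracle, init (1, 0, 0).
exact_at_x1 <- list(
  `1` = c(0.61401155196791268098, 0.29774203927992775849, 0.08824640875215956053),
  `2` = c(0.64202240826898043538, 0.27707729558440861821, 0.08090029614661094641),
  `3` = c(0.66724502424511473994, 0.25848899093004373196, 0.07426598482484152810))

# Same oracle at x = 0.5, Case 1.
exact_case1_x05 <- c(0.78121629453037920372, 0.19259344431312467355,
                     0.02619026115649612274)

traj_states <- function(traj) as.matrix(traj[, c("u", "f", "m")])

# default 101-point Case 1 dataset with the standard split
case1_split_ds <- function(seed = 1) {
  split_dataset(build_dataset(solve_adams(make_case(1))), seed = seed)
}

# small quadratic objective for optimizer tests: mean((Xw - y)^2)
quadratic_problem <- function(seed = 42, n = 40, p = 6) {
  withr::with_seed(seed, {
    X <- cbind(1, matrix(stats::rnorm(n * (p - 1)), n))
    y <- stats::rnorm(n)
  })
  list(
    fn = function(w) {
      r <- drop(X %*% w - y)
      list(mse = mean(r^2), gradient = drop(2 * crossprod(X, r) / length(y)))
    },
    w_star = qr.solve(X, y),
    p = p)
}
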