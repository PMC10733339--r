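test_that("parameter validation rejects out-of-range rates and bad case ids", {
  expect_error(ll_model(0, 0.5), "alpha")
  expect_error(ll_model(1, 0.5), "alpha")
  expect_error(ll_model(0.5, 0), "beta")
  expect_error(ll_model(0.5, 1.2), "beta")
  expect_error(make_case(4), "unknown case id")
  expect_error(make_case("a"), "case_id")
  expect_error(make_case(1.5), "case_id")
})

test_that("benchmark cases carry the published (alpha, beta) pairs", {
  expect_equal(unclass(make_case(1))[c("alpha", "beta")],
               list(alpha = 0.5, beta = 0.1))
  expect_equal(make_case(2)$beta, 0.5)
  expect_equal(make_case(3)$beta, 0.9)
})

test_that("rate matrix has the published coefficients and Metzler structure", {
  A1 <- rate_matrix(make_case(1))
  expect_equal(unname(A1),
               matrix(c(-0.5, 0.05, 0,
                        0.5, -0.55, 0.025,
                        0, 0.5, -0.025), nrow = 3, byrow = TRUE))
  A2 <- rate_matrix(make_case(2))
  expect_equal(unname(A2),
               matrix(c(-0.5, 0.25, 0,
                        0.5, -0.75, 0.125,
                        0, 0.5, -0.125), nrow = 3, byrow = TRUE))
  for (A in list(A1, A2)) {
    expect_true(all(A[row(A) != col(A)] >= 0))
    expect_true(all(diag(A) <= 0))
  }
})

test_that("rate-matrix columns sum exactly to zero for random parameters", {
  withr::with_seed(11, {
    for (i in 1:50) {
      m <- ll_model(runif(1, 1e-6, 1 - 1e-6), runif(1, 1e-6, 1 - 1e-6))
      expect_identical(colSums(rate_matrix(m)), c(u = 0, f = 0, m = 0))
    }
  })
})

test_that("right-hand side matches direct substitution and conserves mass", {
  expect_equal(unname(ll_rhs(make_case(1), c(1, 0, 0))), c(-0.5, 0.5, 0))
  expect_equal(unname(ll_rhs(make_case(2), c(0, 1, 0))), c(0.25, -0.75, 0.5))
  withr::with_seed(12, {
    for (i in 1:20) {
      m <- ll_model(runif(1), runif(1))
      st <- runif(3)
      expect_lt(abs(sum(ll_rhs(m, st))), 1e-15)
    }
  })
  expect_error(ll_rhs(make_case(1), c(NaN, 0, 0)), "finite")
})

test_that("analytic solution is exact: identity at x = 0 and frozen oracle states", {
  for (cid in 1:3) {
    tr0 <- solve_analytic(make_case(cid), xs = 0)
    expect_equal(traj_states(tr0)[1, ], c(u = 1, f = 0, m = 0),
                 ignore_attr = TRUE)
    tr1 <- solve_analytic(make_case(cid), xs = 1)
    expect_equal(unname(traj_states(tr1)[1, ]), exact_at_x1[[as.character(cid)]],
                 tolerance = 1e-13)
  }
  tr <- solve_analytic(make_case(1), xs = 0.5)
  expect_equal(unname(traj_states(tr)[1, ]), exact_case1_x05, tolerance = 1e-13)
  expect_error(solve_analytic(make_case(1), xs = numeric(0)), "empty")
})

test_that("analytic solution agrees with an independent Pade matrix exponential", {
  skip_if_not_installed("Matrix")
  m <- make_case(2)
  A <- rate_matrix(m)
  for (x in c(0.3, 1, 5)) {
    ref <- as.numeric(Matrix::expm(A * x) %*% c(1, 0, 0))
    got <- unname(traj_states(solve_analytic(m, xs = x))[1, ])
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("analytic trajectories conserve mass and stay inside the simplex", {
  withr::with_seed(13, {
    for (i in 1:10) {
      m <- ll_model(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
      tr <- solve_analytic(m, xs = seq(0, 2, by = 0.05))
      st <- traj_states(tr)
      expect_lt(max(abs(rowSums(st) - 1)), 1e-12)
      expect_true(all(st >= -1e-12 & st <= 1 + 1e-12))
    }
  })
})

test_that("steady state is the normalised null vector and the x -> Inf limit", {
  expect_equal(unname(steady_state(make_case(1))),
               c(0.1, 1, 20) / 21.1, tolerance = 1e-12)
  expect_equal(unname(steady_state(make_case(2))),
               c(0.5, 1, 4) / 5.5, tolerance = 1e-12)
  withr::with_seed(14, {
    for (i in 1:20) {
      m <- ll_model(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
      s <- steady_state(m)
      expect_lt(max(abs(rate_matrix(m) %*% s)), 1e-12)
      expect_true(all(s > 0))
      expect_equal(sum(s), 1)
    }
  })
})

test_that("rate matrix has one zero eigenvalue and two with negative real part", {
  withr::with_seed(15, {
    for (i in 1:20) {
      m <- ll_model(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
      ev <- eigen(rate_matrix(m), only.values = TRUE)$values
      ev <- ev[order(-Re(ev))]
      expect_lt(abs(ev[1]), 1e-12)
      expect_true(all(Re(ev[2:3]) < 0))
    }
  })
})

test_that("trajectory CSV round-trips at full double precision", {
  tr <- solve_analytic(make_case(1), xs = seq(0, 1, by = 0.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("x", "u", "f", "m"))
  expect_equal(as.matrix(back), as.matrix(as.data.frame(tr)),
               tolerance = 1e-15, ignore_attr = TRUE)
})
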