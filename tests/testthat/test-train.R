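test_that("the optimiser solves a convex quadratic to the least-squares optimum", {
  qp <- quadratic_problem()
  opt <- scg_optimize(qp$fn, rep(0, qp$p), max_epochs = 200, min_gradient = 0)
  expect_lt(max(abs(opt$w - qp$w_star)), 1e-10)
})

test_that("a min-gradient stop leaves the gradient at or below the threshold", {
  qp <- quadratic_problem()
  opt <- scg_optimize(qp$fn, rep(0, qp$p), max_epochs = 500,
                      min_gradient = 1e-7)
  expect_identical(opt$stop_reason, "min_gradient")
  expect_lte(sqrt(sum(opt$gradient^2)), 1e-7)
})

test_that("scg_config validates its hyperparameters", {
  expect_error(scg_config(sigma = 0))
  expect_error(scg_config(lambda0 = -1))
  expect_error(scg_config(max_epochs = 0))
  expect_s3_class(scg_config(sigma = 7e-5), "scg_config")
})

test_that("training MSE is non-increasing over accepted steps", {
  ds <- case1_split_ds()
  fit <- train_scg(ds, scg = scg_config(max_epochs = 120, max_val_fail = 1000),
                   seed = 2)
  expect_true(all(diff(fit$record$train_mse) <= 1e-18))
})

test_that("training is reproducible bit-for-bit for a fixed seed", {
  ds <- case1_split_ds()
  a <- train_scg(ds, scg = scg_config(max_epochs = 60), seed = 5)
  b <- train_scg(ds, scg = scg_config(max_epochs = 60), seed = 5)
  expect_identical(a$record, b$record)
  expect_identical(flatten_weights(a$weights), flatten_weights(b$weights))
})

test_that("the best-validation epoch minimises validation MSE and is restored", {
  ds <- case1_split_ds()
  fit <- train_scg(ds, seed = 3)
  rec <- fit$record
  expect_equal(fit$best_val_mse, min(rec$val_mse))
  expect_equal(rec$epoch[which.min(rec$val_mse)], fit$best_epoch)
  # restored weights reproduce the recorded best-epoch metrics
  pred <- predict(fit, ds$x)
  err2 <- (as.matrix(pred[, c("u", "f", "m")]) -
           as.matrix(ds[, c("u", "f", "m")]))^2
  expect_equal(mean(err2[ds$split == "val", ]), fit$best_val_mse,
               tolerance = 1e-12)
})

test_that("a validation-failure stop fires after exactly max_val_fail failures", {
  ds <- case1_split_ds()
  fit <- train_scg(ds, scg = scg_config(max_val_fail = 4), seed = 3)
  expect_identical(fit$stop_reason, "val_fail")
  rec <- fit$record
  tail_val <- rec$val_mse[rec$epoch > fit$best_epoch]
  expect_length(tail_val, 4L)
  expect_true(all(tail_val >= fit$best_val_mse))
})

test_that("training rejects degenerate splits", {
  ds <- case1_split_ds()
  no_train <- ds[ds$split != "train", ]
  expect_error(train_scg(no_train, seed = 1), "train")
  no_val <- ds[ds$split != "val", ]
  expect_error(train_scg(no_val, seed = 1), "validation")
})

test_that("multi-restart selects the argmin restart and is deterministic", {
  ds <- case1_split_ds()
  one <- train_scg(ds, scg = scg_config(max_epochs = 80), seed = 100)
  multi1 <- train_multistart(ds, n_restarts = 1, base_seed = 100,
                             scg = scg_config(max_epochs = 80))
  expect_identical(one$record, multi1$record)
  multi <- train_multistart(ds, n_restarts = 4, base_seed = 100,
                            scg = scg_config(max_epochs = 80))
  expect_equal(multi$best_val_mse, min(multi$restarts$best_val_mse))
  expect_true(all(multi$best_val_mse <= multi$restarts$best_val_mse))
  again <- train_multistart(ds, n_restarts = 4, base_seed = 100,
                            scg = scg_config(max_epochs = 80))
  expect_identical(multi$restarts, again$restarts)
})

test_that("tidy and glance expose the training record and summary", {
  ds <- case1_split_ds()
  fit <- train_scg(ds, scg = scg_config(max_epochs = 40, max_val_fail = 1000),
                   seed = 8)
  td <- tidy(fit)
  expect_named(td, c("epoch", "train_mse", "val_mse", "test_mse", "grad_norm"))
  expect_equal(nrow(td), 41L)  # epoch 0 plus 40 accepted steps
  gl <- glance(fit)
  expect_equal(gl$best_val_mse, fit$best_val_mse)
  expect_equal(gl$epochs, 40L)
})
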