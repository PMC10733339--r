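#' Scaled conjugate gradient configuration
#'
#' Hyperparameters of Moller's scaled conjugate gradient (SCG) optimiser and
#' the stopping rules. SCG is a line-search-free conjugate gradient method:
#' curvature along the search direction is estimated by a finite difference
#' of gradients scaled by \code{sigma}, and a Levenberg-Marquardt-style
#' scalar \code{lambda} regulates the step when the curvature estimate is
#' indefinite or the quadratic model is poor.
#'
#' Defaults: \code{sigma = 5e-5} (an alternative of 7e-5 is common in
#' fitting-tool configurations), \code{lambda0 = 5e-7}, at most 1000 epochs,
#' gradient-norm floor 1e-7 (1e-8 also accepted via this argument), six
#' consecutive validation failures for early stopping, MSE goal 0.
#'
#' @param sigma Scale of the finite-difference curvature step, > 0.
#' @param lambda0 Initial trust/scale parameter, > 0.
#' @param max_epochs Maximum accepted SCG steps.
#' @param min_gradient Stop when the training gradient norm falls to or
#'   below this value.
#' @param max_val_fail Consecutive epochs with validation MSE above the
#'   running best before early stopping.
#' @param goal_mse Stop when training MSE reaches this value.
#' @return An object of class \code{scg_config}.
#' @export
scg_config <- function(sigma = 5e-5, lambda0 = 5e-7, max_epochs = 1000L,
                       min_gradient = 1e-7, max_val_fail = 6L, goal_mse = 0) {
  stopifnot(sigma > 0, lambda0 > 0, max_epochs >= 1, min_gradient >= 0,
            max_val_fail >= 1, goal_mse >= 0)
  structure(list(sigma = sigma, lambda0 = lambda0,
                 max_epochs = as.integer(max_epochs),
                 min_gradient = min_gradient,
                 max_val_fail = as.integer(max_val_fail),
                 goal_mse = goal_mse),
            class = "scg_config")
}

#' Moller's scaled conjugate gradient optimiser
#'
#' Minimises a differentiable scalar objective without line searches.
#' Curvature along the conjugate direction p is estimated by a one-sided
#' finite difference of gradients at distance \code{sigma/|p|}; the scalar
#' \code{lambda} regularises the curvature estimate (raised until the
#' estimate is positive definite and whenever the quadratic model fits the
#' objective poorly, lowered when it fits well). Steps are accepted only
#' when the objective decreases, so the objective trace over accepted steps
#' is non-increasing. The conjugate direction is restarted to steepest
#' descent every \code{length(w0)} accepted steps.
#'
#' @param fn Function of a numeric vector returning
#'   \code{list(mse = scalar, gradient = vector)}.
#' @param w0 Starting point.
#' @param sigma,lambda0 See \code{\link{scg_config}}.
#' @param max_epochs Maximum accepted steps.
#' @param min_gradient Stop when the gradient norm is at or below this.
#' @param goal Stop when the objective is at or below this.
#' @param on_epoch Optional callback \code{function(w, E, grad_norm, epoch)}
#'   run after each accepted step; returning \code{FALSE} stops the run
#'   with reason \code{"callback"}.
#' @return List with the final point \code{w}, objective \code{E}, gradient
#'   \code{gradient}, number of accepted \code{epochs} and the
#'   \code{stop_reason} (one of \code{max_epochs, min_gradient, goal,
#'   callback, stall}).
#' @export
scg_optimize <- function(fn, w0, sigma = 5e-5, lambda0 = 5e-7,
                         max_epochs = 1000L, min_gradient = 1e-7,
                         goal = 0, on_epoch = NULL) {
  w <- w0
  N <- length(w)
  lg <- fn(w)
  E <- lg$mse
  r <- -lg$gradient
  p <- r
  success <- TRUE
  lambda <- lambda0
  lambda_bar <- 0
  lambda_cap <- 1e15
  k <- 0L
  p2 <- sum(p^2)
  delta_raw <- NA_real_
  stop_reason <- "max_epochs"
  epochs <- 0L

  for (epoch in seq_len(max_epochs)) {
    gnorm <- sqrt(sum(r^2))
    if (gnorm <= min_gradient) { stop_reason <- "min_gradient"; break }
    if (E <= goal) { stop_reason <- "goal"; break }

    accepted <- FALSE
    repeat {
      if (success) {
        p2 <- sum(p^2)
        if (p2 == 0) break
        sigma_k <- sigma / sqrt(p2)
        g2 <- fn(w + sigma_k * p)$gradient
        s <- (g2 + r) / sigma_k          # (grad(w + sk p) - grad(w)) / sk
        delta_raw <- sum(p * s)
        success <- FALSE                 # consumed; recompute only after accept
      }
      delta <- delta_raw + (lambda - lambda_bar) * p2
      if (delta <= 0) {                  # make the curvature estimate positive
        lambda_bar <- 2 * (lambda - delta / p2)
        delta <- -delta + lambda * p2
        lambda <- lambda_bar
      }
      mu <- sum(p * r)
      if (mu <= 0) {                     # not a descent direction: restart
        p <- r
        success <- TRUE
        next
      }
      alpha_step <- mu / delta
      E_new <- fn(w + alpha_step * p)$mse
      Delta <- 2 * delta * (E - E_new) / mu^2   # comparison ratio
      if (is.finite(Delta) && Delta >= 0) {
        w <- w + alpha_step * p
        lg <- fn(w)
        E <- lg$mse
        r_new <- -lg$gradient
        lambda_bar <- 0
        success <- TRUE
        k <- k + 1L
        if (k %% N == 0L) {
          p <- r_new
        } else {
          beta <- (sum(r_new^2) - sum(r_new * r)) / mu
          p <- r_new + beta * p
        }
        if (Delta >= 0.75) lambda <- max(lambda * 0.5, 1e-300)
        if (Delta < 0.25) lambda <- lambda * 4
        r <- r_new
        accepted <- TRUE
        break
      } else {
        lambda_bar <- lambda
        lambda <- lambda * 4
        if (lambda > lambda_cap) break
      }
    }
    if (!accepted) { stop_reason <- "stall"; break }
    if (!is.finite(E)) stop("non-finite loss; restart advised", call. = FALSE)
    epochs <- epoch
    if (!is.null(on_epoch) &&
        isFALSE(on_epoch(w, E, sqrt(sum(lg$gradient^2)), epoch))) {
      stop_reason <- "callback"
      break
    }
  }
  list(w = w, E = E, gradient = lg$gradient, epochs = epochs,
       stop_reason = stop_reason)
}

#' Train the surrogate network with scaled conjugate gradient
#'
#' Full-batch training of the 1 -> n_hidden -> 3 log-sigmoid network on the
#' training split, with per-epoch monitoring of all three splits. Inputs
#' and targets are min-max normalised to [-1, 1] internally (the normaliser
#' is fitted on the full dataset); all recorded MSEs are on the original
#' scale. Weights are restored from the epoch with the lowest validation
#' MSE.
#'
#' One epoch is one accepted SCG step; inside an epoch the trust parameter
#' lambda is raised (by the < 0.25 comparison-ratio rule) until a step is
#' accepted. The conjugate direction is restarted to steepest descent every
#' \code{n_params} accepted steps. Stopping rules: \code{max_epochs},
#' training gradient norm at or below \code{min_gradient},
#' \code{max_val_fail} consecutive validation failures, training MSE at the
#' goal, or a stall (lambda at its cap with no acceptable step, which only
#' occurs when no descent is numerically possible).
#'
#' @param data Dataset tibble with columns \code{x, u, f, m, split} (from
#'   \code{\link{split_dataset}}).
#' @param config A \code{\link{net_config}}.
#' @param scg An \code{\link{scg_config}}.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class \code{scg_fit}: best \code{weights}, the
#'   per-epoch \code{record} tibble (\code{epoch, train_mse, val_mse,
#'   test_mse, grad_norm}), \code{stop_reason}, \code{best_epoch},
#'   \code{best_val_mse}, the \code{normalizer}, configs and \code{seed}.
#' @export
train_scg <- function(data, config = net_config(), scg = scg_config(), seed) {
  stopifnot(is.data.frame(data), "split" %in% names(data))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  idx_tr <- which(data$split == "train")
  idx_va <- which(data$split == "val")
  idx_te <- which(data$split == "test")
  if (length(idx_tr) == 0L) stop("empty training split", call. = FALSE)
  if (length(idx_va) == 0L) stop("empty validation split", call. = FALSE)

  nrm <- fit_normalizer(data)
  xs_n <- nrm_apply(data$x, "x", nrm)
  targ <- as.matrix(data[, c("u", "f", "m")])
  targ_n <- cbind(nrm_apply(targ[, 1], "u", nrm),
                  nrm_apply(targ[, 2], "f", nrm),
                  nrm_apply(targ[, 3], "m", nrm))

  w0 <- init_weights(config, seed)
  w <- flatten_weights(w0)
  lg_at <- function(wv) {
    net_loss_grad(unflatten_weights(wv, config), xs_n[idx_tr],
                  targ_n[idx_tr, , drop = FALSE])
  }
  # original-scale MSE for each split, given flat weights
  split_mse <- function(wv) {
    out_n <- net_forward(unflatten_weights(wv, config), xs_n)
    out <- cbind(nrm_invert(out_n[, 1], "u", nrm),
                 nrm_invert(out_n[, 2], "f", nrm),
                 nrm_invert(out_n[, 3], "m", nrm))
    err2 <- (out - targ)^2
    c(train = mean(err2[idx_tr, ]),
      val   = mean(err2[idx_va, ]),
      test  = if (length(idx_te)) mean(err2[idx_te, ]) else NA_real_)
  }

  lg0 <- lg_at(w)
  ms <- split_mse(w)
  rec <- list(c(epoch = 0, ms, grad_norm = sqrt(sum(lg0$gradient^2))))
  best_val <- ms[["val"]]
  best_epoch <- 0L
  best_w <- w
  val_fail <- 0L

  on_epoch <- function(wv, E, gnorm_train, epoch) {
    ms <- split_mse(wv)
    rec[[length(rec) + 1L]] <<- c(epoch = epoch, ms, grad_norm = gnorm_train)
    if (ms[["val"]] < best_val) {
      best_val <<- ms[["val"]]
      best_epoch <<- epoch
      best_w <<- wv
      val_fail <<- 0L
    } else {
      val_fail <<- val_fail + 1L
      if (val_fail >= scg$max_val_fail) return(FALSE)
    }
    TRUE
  }

  opt <- scg_optimize(lg_at, w, sigma = scg$sigma, lambda0 = scg$lambda0,
                      max_epochs = scg$max_epochs,
                      min_gradient = scg$min_gradient,
                      goal = scg$goal_mse, on_epoch = on_epoch)
  stop_reason <- if (opt$stop_reason == "callback") "val_fail" else opt$stop_reason

  record <- tibble::as_tibble(do.call(rbind, rec))
  names(record) <- c("epoch", "train_mse", "val_mse", "test_mse", "grad_norm")
  record$epoch <- as.integer(record$epoch)

  structure(list(weights = unflatten_weights(best_w, config),
                 record = record,
                 stop_reason = stop_reason,
                 best_epoch = best_epoch,
                 best_val_mse = best_val,
                 normalizer = nrm,
                 config = config,
                 scg = scg,
                 seed = as.integer(seed)),
            class = "scg_fit")
}

#' @export
print.scg_fit <- function(x, ...) {
  cat("<scg_fit> scaled-conjugate-gradient network fit\n")
  cat(sprintf("  epochs run      : %d (stop: %s)\n",
              max(x$record$epoch), x$stop_reason))
  cat(sprintf("  best val MSE    : %.6g at epoch %d\n",
              x$best_val_mse, x$best_epoch))
  cat(sprintf("  final grad norm : %.6g\n",
              x$record$grad_norm[nrow(x$record)]))
  invisible(x)
}

#' Predict compartment proportions from a fitted surrogate
#'
#' @param object An \code{scg_fit}.
#' @param x Numeric vector of evaluation points (original scale).
#' @param ... Unused.
#' @return Tibble \code{x, u, f, m} on the original scale.
#' @export
predict.scg_fit <- function(object, x, ...) {
  nrm <- object$normalizer
  out_n <- net_forward(object$weights, nrm_apply(x, "x", nrm))
  out <- tibble::tibble(x = x,
                        u = nrm_invert(out_n[, 1], "u", nrm),
                        f = nrm_invert(out_n[, 2], "f", nrm),
                        m = nrm_invert(out_n[, 3], "m", nrm))
  attr(out, "method") <- "surrogate"
  out
}

#' Multi-restart training
#'
#' Runs \code{\link{train_scg}} with seeds \code{base_seed, base_seed + 1,
#' ..., base_seed + n_restarts - 1} and returns the restart with the lowest
#' best-validation MSE. Deterministic given \code{base_seed}.
#'
#' @inheritParams train_scg
#' @param n_restarts Number of restarts, >= 1.
#' @param base_seed First seed.
#' @return The best \code{scg_fit}, with an extra element \code{restarts}: a
#'   tibble of \code{seed, best_val_mse, best_epoch, stop_reason} across all
#'   restarts.
#' @export
train_multistart <- function(data, n_restarts, base_seed,
                             config = net_config(), scg = scg_config()) {
  stopifnot(n_restarts >= 1)
  fits <- purrr::map(seq_len(n_restarts) - 1L, function(i) {
    train_scg(data, config = config, scg = scg, seed = base_seed + i)
  })
  summary <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(seed = f$seed, best_val_mse = f$best_val_mse,
                   best_epoch = f$best_epoch, stop_reason = f$stop_reason)
  })
  best <- fits[[which.min(summary$best_val_mse)]]
  best$restarts <- summary
  best
}
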