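#' Network configuration
#'
#' One-hidden-layer feedforward topology: 1 input (x), a log-sigmoid hidden
#' layer (default twelve units) and 3 linear outputs (u, f, m). With the
#' defaults the network has 12*(1+1) + 3*(12+1) = 63 free parameters.
#'
#' @param n_hidden Number of hidden units (default 12).
#' @return An object of class \code{net_config}.
#' @export
net_config <- function(n_hidden = 12L) {
  stopifnot(is.numeric(n_hidden), length(n_hidden) == 1L, n_hidden >= 1)
  structure(list(n_input = 1L, n_hidden = as.integer(n_hidden),
                 n_output = 3L), class = "net_config")
}

#' Total number of free parameters
#' @param config A \code{net_config}.
#' @export
n_params <- function(config) {
  with(config, n_hidden * (n_input + 1L) + n_output * (n_hidden + 1L))
}

#' Numerically stable log-sigmoid
#'
#' \eqn{\sigma(z) = 1/(1+e^{-z})}, branch on the sign of z so neither
#' branch exponentiates a large positive number. Monotone, bounded in
#' (0, 1), no overflow for any finite input.
#'
#' @param z Numeric vector or matrix.
#' @export
logsigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Nguyen-Widrow weight initialisation
#'
#' Hidden weights are drawn uniformly and rescaled so each hidden unit's
#' incoming weight vector has magnitude 0.7 * n_hidden^(1/n_input) over the
#' normalised [-1, 1] input range; hidden biases are spread evenly across
#' that range so the sigmoid active regions tile the interval. Output-layer
#' weights and biases are small uniform draws. Deterministic per seed; the
#' caller's RNG state is untouched.
#'
#' @param config A \code{net_config}.
#' @param seed Integer seed.
#' @return An object of class \code{mlp_weights}: matrices \code{W1}
#'   (n_hidden x n_input), \code{b1}, \code{W2} (n_output x n_hidden),
#'   \code{b2}.
#' @export
init_weights <- function(config, seed) {
  stopifnot(inherits(config, "net_config"))
  nh <- config$n_hidden
  ni <- config$n_input
  no <- config$n_output
  withr::with_seed(as.integer(seed), {
    scale <- 0.7 * nh^(1 / ni)
    W1 <- matrix(stats::runif(nh * ni, -1, 1), nrow = nh)
    norms <- sqrt(rowSums(W1^2))
    W1 <- W1 * (scale / norms)
    b1 <- if (nh == 1L) 0 else seq(-1, 1, length.out = nh) * scale * sign(W1[, 1L])
    W2 <- matrix(stats::runif(no * nh, -0.5, 0.5), nrow = no)
    b2 <- stats::runif(no, -0.5, 0.5)
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   config = config), class = "mlp_weights")
  })
}

#' Flatten / rebuild the weight vector
#'
#' Column-major concatenation in the fixed order W1, b1, W2, b2 — the view
#' the optimiser works on. Round-trip is exact.
#'
#' @param weights An \code{mlp_weights}.
#' @export
flatten_weights <- function(weights) {
  c(as.vector(weights$W1), weights$b1, as.vector(weights$W2), weights$b2)
}

#' @rdname flatten_weights
#' @param v Flat numeric vector of length \code{n_params(config)}.
#' @param config A \code{net_config}.
#' @export
unflatten_weights <- function(v, config) {
  nh <- config$n_hidden; ni <- config$n_input; no <- config$n_output
  stopifnot(length(v) == n_params(config))
  i <- 0L
  W1 <- matrix(v[i + seq_len(nh * ni)], nrow = nh); i <- i + nh * ni
  b1 <- v[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(v[i + seq_len(no * nh)], nrow = no); i <- i + no * nh
  b2 <- v[i + seq_len(no)]
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, config = config),
            class = "mlp_weights")
}

#' Forward pass
#'
#' \eqn{y = W_2 \sigma(W_1 x + b_1) + b_2}, vectorised over samples.
#'
#' @param weights An \code{mlp_weights}.
#' @param inputs Numeric vector of (normalised) inputs, length n.
#' @return n x 3 matrix of outputs.
#' @export
net_forward <- function(weights, inputs) {
  if (!all(is.finite(inputs))) stop("non-finite input", call. = FALSE)
  H <- logsigmoid(tcrossprod(matrix(inputs, ncol = 1L), weights$W1) +
                  matrix(weights$b1, nrow = length(inputs),
                         ncol = length(weights$b1), byrow = TRUE))
  tcrossprod(H, weights$W2) +
    matrix(weights$b2, nrow = length(inputs), ncol = 3L, byrow = TRUE)
}

#' Mean squared error and its exact gradient
#'
#' The loss is the mean over all samples and output channels of the squared
#' error. The gradient with respect to the flattened weight vector is
#' computed by backpropagation and is exact (validated against central
#' finite differences in the test suite).
#'
#' @param weights An \code{mlp_weights}.
#' @param inputs Length-n numeric vector.
#' @param targets n x 3 numeric matrix.
#' @return List with elements \code{mse} (scalar) and \code{gradient}
#'   (flat vector, same layout as \code{\link{flatten_weights}}).
#' @export
net_loss_grad <- function(weights, inputs, targets) {
  n <- length(inputs)
  if (!is.matrix(targets) || nrow(targets) != n || ncol(targets) != 3L) {
    stop("`targets` must be an n x 3 matrix matching `inputs`", call. = FALSE)
  }
  X <- matrix(inputs, ncol = 1L)
  H <- logsigmoid(tcrossprod(X, weights$W1) +
                  matrix(weights$b1, nrow = n, ncol = length(weights$b1),
                         byrow = TRUE))
  out <- tcrossprod(H, weights$W2) +
    matrix(weights$b2, nrow = n, ncol = 3L, byrow = TRUE)
  err <- out - targets
  mse <- mean(err^2)
  dOut <- 2 * err / (n * 3)
  gW2 <- crossprod(dOut, H)            # n_output x n_hidden
  gb2 <- colSums(dOut)
  dH <- dOut %*% weights$W2            # n x n_hidden
  dZ <- dH * H * (1 - H)
  gW1 <- crossprod(dZ, X)              # n_hidden x n_input
  gb1 <- colSums(dZ)
  list(mse = mse,
       gradient = c(as.vector(gW1), gb1, as.vector(gW2), gb2))
}
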