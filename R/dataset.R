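#' Build a supervised dataset from a trajectory
#'
#' One sample per grid point: input x, targets (u, f, m) copied verbatim
#' from the trajectory.
#'
#' @param traj A trajectory tibble with columns \code{x, u, f, m}.
#' @return A tibble \code{x, u, f, m} carrying the trajectory's provenance in
#'   attribute \code{source}.
#' @export
build_dataset <- function(traj) {
  stopifnot(is.data.frame(traj))
  if (nrow(traj) == 0L) stop("trajectory is empty", call. = FALSE)
  if (!all(c("x", "u", "f", "m") %in% names(traj))) {
    stop("trajectory must have columns x, u, f, m", call. = FALSE)
  }
  out <- tibble::as_tibble(traj[, c("x", "u", "f", "m")])
  attr(out, "source") <- attr(traj, "method") %||% "unknown"
  out
}

#' Seeded train/validation/test split
#'
#' Assigns every sample uniformly at random (without replacement) to one of
#' the three splits. Counts follow largest-remainder apportionment of the
#' ratios: at n = 101 with the default 75/13/12 ratios the counts are
#' 76/13/12. The assignment is deterministic for a fixed seed and does not
#' disturb the caller's RNG state.
#'
#' @param ds Dataset tibble from \code{\link{build_dataset}}.
#' @param ratios Positive split proportions \code{c(train, val, test)}
#'   summing to one. Default \code{c(0.75, 0.13, 0.12)}.
#' @param seed Integer RNG seed (required: the split is a logged run
#'   parameter).
#' @return \code{ds} with an added factor column \code{split} with levels
#'   \code{train, val, test}.
#' @export
split_dataset <- function(ds, ratios = c(0.75, 0.13, 0.12), seed) {
  stopifnot(is.data.frame(ds), nrow(ds) >= 3L)
  if (missing(seed)) stop("`seed` is required for a reproducible split", call. = FALSE)
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("`ratios` must be three positive numbers", call. = FALSE)
  }
  if (abs(sum(ratios) - 1) > 1e-9) {
    stop("`ratios` must sum to 1 (got ", sum(ratios), ")", call. = FALSE)
  }
  n <- nrow(ds)
  counts <- apportion_largest_remainder(n, ratios)
  labels <- rep(c("train", "val", "test"), times = counts)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  out <- ds
  out$split <- factor(labels[order(perm)], levels = c("train", "val", "test"))
  out
}

# Largest-remainder (Hamilton) apportionment of n items to the ratios.
apportion_largest_remainder <- function(n, ratios) {
  quotas <- n * ratios
  base <- floor(quotas)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quotas - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Min-max normaliser to [-1, 1]
#'
#' Fits per-channel affine maps taking the observed range of the input and
#' of each target channel onto [-1, 1] — the standard preprocessing for
#' sigmoid-network fitting. Training happens on the normalised scale;
#' every reported metric is computed after mapping predictions back to
#' original units.
#'
#' @param ds Dataset tibble with columns \code{x, u, f, m}.
#' @return An object of class \code{ll_normalizer}: per-channel \code{min}
#'   and \code{max}.
#' @export
fit_normalizer <- function(ds) {
  stopifnot(is.data.frame(ds), nrow(ds) >= 2L)
  chans <- c("x", "u", "f", "m")
  mins <- vapply(chans, function(ch) min(ds[[ch]]), numeric(1))
  maxs <- vapply(chans, function(ch) max(ds[[ch]]), numeric(1))
  flat <- maxs - mins <= 0
  if (any(flat)) {
    stop("constant channel(s): ", paste(chans[flat], collapse = ", "),
         " — cannot normalise a zero range", call. = FALSE)
  }
  structure(list(min = mins, max = maxs), class = "ll_normalizer")
}

#' @rdname fit_normalizer
#' @param v Numeric vector or matrix of values on the original scale.
#' @param channel Channel name(s): one of \code{"x","u","f","m"}, recycled
#'   across matrix columns.
#' @param spec An \code{ll_normalizer}.
#' @export
nrm_apply <- function(v, channel, spec) {
  stopifnot(inherits(spec, "ll_normalizer"))
  lo <- unname(spec$min[channel])
  hi <- unname(spec$max[channel])
  if (is.matrix(v)) {
    sweep(sweep(v, 2, lo, "-"), 2, (hi - lo) / 2, "/") - 1
  } else {
    2 * (v - lo) / (hi - lo) - 1
  }
}

#' @rdname fit_normalizer
#' @export
nrm_invert <- function(v, channel, spec) {
  stopifnot(inherits(spec, "ll_normalizer"))
  lo <- unname(spec$min[channel])
  hi <- unname(spec$max[channel])
  if (is.matrix(v)) {
    sweep(sweep(v + 1, 2, (hi - lo) / 2, "*"), 2, lo, "+")
  } else {
    (v + 1) / 2 * (hi - lo) + lo
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
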