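utils::globalVariables(c("x", "value", "class_", "compartment", "series",
                         "epoch", "mse", "split", "center", "count",
                         "target", "output", "ae"))

#' Plot an evaluation report
#'
#' The standard fitting diagnostics as ggplot2 panels.
#'
#' @param object An \code{ll_report}.
#' @param type One of \code{"fit"} (surrogate vs reference curves),
#'   \code{"ae"} (absolute-error curves, log scale), \code{"histogram"}
#'   (signed-error histogram), \code{"regression"} (output vs target),
#'   \code{"training"} (per-epoch MSE traces).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ll_report <- function(object,
                               type = c("fit", "ae", "histogram",
                                        "regression", "training"),
                               ...) {
  type <- match.arg(type)
  switch(type,
         fit = plot_fit(object),
         ae = plot_ae(object),
         histogram = plot_histogram(object),
         regression = plot_regression(object),
         training = plot_training(object$fit))
}

#' @export
autoplot.scg_fit <- function(object, ...) plot_training(object)

long_traj <- function(traj, series) {
  tidyr::pivot_longer(traj, cols = c("u", "f", "m"),
                      names_to = "compartment", values_to = "value") |>
    dplyr::mutate(series = series,
                  compartment = factor(compartment, levels = c("u", "f", "m")))
}

plot_fit <- function(report) {
  df <- dplyr::bind_rows(long_traj(report$ref, "reference"),
                         long_traj(report$pred, "surrogate"))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = value, colour = compartment,
                                   linetype = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x", y = "proportion",
                  title = sprintf("Case %d: surrogate vs reference",
                                  report$case_id)) +
    ggplot2::theme_minimal()
}

plot_ae <- function(report) {
  df <- tidyr::pivot_longer(report$ae, cols = dplyr::starts_with("ae_"),
                            names_to = "compartment", values_to = "ae",
                            names_prefix = "ae_")
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = ae, colour = compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "x", y = "absolute error",
                  title = sprintf("Case %d: absolute error", report$case_id)) +
    ggplot2::theme_minimal()
}

plot_histogram <- function(report) {
  df <- tibble::tibble(center = report$histogram$centers,
                       count = report$histogram$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = center, y = count)) +
    ggplot2::geom_col(width = diff(report$histogram$breaks)[1L] * 0.9) +
    ggplot2::labs(x = "signed error (target - output)", y = "instances",
                  title = sprintf("Case %d: error histogram", report$case_id)) +
    ggplot2::theme_minimal()
}

plot_regression <- function(report) {
  out <- as.matrix(report$pred[, c("u", "f", "m")])
  tar <- as.matrix(report$ref[, c("u", "f", "m")])
  df <- tibble::tibble(
    target = as.vector(tar), output = as.vector(out),
    compartment = factor(rep(c("u", "f", "m"), each = nrow(out)),
                         levels = c("u", "f", "m")))
  ggplot2::ggplot(df, ggplot2::aes(x = target, y = output,
                                   colour = compartment)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = sprintf("Case %d: output vs target",
                                  report$case_id)) +
    ggplot2::theme_minimal()
}

plot_training <- function(fit) {
  df <- tidyr::pivot_longer(fit$record,
                            cols = c("train_mse", "val_mse", "test_mse"),
                            names_to = "split", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = mse, colour = split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = fit$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(y = "MSE (original units)",
                  title = "Training progress (dashed: best validation)") +
    ggplot2::theme_minimal()
}
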