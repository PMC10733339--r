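#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x An \code{scg_fit}.
#' @param ... Unused.
#' @return The per-epoch record, one row per epoch: \code{epoch, train_mse,
#'   val_mse, test_mse, grad_norm}.
#' @export
tidy.scg_fit <- function(x, ...) x$record

#' @rdname tidy.scg_fit
#' @export
glance.scg_fit <- function(x, ...) {
  tibble::tibble(best_val_mse = x$best_val_mse,
                 best_epoch = x$best_epoch,
                 epochs = max(x$record$epoch),
                 final_grad_norm = x$record$grad_norm[nrow(x$record)],
                 stop_reason = x$stop_reason,
                 seed = x$seed)
}

#' Tidy an evaluation report
#'
#' @param x An \code{ll_report}.
#' @param ... Unused.
#' @return Per-class metrics: absolute-error maxima/means joined with the
#'   regression diagnostics (the pooled regression row has NA error
#'   columns).
#' @export
tidy.ll_report <- function(x, ...) {
  dplyr::left_join(x$regression, x$ae_summary, by = "class")
}

#' @rdname tidy.ll_report
#' @export
glance.ll_report <- function(x, ...) {
  tibble::tibble(case_id = x$case_id,
                 best_val_mse = x$best_val_mse,
                 best_epoch = x$best_epoch,
                 train_mse = x$mse[["train"]],
                 val_mse = x$mse[["val"]],
                 test_mse = x$mse[["test"]],
                 final_grad_norm = x$final_grad_norm,
                 max_ae_u = x$ae_summary$max_ae[1L],
                 max_ae_f = x$ae_summary$max_ae[2L],
                 max_ae_m = x$ae_summary$max_ae[3L],
                 r_squared_pooled =
                   x$regression$r_squared[x$regression$class == "pooled"],
                 stop_reason = x$stop_reason,
                 seed = x$seed)
}

#' @rdname tidy.ll_report
#' @export
augment.ll_report <- function(x, ...) {
  dplyr::bind_cols(
    x$ref,
    tibble::tibble(u_pred = x$pred$u, f_pred = x$pred$f, m_pred = x$pred$m,
                   ae_u = x$ae$ae_u, ae_f = x$ae$ae_f, ae_m = x$ae$ae_m))
}
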