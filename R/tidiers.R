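#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' `tidy()` returns one row per repetition (kappa) or, with
#' `per_class = TRUE`, the per-class recall/precision/F1 (pooled and
#' repetition-mean). `glance()` returns a one-row summary.
#'
#' @param x an `eval_report` from [cross_validate()].
#' @param per_class return per-class metrics instead of per-repetition
#'   kappas.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.eval_report <- function(x, per_class = FALSE, ...) {
  if (per_class) {
    pooled <- dplyr::mutate(x$per_class_pooled, aggregation = "pooled")
    repm <- dplyr::mutate(x$per_class_rep_mean, aggregation = "rep_mean")
    return(dplyr::bind_rows(pooled, repm))
  }
  tibble::tibble(repetition = seq_along(x$kappa), kappa = x$kappa)
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(kappa_mean = x$kappa_mean, kappa_sd = x$kappa_sd,
                 ci_lower = x$kappa_ci[["lower"]],
                 ci_upper = x$kappa_ci[["upper"]],
                 reps = length(x$kappa),
                 folds = x$settings$folds %||% NA_integer_,
                 metric = x$settings$metric %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot methods for result objects
#'
#' `autoplot.roc_result()` draws the ROC curve with its AUC;
#' `autoplot.eval_report()` shows per-repetition kappas;
#' `autoplot.diagnosis_result()` shows the novelty-score distribution split
#' by the detected status, with the decision threshold marked.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_result
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$kappa)) +
    ggplot2::geom_boxplot(width = 0.3, fill = "#d1e5f0") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Cohen's kappa",
                  title = sprintf("Cross-validated kappa: %.3f +/- %.3f",
                                  object$kappa_mean, object$kappa_sd)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_result
#' @export
autoplot.diagnosis_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mns, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(healthy = "#67a9cf",
                                          diseased = "#ef8a62")) +
    ggplot2::labs(x = "Microbiome novelty score", y = "Samples",
                  fill = "Detected status") +
    ggplot2::theme_minimal()
}
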