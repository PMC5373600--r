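#' Tidy a confusion matrix
#'
#' @param x A [confusion_matrix()].
#' @param digits Passed to [confusion_metrics()].
#' @param ... Unused.
#' @return A one-row tibble of counts and percentage metrics.
#' @exportS3Method generics::tidy
tidy.confusion_matrix <- function(x, digits = NULL, ...) {
  confusion_metrics(x, digits = digits)
}

#' Tidy an odds-ratio result
#'
#' @param x An [odds_ratio()].
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `conf.level`, the four counts, and `defined`.
#' @exportS3Method generics::tidy
tidy.odds_ratio <- function(x, ...) {
  tibble(
    estimate = x$or, conf.low = x$ci_low, conf.high = x$ci_high,
    conf.level = x$conf_level,
    exposed_case = unname(x$counts["a"]),
    exposed_control = unname(x$counts["b"]),
    ref_case = unname(x$counts["c"]),
    ref_control = unname(x$counts["d"]),
    defined = x$defined
  )
}

#' Tidy an empirical ROC curve
#'
#' @param x A [roc_empirical()] object.
#' @param ... Unused.
#' @return The curve's points: `threshold`, `sensitivity`, `fpr`.
#' @exportS3Method generics::tidy
tidy.dwidx_roc <- function(x, ...) x$points

#' @rdname tidy.dwidx_roc
#' @exportS3Method generics::glance
glance.dwidx_roc <- function(x, ...) {
  tibble(auc = x$auc, se_auc = x$se_auc,
         n_pos = x$n_pos, n_neg = x$n_neg, direction = x$direction)
}

#' Tidy a cohort evaluation
#'
#' `tidy()` returns one row per analysis with the percentage metrics and
#' AUC; `glance()` one row with the cohort-level accounting.
#'
#' @param x A [evaluate_cohort()] result.
#' @param digits Optional rounding for the percentage metrics.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dwi_evaluation <- function(x, digits = NULL, ...) {
  purrr::imap_dfr(x$analyses, function(a, name) {
    m <- confusion_metrics(a$cm, digits = digits)
    m$analysis <- name
    m$auc <- if (!is.null(a$roc)) a$roc$auc else NA_real_
    m$se_auc <- if (!is.null(a$roc)) a$roc$se_auc else NA_real_
    m$n <- a$cm$tp + a$cm$fp + a$cm$fn + a$cm$tn
    dplyr::select(m, "analysis", "n", "sensitivity", "specificity",
                  "ppv", "npv", "accuracy", "auc", "se_auc",
                  "tp", "fp", "fn", "tn")
  })
}

#' @rdname tidy.dwi_evaluation
#' @exportS3Method generics::glance
glance.dwi_evaluation <- function(x, ...) {
  tibble(
    n_total = x$n_total, n_visible = x$n_visible,
    detection_rate = x$detection_rate, cutoff = x$cutoff,
    auc_qual = x$analyses$qual$roc$auc %||% NA_real_,
    auc_quant = x$analyses$quant$roc$auc %||% NA_real_,
    auc_dwi_combined = x$analyses$dwi_combined$roc$auc %||% NA_real_,
    auc_dce = x$analyses$dce$roc$auc %||% NA_real_,
    auc_dce_adc = x$analyses$dce_adc$roc$auc %||% NA_real_
  )
}

#' Plot an empirical ROC curve
#'
#' @param object A [roc_empirical()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dwidx_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (SE %.3f)", object$auc, object$se_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curves of a cohort evaluation
#'
#' Overlays the ROC curves of the five analyses.
#'
#' @param object A [evaluate_cohort()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dwi_evaluation <- function(object, ...) {
  pts <- purrr::imap_dfr(object$analyses, function(a, name) {
    if (is.null(a$roc)) return(NULL)
    out <- a$roc$points
    out$analysis <- sprintf("%s (AUC %.3f)", name, a$roc$auc)
    out
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity,
                                    colour = .data$analysis)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
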