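#' Evaluate the five diagnostic readings on a cohort
#'
#' Runs the full pipeline on a lesion table and summarises the
#' diagnostic performance of the five analyses:
#'
#' 1. `qual` — qualitative DWI (score >= 2 positive); ROC on the
#'    three-level score, with the AUC of the binarized call also
#'    reported.
#' 2. `quant` — quantitative DWI (ADC < cutoff positive); ROC on ADC.
#' 3. `dwi_combined` — score + ADC combination ([combine_dwi()]).
#' 4. `dce` — DCE-MRI alone (BI-RADS >= 4 positive); ROC on the
#'    category.
#' 5. `dce_adc` — BI-RADS + ADC combination ([combine_dce()]).
#'
#' DWI analyses (1–3) are computed on the DWI-visible lesions only;
#' DCE analyses (4–5) on the full cohort, invisible lesions included.
#' The combination analysis is additionally stratified by lesion size at
#' 1 cm (boundary lesions in the `<= 1 cm` group), with a chi-square
#' comparison of stratum sensitivities and a Hanley-McNeil z-test of the
#' stratum AUCs.
#'
#' @param lesions A lesion table.
#' @param cutoff ADC positivity cutoff in 10^-3 mm^2/s; default 1.0.
#' @param risk_table A risk lexicon, by default [default_risk_table()].
#' @return An object of class `"dwi_evaluation"` with elements
#'   `analyses` (per-analysis confusion matrix, metrics and ROC),
#'   `size_strata`, `detection_rate`, `n_total`, `n_visible`, `cutoff`.
#'   Use [tidy()] for a long metric table, [glance()] for the headline
#'   AUCs, [autoplot()] for the ROC overlay.
#' @export
#' @examples
#' ev <- evaluate_cohort(simulate_cohort(144, seed = 11))
#' glance(ev)
evaluate_cohort <- function(lesions, cutoff = 1.0,
                            risk_table = default_risk_table()) {
  lesions <- classify_lesions(lesions, cutoff = cutoff,
                              risk_table = risk_table)
  vis <- lesions[lesions$dwi_visible, ]
  truth_vis <- vis$pathology == "malignant"
  truth_all <- lesions$pathology == "malignant"

  one <- function(truth, call, scores, direction) {
    cm <- confusion_matrix(truth, call)
    roc <- if (length(unique(scores[!is.na(scores)])) > 1 &&
               sum(truth) > 0 && sum(!truth) > 0) {
      roc_empirical(scores, truth, direction)
    } else NULL
    list(cm = cm, metrics = confusion_metrics(cm), roc = roc)
  }

  analyses <- list(
    qual = one(truth_vis, vis$qual_positive, vis$qual_score,
               "higher_is_positive"),
    quant = one(truth_vis, vis$adc_positive, vis$adc,
                "lower_is_positive"),
    dwi_combined = one(truth_vis, vis$dwi_combined_positive,
                       as.numeric(vis$dwi_combined_positive),
                       "higher_is_positive"),
    dce = one(truth_all, lesions$dce_positive, lesions$birads,
              "higher_is_positive"),
    dce_adc = one(truth_all, lesions$dce_adc_positive,
                  as.numeric(lesions$dce_adc_positive),
                  "higher_is_positive")
  )
  # the binarized qualitative AUC alongside the three-level one
  if (sum(truth_vis) > 0 && sum(!truth_vis) > 0 &&
      length(unique(vis$qual_positive)) > 1) {
    analyses$qual$roc_binary <- roc_empirical(
      as.numeric(vis$qual_positive), truth_vis, "higher_is_positive")
  }

  strata <- lapply(
    list(small = vis$size_cm <= 1, large = vis$size_cm > 1),
    function(in_stratum) {
      sub <- vis[in_stratum, ]
      if (nrow(sub) == 0) return(NULL)
      truth <- sub$pathology == "malignant"
      cm <- confusion_matrix(truth, sub$dwi_combined_positive)
      roc <- if (sum(truth) > 0 && sum(!truth) > 0 &&
                 length(unique(sub$dwi_combined_positive)) > 1) {
        roc_empirical(as.numeric(sub$dwi_combined_positive), truth,
                      "higher_is_positive")
      } else NULL
      list(cm = cm, metrics = confusion_metrics(cm), roc = roc, n = nrow(sub))
    })
  comparison <- NULL
  if (!is.null(strata$small) && !is.null(strata$large)) {
    cm_s <- strata$small$cm; cm_l <- strata$large$cm
    sens_tab <- matrix(c(cm_s$tp, cm_s$fn, cm_l$tp, cm_l$fn), 2, 2)
    sens_p <- if (all(rowSums(sens_tab) > 0) && all(colSums(sens_tab) > 0)) {
      tryCatch(stats::chisq.test(sens_tab)$p.value, warning = function(w)
        suppressWarnings(stats::chisq.test(sens_tab)$p.value))
    } else NA_real_
    auc_cmp <- if (!is.null(strata$small$roc) && !is.null(strata$large$roc)) {
      compare_auc(strata$small$roc, strata$large$roc)
    } else NULL
    comparison <- list(sensitivity_p = sens_p, auc_comparison = auc_cmp)
  }

  structure(
    list(analyses = analyses,
         size_strata = c(strata, list(comparison = comparison)),
         detection_rate = 100 * nrow(vis) / nrow(lesions),
         n_total = nrow(lesions), n_visible = nrow(vis), cutoff = cutoff),
    class = "dwi_evaluation"
  )
}

#' @export
print.dwi_evaluation <- function(x, ...) {
  cat(sprintf(
    "DWI/DCE diagnostic evaluation: %d lesions (%d visible on DWI, detection rate %.1f%%), ADC cutoff %.2f\n\n",
    x$n_total, x$n_visible, x$detection_rate, x$cutoff))
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}
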