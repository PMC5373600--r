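#' Combine the qualitative score with the ADC value
#'
#' The combination reading reclassifies lesions scored 1 or 2 by their
#' ADC alone — positive iff ADC is strictly below the cutoff — while
#' score-3 lesions are called malignant regardless of ADC. The default
#' cutoff of 1.0 (10^-3 mm^2/s) is the Youden-optimal ADC threshold on
#' the reference cohort. Ties (`adc == cutoff`) are negative: the
#' dichotomy partitions as `< cutoff` vs `>= cutoff`.
#'
#' @param score Integer vector of qualitative scores in \{1, 2, 3\}.
#' @param adc Numeric vector of per-lesion ADC values (> 0).
#' @param cutoff ADC positivity cutoff, 10^-3 mm^2/s.
#' @return Logical vector: positive for malignancy.
#' @export
#' @examples
#' combine_dwi(c(1, 2, 3), c(0.9, 1.2, 1.2))
combine_dwi <- function(score, adc, cutoff = 1.0) {
  if (any(!score %in% c(1L, 2L, 3L))) {
    abort("qualitative score must be 1, 2 or 3", class = "dwidx_domain_error")
  }
  if (cutoff <= 0) abort("cutoff must be positive", class = "dwidx_domain_error")
  score == 3L | adc < cutoff
}

#' Combine the DCE-MRI BI-RADS category with the ADC value
#'
#' The DCE-MRI analogue of [combine_dwi()]: category 5 lesions stay
#' positive and categories 1–2 stay negative regardless of ADC, while
#' categories 3 and 4 are reclassified by the ADC dichotomy (positive iff
#' ADC < cutoff). Lesions invisible on DWI have no ADC; they keep the
#' DCE-alone call (positive iff category >= 4).
#'
#' @param birads Integer vector of BI-RADS categories 1–5.
#' @param adc Numeric ADC vector; `NA` for DWI-invisible lesions.
#' @inheritParams combine_dwi
#' @return Logical vector: positive for malignancy.
#' @export
#' @examples
#' combine_dce(c(3, 4, 5), c(0.8, 1.3, 1.2))
combine_dce <- function(birads, adc, cutoff = 1.0) {
  if (any(!birads %in% 1:5)) {
    abort("birads must be an integer in 1..5", class = "dwidx_domain_error")
  }
  if (cutoff <= 0) abort("cutoff must be positive", class = "dwidx_domain_error")
  dplyr::case_when(
    birads <= 2L ~ FALSE,
    birads == 5L ~ TRUE,
    is.na(adc)   ~ birads >= 4L,
    .default = adc < cutoff
  )
}

#' Classify a cohort under all five readings
#'
#' Appends to a lesion table the per-lesion calls of the five analyses:
#' `qual_score` (1–3) and `qual_positive` (qualitative DWI),
#' `adc_positive` (quantitative DWI), `dwi_combined_positive`
#' (score + ADC combination), `dce_positive` (BI-RADS >= 4) and
#' `dce_adc_positive` (BI-RADS + ADC combination). DWI-based columns are
#' `NA` for invisible lesions; the DCE-based columns are defined for the
#' whole cohort.
#'
#' @param lesions A lesion table.
#' @inheritParams combine_dwi
#' @param risk_table A risk lexicon, by default [default_risk_table()].
#' @return The lesion tibble with the six call columns appended.
#' @export
#' @examples
#' classify_lesions(simulate_cohort(20, seed = 7))
classify_lesions <- function(lesions, cutoff = 1.0,
                             risk_table = default_risk_table()) {
  lesions <- as_lesion_tbl(lesions)
  parts <- split_visible(lesions)
  scored <- score_lesions(parts$visible, risk_table)
  i <- match(lesions$lesion_id, scored$lesion_id)
  lesions$qual_score <- scored$qual_score[i]
  vis <- lesions$dwi_visible
  lesions$qual_positive <- NA
  lesions$qual_positive[vis] <- qual_positive(lesions$qual_score[vis])
  lesions$adc_positive <- ifelse(vis, lesions$adc < cutoff, NA)
  lesions$dwi_combined_positive <- NA
  lesions$dwi_combined_positive[vis] <-
    combine_dwi(lesions$qual_score[vis], lesions$adc[vis], cutoff)
  lesions$dce_positive <- lesions$birads >= 4L
  lesions$dce_adc_positive <- combine_dce(lesions$birads, lesions$adc, cutoff)
  lesions
}

#' Cross-tabulate an ordinal reading against the ADC dichotomy
#'
#' Counts lesions per (level, ADC < cutoff) cell with row percentages —
#' the table used to show how many lesions each combination rule upgrades
#' or downgrades.
#'
#' @param level Ordinal labels (qualitative scores or BI-RADS
#'   categories).
#' @param adc_low Logical: ADC strictly below the cutoff.
#' @return A tibble with one row per level: `n_adc_low`, `pct_adc_low`,
#'   `n_adc_high`, `pct_adc_high`, `total`.
#' @export
#' @examples
#' cross_table(rep(1:3, c(4, 6, 10)), rep(c(TRUE, FALSE), 10))
cross_table <- function(level, adc_low) {
  if (length(level) != length(adc_low)) {
    abort("level and adc_low must have equal length",
          class = "dwidx_domain_error")
  }
  tibble(level = level, adc_low = adc_low) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      n_adc_low = sum(.data$adc_low),
      n_adc_high = sum(!.data$adc_low),
      total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_adc_low = 100 * .data$n_adc_low / .data$total,
      pct_adc_high = 100 * .data$n_adc_high / .data$total
    ) |>
    dplyr::select("level", "n_adc_low", "pct_adc_low",
                  "n_adc_high", "pct_adc_high", "total")
}
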