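#' Engineered reference cohort
#'
#' A deterministic 144-lesion cohort whose marginal counts match the
#' reference breast-lesion cohort used throughout the documentation:
#' 112 malignant and 32 benign lesions, 3 benign lesions invisible on
#' DWI (detection rate 141/144 = 97.9%), per-class lesion-type,
#' descriptor, ADC-dichotomy, size-stratum and BI-RADS counts as
#' published for that cohort. Columns are assigned independently, so
#' *joint* distributions (e.g. score-by-ADC cells) are not calibrated —
#' use it to check marginal accounting, not cross-tables. ADC values are
#' placed at 0.80/0.85 (below the 1.0 cutoff) and 1.20 (above).
#'
#' Two of the published per-class mass descriptor columns sum to one
#' more/less than the lesion-type totals; the cohort reconciles this by
#' moving a single lesion into the irregular category of each, keeping
#' the type totals (22 benign / 97 malignant masses) exact.
#'
#' @return A validated 144-row lesion tibble.
#' @export
#' @examples
#' detection_rate(example_cohort())
example_cohort <- function() {
  ben_vis <- tibble(
    pathology = "benign",
    dwi_visible = TRUE,
    lesion_type = rep(c("mass", "nonmass"), c(22, 7)),
    shape = c(rep(c("oval", "round", "irregular"), c(12, 1, 9)),
              rep(NA, 7)),
    margin = c(rep(c("circumscribed", "irregular"), c(9, 13)), rep(NA, 7)),
    distribution = c(rep(NA, 22), rep("focal", 7)),
    internal_pattern = rep(c("homogeneous", "heterogeneous"), c(21, 8)),
    adc = rep(c(0.85, 1.20), c(6, 23)),
    size_cm = rep(c(0.8, 1.7), c(23, 6))
  )
  ben_inv <- tibble(
    pathology = "benign", dwi_visible = FALSE,
    lesion_type = NA_character_, shape = NA_character_,
    margin = NA_character_, distribution = NA_character_,
    internal_pattern = NA_character_, adc = NA_real_,
    size_cm = c(1.5, 0.6, 0.4)
  )
  mal <- tibble(
    pathology = "malignant",
    dwi_visible = TRUE,
    lesion_type = rep(c("mass", "nonmass"), c(97, 15)),
    shape = c(rep(c("oval", "round", "irregular"), c(11, 4, 82)),
              rep(NA, 15)),
    margin = c(rep(c("circumscribed", "irregular", "spiculated"),
                   c(6, 74, 17)), rep(NA, 15)),
    distribution = c(rep(NA, 97),
                     rep(c("focal", "linear", "segmental"), c(3, 2, 10))),
    internal_pattern = rep(c("homogeneous", "heterogeneous", "rim"),
                           c(18, 69, 25)),
    adc = rep(c(0.80, 1.20), c(86, 26)),
    size_cm = rep(c(0.8, 2.0), c(20, 92))
  )
  cohort <- dplyr::bind_rows(ben_vis, ben_inv, mal)
  cohort$birads <- c(rep(c(3L, 4L, 5L), c(11, 18, 3)),
                     rep(c(3L, 4L, 5L), c(1, 10, 101)))
  cohort$lesion_id <- sprintf("R%03d", seq_len(nrow(cohort)))
  as_lesion_tbl(cohort)
}

#' Engineered score-by-ADC table
#'
#' The per-lesion qualitative scores and ADC dichotomy of the reference
#' cohort's published cross-table: 21 score-1 lesions (7 below the
#' cutoff), 32 score-2 (17 below) and 88 score-3 (68 below; 22.73%
#' at or above). Useful with [cross_table()] and for exercising the
#' combination rule's upgrade/downgrade accounting.
#'
#' @return A 141-row tibble with columns `score` and `adc_low`.
#' @export
#' @examples
#' cross_table(example_score_adc()$score, example_score_adc()$adc_low)
example_score_adc <- function() {
  tibble(
    score = rep(c(1L, 2L, 3L), c(21, 32, 88)),
    adc_low = c(rep(c(TRUE, FALSE), c(7, 14)),
                rep(c(TRUE, FALSE), c(17, 15)),
                rep(c(TRUE, FALSE), c(68, 20)))
  )
}
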