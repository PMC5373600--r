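#' Qualitative three-level DWI confidence score
#'
#' Scores each visible lesion on the 1/2/3 confidence scale from its
#' descriptor risk classes:
#'
#' * **3** (probably malignant) — at least one *major* finding, for either
#'   lesion type.
#' * **2** (indeterminate) — no major finding, and at least two
#'   *intermediate* findings for a mass, or at least one for a non-mass
#'   lesion.
#' * **1** (probably benign) — otherwise: all findings minor, or a mass
#'   with a single intermediate finding.
#'
#' A score of 1 is read as negative for malignancy; scores 2 and 3 as
#' positive (see [qual_positive()]).
#'
#' @param lesions A lesion table; all rows must be DWI-visible.
#' @param risk_table A risk lexicon, by default [default_risk_table()].
#' @return The lesion tibble with integer column `qual_score` appended.
#' @export
#' @examples
#' cohort <- split_visible(simulate_cohort(50, seed = 1))$visible
#' dplyr::count(score_lesions(cohort), qual_score)
score_lesions <- function(lesions, risk_table = default_risk_table()) {
  lesions <- as_lesion_tbl(lesions)
  classes <- risk_classes(lesions, risk_table)
  counts <- classes |>
    dplyr::count(.data$lesion_id, .data$risk) |>
    tidyr::pivot_wider(names_from = "risk", values_from = "n",
                       values_fill = 0L)
  for (lev in c("minor", "intermediate", "major")) {
    if (is.null(counts[[lev]])) counts[[lev]] <- 0L
  }
  i <- match(lesions$lesion_id, counts$lesion_id)
  n_major <- counts$major[i]
  n_inter <- counts$intermediate[i]
  need_inter <- ifelse(lesions$lesion_type == "mass", 2L, 1L)
  lesions$qual_score <- ifelse(n_major >= 1L, 3L,
                        ifelse(n_inter >= need_inter, 2L, 1L))
  lesions
}

#' Binary call from the qualitative score
#'
#' Score 1 is negative; scores 2 and 3 are positive for malignancy.
#'
#' @param score Integer vector of scores in \{1, 2, 3\}.
#' @return Logical vector.
#' @export
qual_positive <- function(score) {
  if (any(!score %in% c(1L, 2L, 3L))) {
    abort("qualitative score must be 1, 2 or 3", class = "dwidx_domain_error")
  }
  score >= 2L
}
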