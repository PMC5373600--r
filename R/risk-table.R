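#' Malignancy-risk lexicon for DWI morphological descriptors
#'
#' Each morphological descriptor value observed on DWI carries an
#' estimated malignancy risk class: minor, intermediate or major. The
#' default lexicon is:
#'
#' | descriptor | minor | intermediate | major |
#' |---|---|---|---|
#' | shape (mass) | oval | round, irregular | — |
#' | margin (mass) | circumscribed | irregular | spiculated |
#' | distribution (non-mass) | focal | linear | segmental |
#' | internal pattern (both) | homogeneous | heterogeneous | rim sign |
#'
#' The table is injectable everywhere it is consumed, so lexicon variants
#' can be scored without changing code.
#'
#' @return A tibble with columns `descriptor`, `value`, `risk`.
#' @export
#' @examples
#' default_risk_table()
default_risk_table <- function() {
  tibble(
    descriptor = c(
      rep("shape", 3), rep("margin", 3),
      rep("distribution", 3), rep("internal_pattern", 3)
    ),
    value = c(
      "oval", "round", "irregular",
      "circumscribed", "irregular", "spiculated",
      "focal", "linear", "segmental",
      "homogeneous", "heterogeneous", "rim"
    ),
    risk = c(
      "minor", "intermediate", "intermediate",
      "minor", "intermediate", "major",
      "minor", "intermediate", "major",
      "minor", "intermediate", "major"
    )
  )
}

validate_risk_table <- function(risk_table) {
  risk_table <- as_tibble(risk_table)
  need <- c("descriptor", "value", "risk")
  if (!all(need %in% names(risk_table))) {
    abort("risk table needs columns descriptor, value, risk",
          class = "dwidx_schema_error")
  }
  if (!all(risk_table$risk %in% c("minor", "intermediate", "major"))) {
    abort("risk must be minor, intermediate or major",
          class = "dwidx_validation_error")
  }
  risk_table
}

risk_lookup <- function(descriptor, value, risk_table) {
  key <- paste(risk_table$descriptor, risk_table$value)
  out <- risk_table$risk[match(paste(descriptor, value), key)]
  if (anyNA(out[!is.na(value)])) {
    bad <- which(is.na(out) & !is.na(value))[1]
    abort(sprintf("no risk class for %s = '%s'",
                  descriptor[bad], value[bad]),
          class = "dwidx_validation_error")
  }
  out
}

#' Risk classes of a lesion's descriptors
#'
#' Maps each recorded morphological descriptor of every visible lesion to
#' its malignancy-risk class. Mass lesions contribute three entries
#' (shape, margin, internal pattern); non-mass lesions contribute two
#' (distribution, internal pattern).
#'
#' @param lesions A lesion table; all rows must be DWI-visible.
#' @param risk_table A risk lexicon, by default [default_risk_table()].
#' @return A tibble with columns `lesion_id`, `descriptor`, `value`,
#'   `risk`, one row per (lesion, descriptor).
#' @export
risk_classes <- function(lesions, risk_table = default_risk_table()) {
  lesions <- as_lesion_tbl(lesions)
  risk_table <- validate_risk_table(risk_table)
  if (any(!lesions$dwi_visible)) {
    abort("risk classes are undefined for lesions not visible on DWI",
          class = "dwidx_domain_error")
  }
  long <- tidyr::pivot_longer(
    lesions[c("lesion_id", "shape", "margin", "distribution",
              "internal_pattern")],
    cols = -"lesion_id", names_to = "descriptor", values_to = "value",
    values_drop_na = TRUE
  )
  long$risk <- risk_lookup(long$descriptor, long$value, risk_table)
  long
}
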