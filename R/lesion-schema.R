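#' Lesion table schema
#'
#' A lesion table holds one row per pathologically verified breast lesion,
#' with the columns used throughout the package:
#'
#' * `lesion_id` — character, unique identifier.
#' * `pathology` — `"benign"` or `"malignant"` (the reference standard).
#' * `dwi_visible` — logical; whether the lesion is visible on the
#'   diffusion-weighted images. Invisible lesions are excluded from all
#'   DWI analyses (they are counted as negative DWI calls) but keep their
#'   BI-RADS category for DCE-MRI analyses.
#' * `lesion_type` — `"mass"` or `"nonmass"`; `NA` when not visible.
#' * `shape` — mass only: `"oval"`, `"round"`, `"irregular"`.
#' * `margin` — mass only: `"circumscribed"`, `"irregular"`, `"spiculated"`.
#' * `distribution` — non-mass only: `"focal"`, `"linear"`, `"segmental"`.
#' * `internal_pattern` — both types: `"homogeneous"`, `"heterogeneous"`,
#'   `"rim"` (the high-signal rim sign).
#' * `adc` — apparent diffusion coefficient in 10^-3 mm^2/s, in (0, 4];
#'   `NA` exactly when the lesion is not visible.
#' * `size_cm` — lesion size in cm, > 0.
#' * `birads` — integer BI-RADS category 1–5 from the DCE-MRI reading.
#'
#' @name lesion-schema
NULL

lesion_columns <- c(
  "lesion_id", "pathology", "dwi_visible", "lesion_type", "shape",
  "margin", "distribution", "internal_pattern", "adc", "size_cm", "birads"
)

lesion_levels <- list(
  pathology        = c("benign", "malignant"),
  lesion_type      = c("mass", "nonmass"),
  shape            = c("oval", "round", "irregular"),
  margin           = c("circumscribed", "irregular", "spiculated"),
  distribution     = c("focal", "linear", "segmental"),
  internal_pattern = c("homogeneous", "heterogeneous", "rim")
)

#' Validate a lesion table
#'
#' Checks a data frame against the lesion schema (see [lesion-schema]) and
#' returns it as a tibble with canonical column order and types. Row order
#' is preserved. Structural problems (missing columns) raise a schema
#' error; per-row problems (invalid factor level, ADC recorded for an
#' invisible lesion, descriptors on the wrong lesion type) raise an error
#' naming the offending rows.
#'
#' @param lesions A data frame with the lesion-schema columns
#'   (case-insensitive names).
#' @return A validated tibble with columns in schema order.
#' @export
#' @examples
#' as_lesion_tbl(simulate_cohort(20, seed = 1))
as_lesion_tbl <- function(lesions) {
  df <- as_tibble(lesions)
  names(df) <- tolower(names(df))
  missing <- setdiff(lesion_columns, names(df))
  if (length(missing) > 0) {
    abort(
      paste0("lesion table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "dwidx_schema_error"
    )
  }
  df <- df[lesion_columns]
  df$lesion_id <- as.character(df$lesion_id)
  df$dwi_visible <- as.logical(df$dwi_visible)
  df$adc <- as.numeric(df$adc)
  df$size_cm <- as.numeric(df$size_cm)
  df$birads <- as.integer(df$birads)
  for (col in names(lesion_levels)) {
    val <- as.character(df[[col]])
    val[!is.na(val) & val == ""] <- NA_character_
    bad <- which(!is.na(val) & !(val %in% lesion_levels[[col]]))
    if (length(bad) > 0) {
      abort(
        sprintf("invalid value '%s' in column '%s' at row %d",
                val[bad[1]], col, bad[1]),
        class = "dwidx_validation_error"
      )
    }
    df[[col]] <- val
  }
  fail <- function(rows, msg) {
    if (length(rows) > 0) {
      abort(sprintf("%s (row %s)", msg,
                    paste(utils::head(rows, 5), collapse = ", ")),
            class = "dwidx_validation_error")
    }
  }
  fail(which(is.na(df$pathology)), "pathology is required")
  fail(which(is.na(df$dwi_visible)), "dwi_visible is required")
  fail(which(is.na(df$size_cm) | df$size_cm <= 0), "size_cm must be > 0")
  fail(which(is.na(df$birads) | df$birads < 1L | df$birads > 5L),
       "birads must be an integer in 1..5")

  vis <- df$dwi_visible
  fail(which(vis & is.na(df$lesion_type)),
       "visible lesions must have a lesion_type")
  fail(which(!vis & (!is.na(df$lesion_type) | !is.na(df$shape) |
                     !is.na(df$margin) | !is.na(df$distribution) |
                     !is.na(df$internal_pattern))),
       "invisible lesions must not carry descriptors")
  fail(which(!vis & !is.na(df$adc)),
       "invisible lesions must not carry an ADC value")
  fail(which(vis & (is.na(df$adc) | df$adc <= 0 | df$adc > 4)),
       "visible lesions must have adc in (0, 4]")

  mass <- vis & !is.na(df$lesion_type) & df$lesion_type == "mass"
  nonmass <- vis & !is.na(df$lesion_type) & df$lesion_type == "nonmass"
  fail(which(mass & (is.na(df$shape) | is.na(df$margin))),
       "mass lesions must have shape and margin")
  fail(which(mass & !is.na(df$distribution)),
       "mass lesions must not have a distribution")
  fail(which(nonmass & is.na(df$distribution)),
       "nonmass lesions must have a distribution")
  fail(which(nonmass & (!is.na(df$shape) | !is.na(df$margin))),
       "nonmass lesions must not have shape or margin")
  fail(which(vis & is.na(df$internal_pattern)),
       "visible lesions must have an internal_pattern")
  df
}

#' Read and write lesion tables
#'
#' `read_lesions()` reads a lesion table from CSV (or, when the readxl
#' package is installed, from the first sheet of an XLSX workbook) and
#' validates it with [as_lesion_tbl()]. `write_lesions()` writes a
#' validated table to CSV; `read_lesions(write_lesions(x))` is the
#' identity on valid tables.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @param lesions A lesion table (validated with [as_lesion_tbl()]).
#' @return `read_lesions()` a validated lesion tibble; `write_lesions()`
#'   the input, invisibly.
#' @export
read_lesions <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dwidx_io_error")
  }
  df <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading xlsx requires the 'readxl' package",
            class = "dwidx_io_error")
    }
    readxl::read_excel(path, sheet = 1)
  } else {
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  as_lesion_tbl(df)
}

#' @rdname read_lesions
#' @export
write_lesions <- function(lesions, path, format = c("auto", "csv")) {
  format <- match.arg(format)
  if (format == "auto" && grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    abort("writing xlsx is not supported; use csv", class = "dwidx_io_error")
  }
  lesions <- as_lesion_tbl(lesions)
  write.csv(lesions, path, row.names = FALSE, na = "")
  invisible(lesions)
}

#' Partition a cohort by DWI visibility
#'
#' Lesions not visible on the diffusion-weighted images are treated as
#' negative DWI calls and excluded from all DWI analyses; the full cohort
#' (including them) is retained for DCE-MRI analyses. The partition is
#' exhaustive and disjoint.
#'
#' @param lesions A lesion table.
#' @return A named list with tibbles `visible` and `not_visible`.
#' @export
#' @examples
#' parts <- split_visible(simulate_cohort(100, seed = 1))
#' nrow(parts$visible) + nrow(parts$not_visible)
split_visible <- function(lesions) {
  lesions <- as_lesion_tbl(lesions)
  list(
    visible = lesions[lesions$dwi_visible, ],
    not_visible = lesions[!lesions$dwi_visible, ]
  )
}

#' DWI lesion detection rate
#'
#' The proportion of lesions visible on DWI, as a percentage of the full
#' cohort.
#'
#' @param lesions A lesion table.
#' @return A single numeric percentage.
#' @export
detection_rate <- function(lesions) {
  lesions <- as_lesion_tbl(lesions)
  100 * sum(lesions$dwi_visible) / nrow(lesions)
}
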