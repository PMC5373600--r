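#' Confusion matrix for a binary diagnostic call
#'
#' `confusion_matrix()` tabulates a logical call against the pathological
#' truth; `confusion_counts()` builds the same object from the four
#' counts directly (useful for published tables).
#'
#' @param truth Logical vector: `TRUE` for malignant (the positive
#'   class).
#' @param call Logical vector: the test's positive calls; same length.
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `"confusion_matrix"` holding `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts(tp = 86, fp = 6, fn = 26, tn = 23)
confusion_matrix <- function(truth, call) {
  if (length(truth) != length(call)) {
    abort("truth and call must have equal length", class = "dwidx_domain_error")
  }
  keep <- !is.na(truth) & !is.na(call)
  truth <- truth[keep]; call <- call[keep]
  confusion_counts(
    tp = sum(truth & call), fp = sum(!truth & call),
    fn = sum(truth & !call), tn = sum(!truth & !call)
  )
}

#' @rdname confusion_matrix
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", class = "dwidx_domain_error")
  }
  if (sum(counts) == 0) {
    abort("confusion matrix must contain at least one observation",
          class = "dwidx_domain_error")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive = malignant)\n")
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(call = c("positive", "negative"),
                               truth = c("malignant", "benign"))))
  invisible(x)
}

#' Diagnostic performance metrics
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy as percentages, computed by exact rational arithmetic before
#' any rounding. A metric whose denominator is zero (e.g. sensitivity in
#' an all-benign cohort) is reported as `NA`, never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param digits Round to this many decimals; `NULL` (default) for full
#'   precision. Published tables conventionally use 2.
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (percent) and the four counts.
#' @export
#' @examples
#' confusion_metrics(confusion_counts(86, 6, 26, 23), digits = 2)
confusion_metrics <- function(cm, digits = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- tibble(
    sensitivity = pct(cm$tp, cm$tp + cm$fn),
    specificity = pct(cm$tn, cm$tn + cm$fp),
    ppv = pct(cm$tp, cm$tp + cm$fp),
    npv = pct(cm$tn, cm$tn + cm$fn),
    accuracy = pct(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn),
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("sensitivity", "specificity", "ppv", "npv", "accuracy"),
      \(x) round(x, digits)))
  }
  out
}

#' Univariate odds ratio with Woolf confidence interval
#'
#' For the 2x2 table of an exposure (e.g. irregular shape, with oval as
#' reference) against malignancy, the odds ratio is `(a*d)/(b*c)` with
#' `a` = exposed cases, `b` = exposed controls, `c` = reference cases,
#' `d` = reference controls. The confidence interval is Woolf's
#' log-normal interval, `exp(log(OR) +/- z * sqrt(1/a+1/b+1/c+1/d))`.
#' If any cell is zero the odds ratio is undefined and reported as `NA`
#' (the convention used for descriptors observed only among
#' malignancies), not raised as an error.
#'
#' @param exposed_case,exposed_control Counts in the exposed (non-reference)
#'   row: malignant and benign lesions carrying the feature.
#' @param ref_case,ref_control Counts in the reference row.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"odds_ratio"`; see [tidy.odds_ratio()].
#' @export
#' @examples
#' odds_ratio(80, 9, 12, 14)   # irregular vs oval mass shape
odds_ratio <- function(exposed_case, exposed_control, ref_case, ref_control,
                       conf_level = 0.95) {
  counts <- c(a = exposed_case, b = exposed_control,
              c = ref_case, d = ref_control)
  if (any(counts < 0)) {
    abort("counts must be non-negative", class = "dwidx_domain_error")
  }
  if (any(counts == 0)) {
    res <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                conf_level = conf_level, counts = counts, defined = FALSE)
    return(structure(res, class = "odds_ratio"))
  }
  or <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  se_log <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se_log)
  structure(list(or = unname(or), ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, counts = counts, defined = TRUE),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  if (!x$defined) {
    cat("Odds ratio: undefined (zero cell)\n")
  } else {
    cat(sprintf("Odds ratio %.2f (%g%% CI %.2f-%.2f)\n",
                x$or, 100 * x$conf_level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

orient_scores <- function(scores, direction) {
  if (direction == "lower_is_positive") -as.numeric(scores)
  else as.numeric(scores)
}

# Mann-Whitney AUC with ties counted one half, via mid-ranks.
auc_mann_whitney <- function(oriented, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(oriented)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Hanley-McNeil standard error of an AUC.
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC curve of a continuous or ordinal reading
#' against the pathological truth. The AUC is the Mann-Whitney
#' probability that a malignant lesion ranks above a benign one (ties
#' counted one half), which equals the trapezoidal area under the
#' plotted curve; its standard error is the Hanley-McNeil closed form
#' with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
#'
#' @param scores Numeric or ordinal reading, one per lesion.
#' @param labels Logical: `TRUE` for malignant.
#' @param direction `"lower_is_positive"` (e.g. ADC: low values indicate
#'   malignancy) or `"higher_is_positive"` (e.g. confidence scores).
#' @return An object of class `"dwidx_roc"`: tibble `points`
#'   (`threshold`, `sensitivity`, `fpr`), `auc`, `se_auc`, `n_pos`,
#'   `n_neg`, `direction`. For `"lower_is_positive"` a point's call is
#'   `score < threshold`; for `"higher_is_positive"` it is
#'   `score > threshold`.
#' @export
#' @examples
#' cohort <- split_visible(simulate_cohort(200, seed = 3))$visible
#' roc_empirical(cohort$adc, cohort$pathology == "malignant")
roc_empirical <- function(scores, labels,
                          direction = c("lower_is_positive",
                                        "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("both classes must be present", class = "dwidx_domain_error")
  }
  x <- orient_scores(scores, direction)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  # vertices between tie groups: call positive iff oriented score > t
  thr <- c(-Inf, sort(unique(x)))
  sens <- vapply(thr, \(t) sum(x[labels] > t) / n_pos, numeric(1))
  fpr <- vapply(thr, \(t) sum(x[!labels] > t) / n_neg, numeric(1))
  ord <- order(fpr, sens)
  points <- tibble(
    threshold = if (direction == "lower_is_positive") -thr[ord] else thr[ord],
    sensitivity = sens[ord],
    fpr = fpr[ord]
  )
  auc <- auc_mann_whitney(x, labels)
  structure(
    list(points = points, auc = auc,
         se_auc = hanley_mcneil_se(auc, n_pos, n_neg),
         n_pos = n_pos, n_neg = n_neg, direction = direction),
    class = "dwidx_roc"
  )
}

#' @export
print.dwidx_roc <- function(x, ...) {
  cat(sprintf(
    "Empirical ROC: AUC %.3f (SE %.4f), %d malignant / %d benign\n",
    x$auc, x$se_auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Scans every distinct observed value as a candidate cutoff and returns
#' the one maximizing the Youden index `J = sensitivity + specificity - 1`.
#' For `"lower_is_positive"` the call at cutoff `c` is `score < c`
#' (ties negative); for `"higher_is_positive"` it is `score > c`. Exact
#' ties in `J` are broken toward the cutoff with higher sensitivity, then
#' the smaller threshold.
#'
#' @inheritParams roc_empirical
#' @return A one-row tibble: `cutoff`, `j`, `sensitivity`,
#'   `specificity` (the latter two as percentages).
#' @export
#' @examples
#' cohort <- split_visible(simulate_cohort(500, seed = 3))$visible
#' youden_cutoff(cohort$adc, cohort$pathology == "malignant")
youden_cutoff <- function(scores, labels,
                          direction = c("lower_is_positive",
                                        "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("both classes must be present", class = "dwidx_domain_error")
  }
  cand <- sort(unique(scores))
  pos_call <- function(c) {
    if (direction == "lower_is_positive") scores < c else scores > c
  }
  grid <- purrr::map_dfr(cand, function(c) {
    call <- pos_call(c)
    sens <- sum(call & labels) / sum(labels)
    spec <- sum(!call & !labels) / sum(!labels)
    tibble(cutoff = c, j = sens + spec - 1,
           sensitivity = 100 * sens, specificity = 100 * spec)
  })
  grid <- grid[order(-grid$j, -grid$sensitivity, grid$cutoff), ]
  grid[1, ]
}

#' Compare two independent AUCs (Hanley-McNeil)
#'
#' Two-sided z-test for the difference of AUCs estimated on *disjoint*
#' samples: `z = (A1 - A2) / sqrt(SE1^2 + SE2^2)` with each standard
#' error from the Hanley-McNeil closed form.
#'
#' @param roc1,roc2 [roc_empirical()] objects from disjoint samples.
#' @return A one-row tibble: `auc1`, `auc2`, `z`, `p`.
#' @export
compare_auc <- function(roc1, roc2) {
  stopifnot(inherits(roc1, "dwidx_roc"), inherits(roc2, "dwidx_roc"))
  se <- sqrt(roc1$se_auc^2 + roc2$se_auc^2)
  diff <- roc1$auc - roc2$auc
  if (se == 0) {
    if (diff != 0) {
      abort("zero combined standard error with unequal AUCs",
            class = "dwidx_domain_error")
    }
    z <- 0
  } else {
    z <- diff / se
  }
  tibble(auc1 = roc1$auc, auc2 = roc2$auc, z = z, p = 2 * pnorm(-abs(z)))
}

# Placement values (V10 over positives, V01 over negatives) with ties
# counted one half, computed from mid-ranks.
delong_placements <- function(oriented, labels) {
  m <- sum(labels); n <- sum(!labels)
  r_all <- rank(oriented)
  v10 <- (r_all[labels] - rank(oriented[labels])) / n
  v01 <- 1 - (r_all[!labels] - rank(oriented[!labels])) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare two paired AUCs (DeLong)
#'
#' Nonparametric covariance-based z-test for the difference of two AUCs
#' measured on the *same* lesions, using the structural components
#' (placement values) of each curve.
#'
#' @param scores1,scores2 The two readings, one value per lesion.
#' @param labels Logical: `TRUE` for malignant.
#' @param direction1,direction2 Direction of each reading (see
#'   [roc_empirical()]); `direction2` defaults to `direction1`.
#' @return A one-row tibble: `auc1`, `auc2`, `z`, `p`.
#' @export
compare_auc_paired <- function(scores1, scores2, labels,
                               direction1 = c("lower_is_positive",
                                              "higher_is_positive"),
                               direction2 = NULL) {
  direction1 <- match.arg(direction1)
  direction2 <- direction2 %||% direction1
  labels <- as.logical(labels)
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels)) {
    abort("scores1, scores2 and labels must have equal length",
          class = "dwidx_domain_error")
  }
  keep <- !is.na(scores1) & !is.na(scores2) & !is.na(labels)
  scores1 <- scores1[keep]; scores2 <- scores2[keep]; labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("both classes must be present", class = "dwidx_domain_error")
  }
  p1 <- delong_placements(orient_scores(scores1, direction1), labels)
  p2 <- delong_placements(orient_scores(scores2, direction2), labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::var(p1$v10 - p2$v10)
  s01 <- stats::var(p1$v01 - p2$v01)
  v <- s10 / m + s01 / n
  diff <- p1$auc - p2$auc
  z <- if (v == 0) {
    if (diff != 0) {
      abort("zero variance with unequal AUCs", class = "dwidx_domain_error")
    }
    0
  } else {
    diff / sqrt(v)
  }
  tibble(auc1 = p1$auc, auc2 = p2$auc, z = z, p = 2 * pnorm(-abs(z)))
}
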