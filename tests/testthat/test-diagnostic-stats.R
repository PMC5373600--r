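test_that("confusion metrics match the published quantitative column and edge tables", {
  m <- confusion_metrics(confusion_counts(tp = 86, fp = 6, fn = 26, tn = 23),
                         digits = 2)
  expect_equal(m$sensitivity, 76.79)
  expect_equal(m$specificity, 79.31)
  expect_equal(m$ppv, 93.48)
  expect_equal(m$npv, 46.94)
  expect_equal(m$accuracy, 77.30)

  perfect <- confusion_metrics(confusion_counts(10, 0, 0, 7))
  expect_true(all(perfect[c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")] == 100))
  half <- confusion_metrics(confusion_counts(1, 1, 1, 1))
  expect_true(all(half[c("sensitivity", "specificity", "ppv", "npv",
                         "accuracy")] == 50))
})

test_that("sensitivity/specificity weights recombine exactly into accuracy", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(0:40, 4, replace = TRUE)
    if (k[1] + k[3] == 0 || k[2] + k[4] == 0) next
    cm <- confusion_counts(k[1], k[2], k[3], k[4])
    m <- confusion_metrics(cm)
    total <- sum(k)
    expect_equal(m$sensitivity * (cm$tp + cm$fn) / 100 +
                   m$specificity * (cm$tn + cm$fp) / 100,
                 m$accuracy * total / 100)
  }
})

test_that("undefined metrics are NA, not zero", {
  all_benign <- confusion_metrics(confusion_counts(0, 4, 0, 16))
  expect_true(is.na(all_benign$sensitivity))
  expect_false(is.na(all_benign$specificity))
  expect_error(confusion_counts(0, 0, 0, 0), class = "dwidx_domain_error")
  expect_error(confusion_counts(-1, 2, 3, 4), class = "dwidx_domain_error")
})

test_that("odds ratios and Woolf intervals reproduce the published univariate table", {
  # irregular vs oval mass shape
  or1 <- tidy(odds_ratio(80, 9, 12, 14))
  expect_equal(round(or1$estimate, 2), 10.37)
  expect_equal(round(or1$conf.low, 2), 3.69)
  expect_lt(abs(or1$conf.high - 29.16), 0.015)
  # heterogeneous vs homogeneous internal pattern
  or2 <- tidy(odds_ratio(58, 6, 4, 19))
  expect_equal(round(or2$estimate, 2), 45.92)
  expect_equal(round(or2$conf.low, 2), 11.70)
  expect_equal(round(or2$conf.high, 2), 180.18)
  # ADC below vs at/above the cutoff
  or3 <- tidy(odds_ratio(79, 5, 17, 17))
  expect_equal(round(or3$estimate, 2), 15.80)
  expect_equal(round(or3$conf.low, 2), 5.12)
  expect_lt(abs(or3$conf.high - 48.74), 0.015)
  # round vs oval and irregular-margin vs circumscribed
  expect_equal(round(tidy(odds_ratio(4, 2, 12, 14))$estimate, 2), 2.33)
  expect_equal(round(tidy(odds_ratio(60, 12, 11, 13))$estimate, 2), 5.91)
})

test_that("zero cells give an undefined odds ratio, and symmetry laws hold", {
  undef <- odds_ratio(25, 0, 11, 13)
  expect_false(undef$defined)
  expect_true(is.na(undef$or))

  expect_equal(odds_ratio(7, 7, 7, 7)$or, 1)
  set.seed(9)
  for (i in 1:50) {
    k <- sample(1:60, 4, replace = TRUE)
    a <- odds_ratio(k[1], k[2], k[3], k[4])
    # swapping both rows and both columns leaves the OR unchanged
    expect_equal(odds_ratio(k[4], k[3], k[2], k[1])$or, a$or)
    # transposing exposure and outcome inverts it
    expect_equal(a$or * odds_ratio(k[2], k[1], k[4], k[3])$or, 1)
  }
})

test_that("the empirical AUC equals brute-force pair counting on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:60, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    # half the instances have heavy ties
    scores <- if (i %% 2 == 0) {
      sample(seq(0.5, 1.5, by = 0.25), n, replace = TRUE)
    } else {
      runif(n, 0.4, 1.6)
    }
    direction <- if (i %% 3 == 0) "higher_is_positive" else "lower_is_positive"
    roc <- roc_empirical(scores, labels, direction)
    expect_equal(roc$auc, auc_pair_counting(scores, labels, direction),
                 tolerance = 1e-12)
    # the stored points integrate (trapezoid) to the same area
    trap <- with(roc$points,
                 sum(diff(fpr) * (utils::head(sensitivity, -1) +
                                    utils::tail(sensitivity, -1)) / 2))
    expect_equal(trap, roc$auc, tolerance = 1e-12)
    expect_true(all(diff(roc$points$sensitivity) >= 0))
    expect_true(all(diff(roc$points$fpr) >= 0))
  }
})

test_that("the Hanley-McNeil standard error matches the closed form literally", {
  set.seed(23)
  scores <- c(runif(40, 0.4, 1.2), runif(25, 0.8, 1.6))
  labels <- rep(c(TRUE, FALSE), c(40, 25))
  roc <- roc_empirical(scores, labels, "lower_is_positive")
  a <- roc$auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (40 - 1) * (q1 - a^2) + (25 - 1) * (q2 - a^2)) /
               (40 * 25))
  expect_equal(roc$se_auc, se, tolerance = 1e-14)
})

test_that("AUC agrees with pROC and flips under direction reversal", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- round(runif(80, 0.4, 1.6), 2)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE, prob = c(0.7, 0.3))
  ours <- roc_empirical(scores, labels, "lower_is_positive")$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(labels, scores, direction = ">", quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)

  tie_free <- scores + seq_along(scores) * 1e-9
  expect_equal(
    roc_empirical(tie_free, labels, "higher_is_positive")$auc,
    1 - roc_empirical(tie_free, labels, "lower_is_positive")$auc,
    tolerance = 1e-12
  )
  expect_error(roc_empirical(scores, rep(TRUE, 80)),
               class = "dwidx_domain_error")
})

test_that("perfectly separated readings give AUC 1 and Youden J 1", {
  roc <- roc_empirical(c(0.4, 0.5, 1.4, 1.5), c(TRUE, TRUE, FALSE, FALSE),
                       "lower_is_positive")
  expect_equal(roc$auc, 1.0)
  yj <- youden_cutoff(c(0.4, 0.5, 1.4, 1.5), c(TRUE, TRUE, FALSE, FALSE),
                      "lower_is_positive")
  expect_equal(yj$j, 1.0)
  expect_true(yj$cutoff > 0.5 & yj$cutoff <= 1.4)
})

test_that("the Youden scan attains the grid-oracle maximum on random instances", {
  set.seed(37)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n, 0.4, 1.6), sample(1:2, 1))
    direction <- if (i %% 2 == 0) "higher_is_positive" else "lower_is_positive"
    got <- youden_cutoff(scores, labels, direction)
    expect_equal(got$j, youden_grid_max(scores, labels, direction),
                 tolerance = 1e-12)
    # reported sensitivity/specificity are consistent with the cutoff
    call <- if (direction == "lower_is_positive") scores < got$cutoff
            else scores > got$cutoff
    expect_equal(got$sensitivity, 100 * sum(call & labels) / sum(labels))
    expect_equal(got$specificity, 100 * sum(!call & !labels) / sum(!labels))
  }
})

test_that("the Youden cutoff on a default synthetic cohort sits near the theoretical optimum", {
  cohort <- simulate_cohort(10000, seed = 555)
  vis <- cohort[cohort$dwi_visible, ]
  got <- youden_cutoff(vis$adc, vis$pathology == "malignant",
                       "lower_is_positive")
  # J(c) = F_mal(c) - F_ben(c) maximized by quadrature-free optimization
  jfun <- function(c) {
    ptrunc(c, 0.88, 0.19, 0.42, 1.36) - ptrunc(c, 1.14, 0.23, 0.66, 1.58)
  }
  opt <- optimize(jfun, c(0.6, 1.4), maximum = TRUE)$maximum
  expect_lt(abs(got$cutoff - opt), 0.05)
})

test_that("independent AUC comparison follows the closed-form z", {
  se_hm <- function(a, n1, n2) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
           (n1 * n2))
  }
  stub <- function(a, n1, n2) {
    structure(list(points = NULL, auc = a, se_auc = se_hm(a, n1, n2),
                   n_pos = n1, n_neg = n2, direction = "lower_is_positive"),
              class = "dwidx_roc")
  }
  r1 <- stub(0.78, 20, 25)
  r2 <- stub(0.84, 91, 7)
  got <- compare_auc(r1, r2)
  expect_equal(got$z,
               (0.78 - 0.84) / sqrt(se_hm(0.78, 20, 25)^2 +
                                      se_hm(0.84, 91, 7)^2),
               tolerance = 1e-14)
  # symmetric under swapping, identical under equality
  expect_equal(compare_auc(r2, r1)$p, got$p)
  expect_equal(compare_auc(r2, r1)$z, -got$z)
  same <- compare_auc(r1, r1)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("paired DeLong z matches brute-force structural components", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(12:40, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s1 <- round(runif(n, 0.4, 1.6), 1)   # ties likely
    s2 <- s1 + rnorm(n, 0, 0.2)
    got <- compare_auc_paired(s1, s2, labels,
                              direction1 = "lower_is_positive")
    expect_equal(got$z,
                 delong_bruteforce(s1, s2, labels, "lower_is_positive"),
                 tolerance = 1e-10)
    swapped <- compare_auc_paired(s2, s1, labels,
                                  direction1 = "lower_is_positive")
    expect_equal(swapped$z, -got$z, tolerance = 1e-12)
  }
  labels <- rep(c(TRUE, FALSE), 10)
  s <- runif(20)
  same <- compare_auc_paired(s, s, labels, direction1 = "lower_is_positive")
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("paired DeLong agrees with pROC on a worked instance", {
  skip_if_not_installed("pROC")
  set.seed(43)
  labels <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.6, 0.4))
  adc <- runif(60, 0.4, 1.6)
  score <- ifelse(labels, sample(1:3, 60, TRUE, c(.2, .3, .5)),
                  sample(1:3, 60, TRUE, c(.5, .3, .2)))
  got <- compare_auc_paired(adc, score, labels,
                            direction1 = "lower_is_positive",
                            direction2 = "higher_is_positive")
  ref <- pROC::roc.test(
    pROC::roc(labels, -adc, direction = "<", quiet = TRUE),
    pROC::roc(labels, score, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(abs(got$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
})
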