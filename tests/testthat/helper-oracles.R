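# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pair counting instead of ranks, double loops
# instead of placement algebra, quadrature instead of sampling.

# O(n^2) Mann-Whitney AUC by explicit pair counting, ties worth one half.
auc_pair_counting <- function(scores, labels, direction = "lower_is_positive") {
  x <- if (direction == "lower_is_positive") -scores else scores
  pos <- x[labels]; neg <- x[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Youden scan over a grid ten times finer than the observed thresholds.
youden_grid_max <- function(scores, labels, direction = "lower_is_positive") {
  u <- sort(unique(scores))
  grid <- sort(unique(c(u, seq(min(u) - 0.1, max(u) + 0.1, length.out = 10 * length(u)))))
  best <- -Inf
  for (c in grid) {
    call <- if (direction == "lower_is_positive") scores < c else scores > c
    j <- sum(call & labels) / sum(labels) + sum(!call & !labels) / sum(!labels) - 1
    if (j > best) best <- j
  }
  best
}

# DeLong z by brute-force structural components (double loops).
delong_bruteforce <- function(s1, s2, labels,
                              direction1 = "lower_is_positive",
                              direction2 = direction1) {
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  comps <- function(scores, direction) {
    x <- if (direction == "lower_is_positive") -scores else scores
    pos <- x[labels]; neg <- x[!labels]
    v10 <- vapply(pos, function(p) mean(vapply(neg, function(q) psi(p, q),
                                               numeric(1))), numeric(1))
    v01 <- vapply(neg, function(q) mean(vapply(pos, function(p) psi(p, q),
                                               numeric(1))), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  c1 <- comps(s1, direction1); c2 <- comps(s2, direction2)
  m <- sum(labels); n <- sum(!labels)
  v <- stats::var(c1$v10 - c2$v10) / m + stats::var(c1$v01 - c2$v01) / n
  (c1$auc - c2$auc) / sqrt(v)
}

# Truncated-Gaussian density, CDF and mean by closed form / quadrature.
dtrunc <- function(x, mean, sd, lo, hi) {
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  ifelse(x < lo | x > hi, 0, dnorm(x, mean, sd) / z)
}
ptrunc <- function(x, mean, sd, lo, hi) {
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  pmin(1, pmax(0, (pnorm(pmin(pmax(x, lo), hi), mean, sd) -
                     pnorm(lo, mean, sd)) / z))
}
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Single-lesion table builder for scoring tests.
make_lesion <- function(type, shape = NA, margin = NA, distribution = NA,
                        pattern, adc = 1.0, pathology = "malignant",
                        size_cm = 1.5, birads = 4L, id = "L1") {
  tibble::tibble(
    lesion_id = id, pathology = pathology, dwi_visible = TRUE,
    lesion_type = type, shape = shape, margin = margin,
    distribution = distribution, internal_pattern = pattern,
    adc = adc, size_cm = size_cm, birads = birads
  )
}

# All 27 mass and 9 nonmass descriptor configurations.
all_configs <- function() {
  mass <- expand.grid(
    shape = c("oval", "round", "irregular"),
    margin = c("circumscribed", "irregular", "spiculated"),
    pattern = c("homogeneous", "heterogeneous", "rim"),
    stringsAsFactors = FALSE
  )
  nonmass <- expand.grid(
    distribution = c("focal", "linear", "segmental"),
    pattern = c("homogeneous", "heterogeneous", "rim"),
    stringsAsFactors = FALSE
  )
  list(mass = mass, nonmass = nonmass)
}

score_of <- function(type, shape = NA, margin = NA, distribution = NA,
                     pattern) {
  dwidx::score_lesions(
    make_lesion(type, shape, margin, distribution, pattern)
  )$qual_score
}
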