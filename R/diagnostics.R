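#' Confusion counts from paired index/reference values
#'
#' Positivity is cutoff-inclusive (`value <= cutoff`) for both the index
#' under test and the reference, matching the clinical convention for
#' pressure-derived indices (iFR <= 0.89, FFR <= 0.80).
#'
#' @param index numeric vector of index values in (0, 1].
#' @param reference numeric vector of reference values, same length.
#' @param cutoff_index,cutoff_reference positivity cutoffs.
#' @return a list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_from_pairs <- function(index, reference, cutoff_index = 0.89,
                                 cutoff_reference = 0.80) {
  if (length(index) != length(reference)) {
    stop_invalid("index and reference must have equal length")
  }
  ipos <- index <= cutoff_index
  rpos <- reference <= cutoff_reference
  confusion_counts(sum(ipos & rpos), sum(ipos & !rpos),
                   sum(!ipos & rpos), sum(!ipos & !rpos))
}

#' Build confusion counts directly
#'
#' @param tp,fp,fn,tn non-negative integer counts (total > 0).
#' @return a list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop_invalid("counts must be non-negative with a positive total")
  }
  structure(as.list(counts), class = "confusion_counts")
}

# One proportion with its Clopper-Pearson exact 95% CI; zero denominator
# is flagged undefined rather than coerced to 0.
proportion_ci <- function(successes, total, conf_level = 0.95) {
  if (total == 0) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                undefined = TRUE))
  }
  ci <- stats::binom.test(successes, total, conf.level = conf_level)$conf.int
  list(estimate = successes / total, lower = ci[1], upper = ci[2],
       undefined = FALSE)
}

#' Diagnostic metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy, each with a two-sided
#' Clopper-Pearson 95% CI. Metrics with a zero denominator are flagged
#' undefined.
#'
#' @param counts a `confusion_counts`.
#' @param conf_level confidence level.
#' @return a list of class `diagnostic_metrics`; each element has
#'   `estimate`, `lower`, `upper`, `undefined`.
#' @export
diagnostic_metrics <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, structure(
    list(
      sensitivity = proportion_ci(tp, tp + fn, conf_level),
      specificity = proportion_ci(tn, tn + fp, conf_level),
      ppv = proportion_ci(tp, tp + fp, conf_level),
      npv = proportion_ci(tn, tn + fn, conf_level),
      accuracy = proportion_ci(tp + tn, tp + fp + fn + tn, conf_level)
    ),
    class = "diagnostic_metrics"
  ))
}

#' Display-rounded metric percentages
#'
#' Point estimates as whole percentages, rounded half-up (report-table
#' convention).
#'
#' @param metrics a `diagnostic_metrics`.
#' @return named numeric vector of whole-percent estimates.
#' @export
metrics_percent <- function(metrics) {
  vapply(metrics, function(m) round_half_up(100 * m$estimate), numeric(1))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = A - B`; bias is their mean, the limits of agreement
#' are `bias +/- 1.96 * sd(d)` with the sample (n-1) standard deviation.
#'
#' @param values_a,values_b paired measurements (equal length, n >= 2).
#' @return a list of class `bland_altman_result`: `bias`, `sd`, `lower`,
#'   `upper`, `n`, `differences`, `means`.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop_invalid("paired vectors must have equal length")
  }
  if (length(values_a) < 2) stop_invalid("Bland-Altman needs n >= 2")
  d <- values_a - values_b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd = s, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
         n = length(d), differences = d, means = (values_a + values_b) / 2),
    class = "bland_altman_result"
  )
}

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' Independent-samples comparison:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p. For correlations measured on the same subjects against a
#' shared variable, see [steiger_compare()].
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z`, `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop_invalid("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop_invalid("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two dependent correlations sharing one variable (Steiger)
#'
#' Steiger's Z for `cor(x, y1)` vs `cor(x, y2)` measured on the same n
#' subjects, with `r12 = cor(y1, y2)`. Provided as the dependent-sample
#' alternative to [fisher_z_compare()]; not used by default in reports.
#'
#' @param r1,r2 the two correlations with the shared variable.
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return list with `z`, `p`.
#' @export
steiger_compare <- function(r1, r2, r12, n) {
  if (any(abs(c(r1, r2, r12)) >= 1)) stop_invalid("|r| must be < 1")
  if (n <= 3) stop_invalid("sample size must exceed 3")
  rbar <- (r1 + r2) / 2
  det_r <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  cov_term <- (r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) /
    (1 - rbar^2)^2
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * cov_term))
  if (det_r < 0) warning("correlation triple is not positive definite")
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Decision-curve analysis
#'
#' Net benefit of the fixed-cutoff classifier across threshold
#' probabilities pt: `NB(pt) = TP/n - (FP/n) * pt/(1-pt)`, against
#' treat-all (`prevalence - (1-prevalence) * pt/(1-pt)`) and treat-none
#' (identically 0).
#'
#' @param index index values; positive when `<= cutoff`.
#' @param labels logical (or 0/1) disease labels.
#' @param cutoff index positivity cutoff.
#' @param thresholds threshold-probability grid, strictly inside (0, 1).
#' @return a data frame of class `dca_result` with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(index, labels, cutoff = 0.89,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.logical(labels)
  if (length(index) != length(labels)) {
    stop_invalid("index and labels must have equal length")
  }
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop_invalid("thresholds must lie strictly inside (0, 1)")
  }
  n <- length(index)
  pos <- index <= cutoff
  tp <- sum(pos & labels)
  fp <- sum(pos & !labels)
  prev <- mean(labels)
  w <- thresholds / (1 - thresholds)
  structure(
    data.frame(
      threshold = thresholds,
      nb_model = tp / n - (fp / n) * w,
      nb_all = prev - (1 - prev) * w,
      nb_none = 0
    ),
    class = c("dca_result", "data.frame")
  )
}
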