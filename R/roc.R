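# Placement values of the Mann-Whitney kernel: for each positive score,
# the mean of psi(x, y) over negatives (1 if x > y, 1/2 if tied), and
# symmetrically for negatives. AUC = mean of either set.
placement_values <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' The index is oriented so that a lower value means disease: the
#' discrimination score is `1 - index`. The AUC is the Mann-Whitney
#' statistic (ties counted one half) and the 95% CI uses the DeLong
#' placement-value variance.
#'
#' @param index index values (lower = more diseased); ignored if `score`
#'   is supplied directly.
#' @param labels logical (or 0/1) disease labels; both classes required.
#' @param score optional pre-oriented scores (higher = more diseased).
#' @param conf_level confidence level.
#' @return a list of class `roc_result`: `auc`, `se`, `lower`, `upper`,
#'   `points` (data frame `fpr`, `tpr`, monotone from (0,0) to (1,1)),
#'   `orientation`.
#' @export
auc_empirical <- function(index = NULL, labels, score = NULL,
                          conf_level = 0.95) {
  labels <- as.logical(labels)
  if (is.null(score)) {
    if (is.null(index)) stop_invalid("supply either index or score")
    score <- 1 - index
  }
  if (length(score) != length(labels)) {
    stop_invalid("scores and labels must have equal length")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_invalid("both classes must be present to compute an ROC curve")
  }
  pv <- placement_values(score, labels)
  var_auc <- stats::var(pv$v10) / n1 + stats::var(pv$v01) / n0
  se <- sqrt(var_auc)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  pts <- data.frame(
    fpr = vapply(thr, function(t) mean(score[!labels] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(score[labels] >= t), numeric(1))
  )
  structure(
    list(auc = pv$auc, se = se,
         lower = max(0, pv$auc - zq * se), upper = min(1, pv$auc + zq * se),
         points = pts,
         orientation = "lower index => positive (score = 1 - index)"),
    class = "roc_result"
  )
}

#' Compare two paired AUCs by the DeLong method
#'
#' Both markers must be measured on the same subjects against the same
#' labels. The variance of the AUC difference uses the DeLong (1988)
#' covariance of placement values; `z = (AUC_A - AUC_B) / se` with a
#' two-sided normal p. When the variance degenerates (e.g. identical
#' markers), z is 0 with p = 1 if the AUCs agree, otherwise the result is
#' flagged undefined.
#'
#' @param index_a,index_b the two index vectors (lower = more diseased);
#'   alternatively supply pre-oriented `score_a`, `score_b`.
#' @param labels logical (or 0/1) disease labels.
#' @param score_a,score_b optional pre-oriented scores.
#' @return list with `auc_a`, `auc_b`, `z`, `p`, `se`, `undefined`.
#' @export
delong_compare <- function(index_a = NULL, index_b = NULL, labels,
                           score_a = NULL, score_b = NULL) {
  labels <- as.logical(labels)
  if (is.null(score_a)) score_a <- 1 - index_a
  if (is.null(score_b)) score_b <- 1 - index_b
  if (length(score_a) != length(labels) || length(score_b) != length(labels)) {
    stop_invalid("scores and labels must have equal length")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_invalid("both classes must be present")
  pa <- placement_values(score_a, labels)
  pb <- placement_values(score_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  diff <- pa$auc - pb$auc
  if (var_diff <= 1e-15) {
    if (abs(diff) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1, se = 0,
                  undefined = FALSE))
    }
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = NA_real_, p = NA_real_,
                se = 0, undefined = TRUE))
  }
  se <- sqrt(var_diff)
  z <- diff / se
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       se = se, undefined = FALSE)
}
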