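test_that("confusion counts follow the inclusive cutoff rule", {
  x <- c(0.85, 0.91, 0.7, 0.95)
  counts <- confusion_from_pairs(x, x, 0.89, 0.89)
  expect_identical(counts$fp + counts$fn, 0L)

  counts <- confusion_from_pairs(c(0.88, 0.95), c(0.86, 0.93), 0.89, 0.89)
  expect_identical(unlist(counts), c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  # boundary: index exactly at its cutoff is positive
  counts <- confusion_from_pairs(0.89, 0.90, 0.89, 0.89)
  expect_identical(unlist(counts), c(tp = 0L, fp = 1L, fn = 0L, tn = 0L))

  expect_error(confusion_from_pairs(c(0.8, 0.9), 0.8),
               class = "ctifr_invalid_parameter")
})

test_that("diagnostic metrics reproduce a published-style performance table", {
  # FFR as reference: TP=11, FP=4, FN=4, TN=17
  pct <- report_from_counts(11, 4, 4, 17)$percent
  expect_identical(pct, c(sensitivity = 73, specificity = 81, ppv = 73,
                          npv = 81, accuracy = 78))
  # iFR as reference: TP=11, FP=3, FN=4, TN=18
  pct <- report_from_counts(11, 3, 4, 18)$percent
  expect_identical(pct, c(sensitivity = 73, specificity = 86, ppv = 79,
                          npv = 82, accuracy = 81))
  # degenerate perfect classifier
  pct <- report_from_counts(1, 0, 0, 1)$percent
  expect_true(all(pct == 100))
})

test_that("metric confidence intervals are exact binomial and bracket the estimate", {
  m <- diagnostic_metrics(confusion_counts(11, 4, 4, 17))
  for (name in names(m)) {
    est <- m[[name]]
    expect_true(est$lower <= est$estimate && est$estimate <= est$upper)
  }
  # cross-check sensitivity CI against binom.test directly
  ref <- stats::binom.test(11, 15)$conf.int
  expect_equal(c(m$sensitivity$lower, m$sensitivity$upper), as.numeric(ref))
  # zero denominator flagged undefined, not zero
  und <- diagnostic_metrics(confusion_counts(0, 0, 0, 5))
  expect_true(und$sensitivity$undefined)
  expect_true(is.na(und$sensitivity$estimate))
})

test_that("empirical AUC equals the Mann-Whitney pair enumeration", {
  # hand-enumerable fixture: 2 concordant, 2 discordant of 4 pairs
  res <- auc_empirical(labels = c(TRUE, TRUE, FALSE, FALSE),
                       score = c(0.8, 0.7, 0.9, 0.6))
  expect_equal(res$auc, 0.5)
  expect_equal(auc_empirical(labels = c(TRUE, FALSE), score = c(1, 0))$auc, 1)
  expect_equal(auc_empirical(labels = c(TRUE, FALSE, TRUE),
                             score = c(0.5, 0.5, 0.5))$auc, 0.5)
  expect_error(auc_empirical(labels = c(TRUE, TRUE), score = c(1, 2)),
               class = "ctifr_invalid_parameter")

  brute_auc <- function(score, labels) {
    x <- score[labels]; y <- score[!labels]
    total <- 0
    for (xi in x) for (yj in y) total <- total + (xi > yj) + 0.5 * (xi == yj)
    total / (length(x) * length(y))
  }
  for (seed in 1:100) {
    dat <- withr::with_seed(seed, {
      n <- sample(4:30, 1)
      list(score = round(stats::runif(n), 2),  # rounding forces ties
           labels = c(TRUE, FALSE, stats::runif(n - 2) > 0.5))
    })
    expect_equal(auc_empirical(labels = dat$labels, score = dat$score)$auc,
                 brute_auc(dat$score, dat$labels))
  }

  # ROC points run monotonically from (0,0) to (1,1)
  pts <- auc_empirical(labels = c(TRUE, TRUE, FALSE, FALSE),
                       score = c(0.8, 0.7, 0.9, 0.6))$points
  expect_equal(as.numeric(pts[1, ]), c(0, 0))
  expect_equal(as.numeric(pts[nrow(pts), ]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("AUC and DeLong CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  dat <- withr::with_seed(99, {
    idx <- c(stats::rnorm(20, 0.8, 0.08), stats::rnorm(15, 0.9, 0.05))
    list(index = pmin(idx, 1), labels = rep(c(TRUE, FALSE), c(20, 15)))
  })
  ours <- auc_empirical(index = dat$index, labels = dat$labels)
  theirs <- pROC::roc(dat$labels, 1 - dat$index, quiet = TRUE,
                      direction = "<", levels = c(FALSE, TRUE))
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)))
  ci <- as.numeric(pROC::ci.auc(theirs, method = "delong"))
  expect_equal(c(ours$lower, ours$upper), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("the paired DeLong test matches brute-force placement values", {
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  a <- c(0.92, 0.81, 0.74, 0.55, 0.60, 0.43)
  b <- c(0.88, 0.52, 0.70, 0.61, 0.33, 0.45)
  res <- delong_compare(labels = labels, score_a = a, score_b = b)

  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  pv <- function(score) {
    x <- score[labels]; y <- score[!labels]
    v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
    v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- pv(a); pb <- pv(b)
  var_diff <- (stats::var(pa$v10) + stats::var(pb$v10) -
                 2 * stats::cov(pa$v10, pb$v10)) / 3 +
              (stats::var(pa$v01) + stats::var(pb$v01) -
                 2 * stats::cov(pa$v01, pb$v01)) / 3
  z_expected <- (pa$auc - pb$auc) / sqrt(var_diff)
  expect_lt(abs(res$z - z_expected), 1e-10)
  expect_equal(res$p, 2 * stats::pnorm(-abs(z_expected)))

  # identical markers: z = 0, p = 1
  same <- delong_compare(labels = labels, score_a = a, score_b = a)
  expect_identical(c(same$z, same$p), c(0, 1))
  # antisymmetry
  rev <- delong_compare(labels = labels, score_a = b, score_b = a)
  expect_equal(rev$z, -res$z)
  expect_equal(rev$p, res$p)
})

test_that("DeLong comparison agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  dat <- withr::with_seed(7, {
    n <- 40
    labels <- stats::runif(n) < 0.4
    list(labels = labels,
         a = stats::runif(n) + labels * 0.5,
         b = stats::runif(n) + labels * 0.3)
  })
  ours <- delong_compare(labels = dat$labels, score_a = dat$a, score_b = dat$b)
  ra <- pROC::roc(dat$labels, dat$a, quiet = TRUE, direction = "<",
                  levels = c(FALSE, TRUE))
  rb <- pROC::roc(dat$labels, dat$b, quiet = TRUE, direction = "<",
                  levels = c(FALSE, TRUE))
  theirs <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p, theirs$p.value, tolerance = 1e-9)
})

test_that("Bland-Altman bias and limits of agreement are the 1.96-sd band", {
  same <- bland_altman(c(0.8, 0.9, 0.7), c(0.8, 0.9, 0.7))
  expect_identical(c(same$bias, same$lower, same$upper), c(0, 0, 0))

  ba <- bland_altman(c(0.5, 0.6, 0.7), c(0.5, 0.5, 0.5))
  expect_equal(ba$bias, 0.1)
  expect_equal(ba$sd, 0.1)
  expect_equal(c(ba$lower, ba$upper), c(0.1 - 0.196, 0.1 + 0.196))

  # agreement scale of the published iFR comparison: upper limit ~0.093
  expect_equal(0.003 + 1.96 * 0.046, 0.09316)

  expect_error(bland_altman(1, numeric(0)), class = "ctifr_invalid_parameter")
  expect_error(bland_altman(1, 1), class = "ctifr_invalid_parameter")

  # ~95% of large Gaussian samples fall inside the limits
  d <- withr::with_seed(11, stats::rnorm(5000, 0.01, 0.05))
  ba <- bland_altman(d, numeric(5000))
  coverage <- mean(d >= ba$lower & d <= ba$upper)
  expect_gte(coverage, 0.93)
})

test_that("Fisher r-to-z comparison reproduces known p-values", {
  expect_equal(fisher_z_compare(0.5, 30, 0.5, 40)$p, 1)
  # equal-size samples with nearly equal correlations: p = 0.941
  expect_equal(round(fisher_z_compare(0.67, 36, 0.68, 36)$p, 3), 0.941)
  # strongly different correlations: z ~ 7.1, p << 0.001
  res <- fisher_z_compare(0.9, 50, 0.0, 50)
  expect_gt(abs(res$z), 7)
  expect_lt(res$p, 1e-3)
  expect_error(fisher_z_compare(1, 30, 0.5, 30), class = "ctifr_invalid_parameter")
  expect_error(fisher_z_compare(0.5, 3, 0.5, 30), class = "ctifr_invalid_parameter")
  # dependent-sample variant: identical correlations still give p = 1
  expect_equal(steiger_compare(0.6, 0.6, 0.5, 36)$p, 1)
})

test_that("decision curves follow the net-benefit formula", {
  # direct evaluation at pt = 0.2 with TP=11, FP=4 of n=36
  idx <- c(rep(0.8, 15), rep(0.95, 21))
  labels <- c(rep(TRUE, 11), rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 17))
  dca <- decision_curve(idx, labels, cutoff = 0.89, thresholds = c(0.2, 0.5))
  expect_equal(dca$nb_model[1], 11 / 36 - (4 / 36) * 0.25)
  expect_equal(dca$nb_model[1], 0.278, tolerance = 1e-3)
  # treat-all at pt = 0.2 with prevalence 15/36
  expect_equal(dca$nb_all[1], 15 / 36 - (21 / 36) * 0.25)
  expect_equal(dca$nb_all[1], 0.271, tolerance = 1e-3)
  expect_true(all(dca$nb_none == 0))

  # model net benefit never exceeds prevalence; FP = 0 pins NB at TP/n
  grid <- seq(0.01, 0.99, by = 0.01)
  dca <- decision_curve(idx, labels, cutoff = 0.89, thresholds = grid)
  expect_true(all(dca$nb_model <= mean(labels) + 1e-12))
  perfect <- decision_curve(ifelse(labels, 0.5, 0.95), labels,
                            cutoff = 0.89, thresholds = grid)
  expect_true(all(abs(perfect$nb_model - 15 / 36) < 1e-12))
  # treat-all tends to prevalence as pt -> 0
  expect_equal(decision_curve(idx, labels, thresholds = 1e-6)$nb_all,
               mean(labels), tolerance = 1e-5)

  expect_error(decision_curve(idx, labels, thresholds = c(0.5, 1)),
               class = "ctifr_invalid_parameter")
})
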