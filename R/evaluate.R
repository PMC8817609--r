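#' Full diagnostic evaluation of a paired per-vessel table
#'
#' Runs the complete evaluation battery of the pipeline for the computed
#' index against one or two invasive references: confusion counts and
#' metrics with exact binomial CIs, empirical AUC with DeLong CI, pairwise
#' DeLong comparison of the index against the anatomic DS% classifier
#' (when a `ds_percent` column is present), Bland-Altman agreement,
#' Pearson correlations with a Fisher r-to-z comparison across the two
#' references, and decision curves.
#'
#' @param pairs data frame with the computed index column and reference
#'   columns.
#' @param index_col name of the computed-index column.
#' @param ifr_col,ffr_col names of the invasive reference columns; either
#'   may be `NULL` if absent.
#' @param cutoff_index,cutoff_ifr,cutoff_ffr positivity cutoffs.
#' @param dca_thresholds threshold grid for the decision curves.
#' @return a list of class `diagnostic_report`.
#' @export
diagnostic_report <- function(pairs, index_col = "ifr_ct",
                              ifr_col = "ifr_invasive",
                              ffr_col = "ffr_invasive",
                              cutoff_index = 0.89, cutoff_ifr = 0.89,
                              cutoff_ffr = 0.80,
                              dca_thresholds = seq(0.01, 0.99, by = 0.01)) {
  cols <- c(index_col, ifr_col, ffr_col)
  missing_cols <- setdiff(cols[!vapply(cols, is.null, logical(1))], names(pairs))
  if (length(missing_cols)) {
    stop_invalid("missing column(s) ", paste(missing_cols, collapse = ", "),
                 "; available: ", paste(names(pairs), collapse = ", "))
  }
  index <- pairs[[index_col]]
  refs <- list()
  if (!is.null(ffr_col)) {
    refs$ffr <- list(values = pairs[[ffr_col]], cutoff = cutoff_ffr)
  }
  if (!is.null(ifr_col)) {
    refs$ifr <- list(values = pairs[[ifr_col]], cutoff = cutoff_ifr)
  }
  per_ref <- lapply(refs, function(ref) {
    labels <- ref$values <= ref$cutoff
    counts <- confusion_from_pairs(index, ref$values, cutoff_index, ref$cutoff)
    out <- list(
      counts = counts,
      metrics = diagnostic_metrics(counts),
      bland_altman = bland_altman(index, ref$values),
      correlation = stats::cor(index, ref$values)
    )
    if (any(labels) && !all(labels)) {
      out$roc <- auc_empirical(index, labels)
      out$dca <- decision_curve(index, labels, cutoff_index, dca_thresholds)
      if ("ds_percent" %in% names(pairs)) {
        # anatomic comparator: higher DS% = more diseased
        out$delong_vs_ds <- delong_compare(labels = labels,
                                           score_a = 1 - index,
                                           score_b = pairs$ds_percent)
      }
    }
    out
  })
  comparison <- NULL
  if (length(per_ref) == 2) {
    n <- length(index)
    r1 <- per_ref$ffr$correlation
    r2 <- per_ref$ifr$correlation
    if (is.finite(r1) && is.finite(r2) && abs(r1) < 1 && abs(r2) < 1 && n > 3) {
      comparison <- c(fisher_z_compare(r1, n, r2, n),
                      list(r_ffr = r1, r_ifr = r2, degenerate = FALSE))
    } else {
      # perfect or undefined correlations cannot be z-transformed
      comparison <- list(z = NA_real_, p = NA_real_, r_ffr = r1, r_ifr = r2,
                         degenerate = TRUE)
    }
  }
  structure(
    list(n = length(index), references = per_ref,
         correlation_comparison = comparison,
         cutoffs = list(index = cutoff_index, ifr = cutoff_ifr,
                        ffr = cutoff_ffr)),
    class = "diagnostic_report"
  )
}

#' Metrics table from printed confusion counts
#'
#' Bypass mode for reproducing a published performance table when only
#' the confusion counts are available, without raw per-vessel data.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return a list with `counts`, `metrics`, and `percent` (the half-up
#'   whole-percent display values).
#' @export
report_from_counts <- function(tp, fp, fn, tn) {
  counts <- confusion_counts(tp, fp, fn, tn)
  metrics <- diagnostic_metrics(counts)
  list(counts = counts, metrics = metrics, percent = metrics_percent(metrics))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic report (n = %d vessels)\n", x$n))
  for (ref in names(x$references)) {
    r <- x$references[[ref]]
    cat(sprintf("\n-- index <= %.2f vs %s <= %.2f --\n",
                x$cutoffs$index, toupper(ref), x$cutoffs[[ref]]))
    cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
                r$counts$tp, r$counts$fp, r$counts$fn, r$counts$tn))
    pct <- metrics_percent(r$metrics)
    for (m in names(pct)) {
      ci <- r$metrics[[m]]
      cat(sprintf("  %-12s %3.0f%% (%.2f-%.2f)\n", m, pct[[m]],
                  100 * ci$lower, 100 * ci$upper))
    }
    if (!is.null(r$roc)) {
      cat(sprintf("  AUC          %.2f (%.2f-%.2f)\n",
                  r$roc$auc, r$roc$lower, r$roc$upper))
    }
    cat(sprintf("  Bland-Altman bias %.3f, LoA (%.3f, %.3f)\n",
                r$bland_altman$bias, r$bland_altman$lower, r$bland_altman$upper))
    cat(sprintf("  Pearson r    %.2f\n", r$correlation))
  }
  if (!is.null(x$correlation_comparison) &&
      !isTRUE(x$correlation_comparison$degenerate)) {
    cc <- x$correlation_comparison
    cat(sprintf("\nCorrelation comparison (r = %.2f vs %.2f): z = %.3f, p = %.3f\n",
                cc$r_ffr, cc$r_ifr, cc$z, cc$p))
  }
  invisible(x)
}
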