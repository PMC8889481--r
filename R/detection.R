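#' Error matrix for hypoxemia detection at a cut-off
#'
#' Condition positive: reference SaO2 strictly below 90\% (values of exactly
#' 90 are normoxic). Predicted positive: windowed SpO2 median strictly below
#' the cut-off.
#'
#' @param pairs Hypoxia-phase pairs `data.frame`.
#' @param cutoff SpO2 cut-off, percent (default 90).
#' @return List of class `error_matrix`: `tp`, `fp`, `tn`, `fn` counts.
#' @export
error_matrix <- function(pairs, cutoff = 90) {
  if (nrow(pairs) == 0L) stop("no pairs", call. = FALSE)
  cond <- pairs$sao2 < 90
  pred <- pairs$spo2_median < cutoff
  structure(list(tp = sum(cond & pred), fp = sum(!cond & pred),
                 tn = sum(!cond & !pred), fn = sum(cond & !pred)),
            class = "error_matrix")
}

#' Rate metrics from an error matrix
#'
#' Sensitivity, specificity, positive and negative predictive values, and
#' accuracy `(TP + TN) / n`. A rate whose denominator is zero is returned
#' as `NA` with a warning, never as 0. Counts may be non-integer (supports
#' rate-derived reconstruction).
#'
#' @param m An [error_matrix()] (or any list with `tp`, `fp`, `tn`, `fn`).
#' @return Named numeric vector: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`.
#' @export
classifier_metrics <- function(m) {
  safe_div <- function(num, den, what) {
    if (den <= 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  c(sensitivity = safe_div(m$tp, m$tp + m$fn, "sensitivity"),
    specificity = safe_div(m$tn, m$tn + m$fp, "specificity"),
    ppv = safe_div(m$tp, m$tp + m$fp, "PPV"),
    npv = safe_div(m$tn, m$tn + m$fn, "NPV"),
    accuracy = safe_div(m$tp + m$tn, m$tp + m$fp + m$tn + m$fn, "accuracy"))
}

#' Reconstruct predictive values from printed rates and class counts
#'
#' Consistency bridge for published detection tables: given sensitivity,
#' specificity and the condition-positive/negative counts, rebuild the
#' (possibly fractional) error matrix `tp = sens * P`, `tn = spec * N` and
#' return all rate metrics.
#'
#' @param sens,spec Rates in \[0, 1\].
#' @param positives,negatives Condition-positive and -negative counts.
#' @return As [classifier_metrics()].
#' @export
metrics_from_rates <- function(sens, spec, positives, negatives) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            positives > 0, negatives > 0)
  tp <- sens * positives
  tn <- spec * negatives
  classifier_metrics(list(tp = tp, fn = positives - tp,
                          tn = tn, fp = negatives - tn))
}

#' ROC curve over the observed SpO2 medians
#'
#' Sweeps the predicted-positive rule `SpO2 < cutoff` over every distinct
#' observed score plus sentinels below and above the score range, yielding
#' the full curve from (0, 0) to (1, 1).
#'
#' @param pairs Hypoxia-phase pairs `data.frame` with both classes present.
#' @return `data.frame` with `cutoff`, `fpr`, `tpr`, `sensitivity`,
#'   `specificity`, ordered by increasing cut-off.
#' @export
roc_curve <- function(pairs) {
  cond <- pairs$sao2 < 90
  if (!any(cond) || all(cond))
    stop("ROC needs both classes present", call. = FALSE)
  scores <- pairs$spo2_median
  cuts <- c(sort(unique(scores)), max(scores) + 1)
  P <- sum(cond); N <- sum(!cond)
  tpr <- vapply(cuts, function(ct) sum(cond & scores < ct) / P, numeric(1))
  fpr <- vapply(cuts, function(ct) sum(!cond & scores < ct) / N, numeric(1))
  data.frame(cutoff = cuts, fpr = fpr, tpr = tpr,
             sensitivity = tpr, specificity = 1 - fpr)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over the swept curve (with the (0,0) anchor);
#' equal to the Mann-Whitney concordance probability, ties counting one
#' half.
#'
#' @param x A [roc_curve()] table, or a pairs `data.frame`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(x) {
  roc <- if (is.data.frame(x) && all(c("fpr", "tpr") %in% names(x))) x
         else roc_curve(x)
  fpr <- c(0, roc$fpr); tpr <- c(0, roc$tpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Youden-optimal SpO2 cut-off
#'
#' The cut-off maximizing Youden's J = sensitivity + specificity - 1 over
#' the ROC sweep. Ties are broken toward the higher cut-off (higher
#' sensitivity, the clinically conservative side). A degenerate sweep in
#' which J never exceeds 0 returns the highest swept cut-off with a
#' warning.
#'
#' @param pairs Hypoxia-phase pairs `data.frame`.
#' @return Cut-off in percent SpO2.
#' @export
optimal_cutoff <- function(pairs) {
  roc <- roc_curve(pairs)
  j <- roc$tpr - roc$fpr
  if (max(j) <= 0)
    warning("no cut-off improves on chance; returning the sweep end",
            call. = FALSE)
  best <- which(j == max(j))
  roc$cutoff[max(best)]
}

detection_point <- function(pairs, cutoff) {
  classifier_metrics(error_matrix(pairs, cutoff))
}

#' Detection report with bootstrap confidence intervals
#'
#' Metrics at the given cut-off and at the Youden-optimal cut-off, plus
#' AUROC, each with percentile bootstrap CIs. Resampling is stratified by
#' true class (hypoxemic / normoxic pairs resampled separately), preserving
#' prevalence. The optimal cut-off is re-derived inside each resample for
#' its own metrics. Deterministic given `seed`.
#'
#' @param pairs Hypoxia-phase pairs `data.frame`, both classes present.
#' @param cutoff Primary cut-off (default 90).
#' @param reps Bootstrap repetitions.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List of class `detection_result`: `cutoff`, `optimal_cutoff`,
#'   `n_positive`, `n_negative`, `auroc` (with CI), `at_cutoff` and
#'   `at_optimal` (metric estimates with CIs), and the `roc` table.
#' @export
detection_report <- function(pairs, cutoff = 90, reps = 10000, seed,
                             level = 0.95) {
  cond <- pairs$sao2 < 90
  if (!any(cond) || all(cond))
    stop("detection report needs both classes present", call. = FALSE)
  opt <- optimal_cutoff(pairs)
  point_fixed <- detection_point(pairs, cutoff)
  point_opt <- detection_point(pairs, opt)
  auc <- auroc(pairs)

  pos_idx <- which(cond); neg_idx <- which(!cond)
  metric_names <- names(point_fixed)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = reps, ncol = 2 * length(metric_names) + 1)
    for (b in seq_len(reps)) {
      take <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
                sample(neg_idx, length(neg_idx), replace = TRUE))
      rp <- pairs[take, , drop = FALSE]
      m_fixed <- detection_point(rp, cutoff)
      m_opt <- suppressWarnings(detection_point(rp, optimal_cutoff(rp)))
      out[b, ] <- c(m_fixed, m_opt, auroc(rp))
    }
    out
  })
  a <- (1 - level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  mk <- function(est, cols) {
    data.frame(metric = names(est), estimate = unname(est),
               ci_lo = ci[1, cols], ci_hi = ci[2, cols],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  k <- length(metric_names)
  structure(list(cutoff = cutoff, optimal_cutoff = opt,
                 n_positive = length(pos_idx), n_negative = length(neg_idx),
                 auroc = c(estimate = auc, ci_lo = unname(ci[1, 2 * k + 1]),
                           ci_hi = unname(ci[2, 2 * k + 1])),
                 at_cutoff = mk(point_fixed, seq_len(k)),
                 at_optimal = mk(point_opt, k + seq_len(k)),
                 roc = roc_curve(pairs)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result: %d hypoxemic / %d normoxic, AUROC %.3f (%.3f-%.3f)>\n",
              x$n_positive, x$n_negative, x$auroc["estimate"],
              x$auroc["ci_lo"], x$auroc["ci_hi"]))
  cat(sprintf("  cut-off %.1f:\n", x$cutoff))
  print(x$at_cutoff, digits = 3)
  cat(sprintf("  optimal cut-off %.1f:\n", x$optimal_cutoff))
  print(x$at_optimal, digits = 3)
  invisible(x)
}
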