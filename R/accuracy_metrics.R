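diffs_of <- function(pairs, sao2 = NULL) {
  if (is.data.frame(pairs)) {
    if (nrow(pairs) == 0L) stop("no pairs", call. = FALSE)
    pairs$spo2_median - pairs$sao2
  } else {
    stopifnot(length(pairs) == length(sao2))
    if (length(pairs) == 0L) stop("no pairs", call. = FALSE)
    pairs - sao2
  }
}

#' Root-mean-square error between SpO2 and SaO2
#'
#' The ISO accuracy statistic A_rms: `sqrt(mean((SpO2_i - SaO2_i)^2))`.
#'
#' @param pairs A pairs `data.frame` (columns `spo2_median`, `sao2`) or a
#'   numeric vector of SpO2 values.
#' @param sao2 SaO2 vector when `pairs` is numeric.
#' @return RMSE in percent saturation.
#' @export
rmse <- function(pairs, sao2 = NULL) {
  d <- diffs_of(pairs, sao2)
  sqrt(mean(d^2))
}

#' Mean bias (SpO2 - SaO2)
#' @inheritParams rmse
#' @return Mean difference in percent; negative means the device
#'   underestimates.
#' @export
mean_bias <- function(pairs, sao2 = NULL) mean(diffs_of(pairs, sao2))

#' Mean absolute bias
#' @inheritParams rmse
#' @return Mean of `|SpO2 - SaO2|` in percent.
#' @export
mean_abs_bias <- function(pairs, sao2 = NULL) mean(abs(diffs_of(pairs, sao2)))

#' Precision as the SD of regression residuals
#'
#' Fits SpO2 on SaO2 by ordinary least squares (the SpO2_fit line) and
#' returns the standard deviation of the residuals: the spread of the test
#' readings around the line, separating random error from calibration
#' offset. Denominator `n - 2` by default (the regression degrees of
#' freedom); `n - 1` exposed for sensitivity.
#'
#' @inheritParams rmse
#' @param ddof Residual degrees-of-freedom correction, 2 (default) or 1.
#' @return Residual SD in percent.
#' @export
precision_residual_sd <- function(pairs, sao2 = NULL, ddof = 2) {
  if (is.data.frame(pairs)) { sao2 <- pairs$sao2; y <- pairs$spo2_median }
  else y <- pairs
  n <- length(y)
  if (n < 3L) stop("precision needs at least 3 pairs", call. = FALSE)
  sxx <- sum((sao2 - mean(sao2))^2)
  if (sxx == 0)
    stop("degenerate regression: SaO2 constant in this stratum",
         call. = FALSE)
  slope <- sum((sao2 - mean(sao2)) * (y - mean(y))) / sxx
  res <- (y - mean(y)) - slope * (sao2 - mean(sao2))
  sqrt(sum(res^2) / (n - ddof))
}

#' Percentile bootstrap confidence interval for a pairwise statistic
#'
#' Resamples matched pairs with replacement (optionally whole sessions, the
#' cluster bootstrap) and returns the percentile interval of the statistic.
#' Deterministic given `seed`.
#'
#' @param statistic Function of a pairs `data.frame` returning one number,
#'   e.g. [rmse()].
#' @param pairs Pairs `data.frame` with at least 2 rows.
#' @param reps Bootstrap repetitions (study default 10,000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param cluster Optional column name (e.g. `"session_id"`) to resample
#'   whole clusters instead of rows.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(statistic, pairs, reps = 10000, seed,
                         level = 0.95, cluster = NULL) {
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  if (n < 2L) stop("bootstrap needs at least 2 pairs", call. = FALSE)
  stats_v <- with_seed(seed, {
    if (is.null(cluster)) {
      vapply(seq_len(reps), function(i) {
        statistic(pairs[sample.int(n, n, replace = TRUE), , drop = FALSE])
      }, numeric(1))
    } else {
      ids <- unique(pairs[[cluster]])
      idx_by <- split(seq_len(n), pairs[[cluster]])
      vapply(seq_len(reps), function(i) {
        take <- unlist(idx_by[sample(ids, length(ids), replace = TRUE)],
                       use.names = FALSE)
        statistic(pairs[take, , drop = FALSE])
      }, numeric(1))
    }
  })
  a <- (1 - level) / 2
  q <- unname(stats::quantile(stats_v, c(a, 1 - a), type = 7, na.rm = TRUE))
  c(lo = q[1], hi = q[2])
}

#' Bland-Altman agreement statistics
#'
#' Mean difference and 95\% limits of agreement,
#' `bias +/- 1.96 * SD(differences)` (SD with `n - 1`).
#'
#' @inheritParams rmse
#' @return List with `mean_bias`, `loa_lo`, `loa_hi`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pairs, sao2 = NULL) {
  d <- diffs_of(pairs, sao2)
  if (length(d) < 2L) stop("Bland-Altman needs at least 2 pairs",
                           call. = FALSE)
  b <- mean(d); s <- stats::sd(d)
  list(mean_bias = b, loa_lo = b - 1.96 * s, loa_hi = b + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Accuracy report for one stratum of pairs
#'
#' Computes n, RMSE with a percentile bootstrap CI, mean bias, mean absolute
#' bias, and residual-SD precision. Precision is `NA` (with a warning
#' suppressed into `NA`) when the stratum's SaO2 is constant or n < 3.
#'
#' @param pairs Pairs `data.frame`.
#' @param reps,seed,level Bootstrap settings, see [bootstrap_ci()].
#' @param stratum Label attached to the report row.
#' @return One-row `data.frame`: `stratum, n, rmse, rmse_lo, rmse_hi,
#'   mean_bias, mean_abs_bias, precision`.
#' @export
accuracy_report <- function(pairs, reps = 10000, seed, level = 0.95,
                            stratum = "all") {
  ci <- if (nrow(pairs) >= 2L)
    bootstrap_ci(rmse, pairs, reps = reps, seed = seed, level = level)
  else c(lo = NA_real_, hi = NA_real_)
  prec <- tryCatch(precision_residual_sd(pairs), error = function(e) NA_real_)
  data.frame(stratum = stratum, n = nrow(pairs), rmse = rmse(pairs),
             rmse_lo = unname(ci["lo"]), rmse_hi = unname(ci["hi"]),
             mean_bias = mean_bias(pairs), mean_abs_bias = mean_abs_bias(pairs),
             precision = prec, stringsAsFactors = FALSE)
}

#' Accuracy table over device x stratum cells
#'
#' The shape of the study's accuracy tables: one row per combination of the
#' grouping columns, each carrying the full [accuracy_report()] row.
#'
#' @param pairs Pairs `data.frame`.
#' @param by Grouping columns, e.g. `c("device_id", "stratum")` or
#'   `c("device_id", "subgroup")`.
#' @param reps,seed,level Bootstrap settings; per-cell seeds are split from
#'   `seed` deterministically.
#' @return `data.frame`, one row per non-empty cell.
#' @export
accuracy_table <- function(pairs, by = c("device_id", "stratum"),
                           reps = 10000, seed, level = 0.95) {
  key <- interaction(pairs[by], drop = TRUE, lex.order = TRUE)
  cells <- split(pairs, key)
  seeds <- split_seed(seed, length(cells))
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    rep_row <- accuracy_report(cell, reps = reps, seed = seeds[i],
                               level = level,
                               stratum = names(cells)[i])
    rows[[i]] <- cbind(cell[1L, by, drop = FALSE], rep_row[-1L],
                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ISO-style compliance verdict for an accuracy report
#'
#' Pass requires RMSE at or below 4 percentage points and a bootstrap CI
#' upper bound at or below 8 (both inclusive).
#'
#' @param report One-row output of [accuracy_report()].
#' @return List `pass` (logical) and `reasons` (character, empty on pass).
#' @export
iso_compliance <- function(report) {
  reasons <- character()
  if (!is.finite(report$rmse) || report$rmse > 4)
    reasons <- c(reasons, sprintf("RMSE %.2f exceeds 4%%", report$rmse))
  if (!is.finite(report$rmse_hi) || report$rmse_hi > 8)
    reasons <- c(reasons,
                 sprintf("RMSE CI upper bound %.2f exceeds 8%%",
                         report$rmse_hi))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' ISO-style sample-size and balance check
#'
#' Pass requires at least 200 pairs from at least 10 distinct subjects, with
#' the SaO2 values spread over 70-100\%: no 5-point bin may hold more than
#' `max_bin_frac` of the points (a documented proxy for the standard's
#' balance requirement).
#'
#' @param pairs Pairs `data.frame` carrying `session_id` and `sao2`.
#' @param min_points,min_subjects,bin_width,max_bin_frac Rule parameters.
#' @return List `pass` and `reasons`.
#' @export
iso_sample_check <- function(pairs, min_points = 200, min_subjects = 10,
                             bin_width = 5, max_bin_frac = 0.4) {
  reasons <- character()
  n <- nrow(pairs)
  if (n < min_points)
    reasons <- c(reasons, sprintf("%d pairs < %d required", n, min_points))
  ns <- length(unique(pairs$session_id))
  if (ns < min_subjects)
    reasons <- c(reasons, sprintf("%d subjects < %d required", ns,
                                  min_subjects))
  if (n > 0L) {
    bins <- cut(pairs$sao2, breaks = seq(70, 100, by = bin_width),
                include.lowest = TRUE, right = FALSE)
    frac <- max(table(bins)) / n
    if (frac > max_bin_frac)
      reasons <- c(reasons,
                   sprintf("%.0f%% of points in one %g-point SaO2 bin (max %.0f%%)",
                           100 * frac, bin_width, 100 * max_bin_frac))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
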