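check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  for (g in groups)
    if (length(g) < 2L)
      stop("every group needs at least 2 observations", call. = FALSE)
  groups
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA computed from sums of squares, with
#' the F statistic referred to F(k - 1, N - k).
#'
#' @param groups Named list of numeric vectors, one per group (each n >= 2).
#' @return List of class `comparison_result`: `test`, `statistic`,
#'   `p_value`, `df`, plus the mean-square components.
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (ss_within == 0)
    stop("zero within-group variance: ANOVA undefined", call. = FALSE)
  ms_b <- ss_between / (k - 1)
  ms_w <- ss_within / (N - k)
  f <- ms_b / ms_w
  structure(list(test = "one-way ANOVA", statistic = f,
                 p_value = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
                 df = c(k - 1, N - k), ms_within = ms_w,
                 group_means = means, group_n = n),
            class = "comparison_result")
}

#' Tukey-Kramer all-pairs comparison
#'
#' Post hoc pairwise comparison of group means using studentized-range
#' critical values with the Tukey-Kramer unequal-n standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))`. Returns the significant-pair set used
#' to annotate accuracy tables.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Family-wise significance level.
#' @return `comparison_result` with a `pairs` `data.frame` (`g1`, `g2`,
#'   `diff`, `q`, `p_adj`, `significant`) and `significant_pairs`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  aov0 <- one_way_anova(groups)
  k <- length(groups)
  N <- sum(aov0$group_n)
  combs <- utils::combn(names(groups), 2)
  rows <- apply(combs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(aov0$ms_within / 2 *
                 (1 / aov0$group_n[[i]] + 1 / aov0$group_n[[j]]))
    d <- aov0$group_means[[i]] - aov0$group_means[[j]]
    q <- abs(d) / se
    data.frame(g1 = i, g2 = j, diff = d, q = q,
               p_adj = stats::ptukey(q, k, N - k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p_adj < alpha
  structure(list(test = "Tukey-Kramer", statistic = max(tab$q),
                 p_value = min(tab$p_adj), alpha = alpha, pairs = tab,
                 significant_pairs = tab[tab$significant,
                                         c("g1", "g2"), drop = FALSE]),
            class = "comparison_result")
}

#' Levene test of variance homogeneity
#'
#' One-way ANOVA on absolute deviations from the group center: the mean in
#' the classic form (default), or the median (Brown-Forsythe variant).
#'
#' @param groups Named list of numeric vectors.
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return `comparison_result`.
#' @export
levene <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- check_groups(groups)
  cfun <- if (center == "mean") mean else stats::median
  absdev <- lapply(groups, function(g) abs(g - cfun(g)))
  res <- tryCatch(one_way_anova(absdev), error = function(e)
    stop("Levene test degenerate: ", conditionMessage(e), call. = FALSE))
  res$test <- sprintf("Levene (%s-centered)", center)
  res
}

# exact signed-rank null distribution over midranks (handles tied ranks by
# doubling to integers); returns P(W+ <= w) and P(W+ >= w)
signed_rank_exact_p <- function(ranks2, w2) {
  # generating-function DP over sum of included doubled-ranks
  total <- sum(ranks2)
  dp <- numeric(total + 1L)
  dp[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dp[seq_len(total + 1L - r)])
    dp <- dp + shifted
  }
  dp <- dp / sum(dp)
  lo <- sum(dp[seq_len(w2 + 1L)])              # P(W2 <= w2)
  hi <- sum(dp[(w2 + 1L):(total + 1L)])        # P(W2 >= w2)
  c(lo = lo, hi = hi)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the nonzero paired differences `y - x`.
#' Zero differences are dropped (Wilcoxon convention; `zero_method =
#' "pratt"` ranks them first and then discards their contribution). The
#' null distribution is exact (full convolution over midranks) for n <= 25
#' and a normal approximation with tie correction and continuity correction
#' above.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for the exact distribution.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @return `comparison_result` with `statistic` (W+, the positive-rank sum)
#'   and `p_value`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25,
                            zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- y - x
  if (all(d == 0))
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  if (n <= exact_max && zero_method == "wilcox") {
    p2 <- signed_rank_exact_p(as.integer(round(2 * r)),
                              as.integer(round(2 * w_plus)))
    p <- min(1, 2 * min(p2))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(test = "Wilcoxon signed-rank (paired)", statistic = w_plus,
                 p_value = p, n_used = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g, p = %.4g>\n", x$test, x$statistic,
              x$p_value))
  if (!is.null(x$significant_pairs) && nrow(x$significant_pairs))
    cat("  significant pairs:",
        paste(x$significant_pairs$g1, x$significant_pairs$g2, sep = "~",
              collapse = ", "), "\n")
  invisible(x)
}

#' Between-stratum comparison battery for one metric
#'
#' Groups the paired differences by stratum and runs the table-footnote
#' battery: one-way ANOVA plus Tukey-Kramer on the mean (or absolute-mean)
#' bias, or the Levene test for precision.
#'
#' @param pairs Pairs `data.frame`.
#' @param metric `"bias"`, `"absbias"`, or `"precision"`.
#' @param by Grouping column (`"stratum"`, `"subgroup"`, or `"device_id"`).
#' @param alpha Significance level for the post hoc set.
#' @return List with the omnibus `comparison_result` and, for bias metrics,
#'   the `tukey` result.
#' @export
compare_strata <- function(pairs, metric = c("bias", "absbias", "precision"),
                           by = "stratum", alpha = 0.05) {
  metric <- match.arg(metric)
  d <- pairs$spo2_median - pairs$sao2
  groups <- split(d, pairs[[by]])
  groups <- groups[lengths(groups) >= 2L]
  if (metric == "absbias") groups <- lapply(groups, abs)
  if (metric == "precision") {
    res <- levene(groups)
    list(omnibus = res, tukey = NULL)
  } else {
    list(omnibus = one_way_anova(groups),
         tukey = tukey_kramer(groups, alpha = alpha))
  }
}
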