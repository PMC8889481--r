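test_that("rmse, bias and |bias| match hand-evaluated cases", {
  # zero error
  expect_equal(rmse(make_pairs(c(95, 90), c(95, 90))), 0)
  # differences [+2, -2] -> rmse 2, bias 0, |bias| 2
  p <- make_pairs(c(97, 88), c(95, 90))
  expect_equal(rmse(p), 2)
  expect_equal(mean_bias(p), 0)
  expect_equal(mean_abs_bias(p), 2)
  # differences [3, 4] -> sqrt(12.5)
  expect_equal(rmse(make_pairs(c(98, 94), c(95, 90))), sqrt(12.5))
  # single pair (90, 88)
  p1 <- make_pairs(90, 88)
  expect_equal(mean_bias(p1), 2)
  expect_equal(mean_abs_bias(p1), 2)
  # constant negative offset
  p2 <- make_pairs(c(93.08, 88.08, 83.08) , c(95, 90, 85))
  expect_equal(mean_bias(p2), -1.92)
  expect_error(rmse(make_pairs(numeric(), numeric())), "no pairs")
})

test_that("rmse^2 = bias^2 + (n-1)/n * var(diff) on random inputs", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:300, 1)
    p <- random_pairs(n, bias = runif(1, -5, 5), sd = runif(1, 0, 4))
    d <- p$spo2_median - p$sao2
    expect_equal(rmse(p)^2,
                 mean_bias(p)^2 + (n - 1) / n * var(d),
                 tolerance = 1e-12)
    expect_gte(rmse(p) + 1e-12, abs(mean_bias(p)))
    expect_gte(mean_abs_bias(p) + 1e-12, abs(mean_bias(p)))
  }
})

test_that("precision equals the residual SD of an independent OLS solve", {
  # exact line -> zero residual spread
  sao2 <- c(80, 85, 90, 95, 100)
  expect_equal(precision_residual_sd(make_pairs(0.9 * sao2 + 8, sao2)), 0)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    p <- random_pairs(n, bias = -1, sd = 2)
    fit <- lm(spo2_median ~ sao2, data = p)   # oracle
    expect_equal(precision_residual_sd(p),
                 sqrt(sum(residuals(fit)^2) / (n - 2)))
    expect_equal(precision_residual_sd(p, ddof = 1),
                 sqrt(sum(residuals(fit)^2) / (n - 1)))
  }
  expect_error(precision_residual_sd(make_pairs(c(90, 91, 92), rep(95, 3))),
               "degenerate regression")
})

test_that("precision <= SD of differences when the fit beats unit slope", {
  set.seed(12)
  for (i in 1:20) {
    sao2 <- runif(60, 80, 100)
    # true slope far from 1 so the fitted line clearly improves on it
    p <- make_pairs(0.5 * sao2 + 45 + rnorm(60, 0, 1), sao2)
    expect_lte(precision_residual_sd(p),
               sd(p$spo2_median - p$sao2) + 1e-12)
  }
})

test_that("bootstrap CI: determinism, degenerate inputs, hand-made widths", {
  p <- random_pairs(40, bias = -2, sd = 2)
  ci1 <- bootstrap_ci(rmse, p, reps = 500, seed = 42)
  ci2 <- bootstrap_ci(rmse, p, reps = 500, seed = 42)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, bootstrap_ci(rmse, p, reps = 500, seed = 43)))
  expect_lte(ci1[["lo"]], rmse(p))
  expect_gte(ci1[["hi"]], rmse(p))

  # all pairs identical -> zero-variance resamples -> point interval
  pid <- make_pairs(rep(92, 10), rep(90, 10))
  expect_equal(unname(bootstrap_ci(rmse, pid, reps = 100, seed = 1)),
               c(2, 2))
  expect_error(bootstrap_ci(rmse, pid[1, ], reps = 10, seed = 1),
               "at least 2")

  # cluster bootstrap resamples whole sessions
  pc <- rbind(make_pairs(rep(95, 5), rep(95, 5), session_id = "a"),
              make_pairs(rep(92, 5), rep(95, 5), session_id = "b"))
  cic <- bootstrap_ci(rmse, pc, reps = 200, seed = 9,
                      cluster = "session_id")
  # resamples are all-a (rmse 0), mixed (sqrt(4.5)), or all-b (3)
  expect_true(all(c(cic) %in% c(0, sqrt(4.5), 3)))
})

test_that("bootstrap intervals narrow with n", {
  set.seed(77)
  width <- function(n) {
    p <- random_pairs(n, bias = -1.9, sd = 2.7)
    ci <- bootstrap_ci(rmse, p, reps = 400, seed = sample.int(1e6, 1))
    ci[["hi"]] - ci[["lo"]]
  }
  w50 <- replicate(30, width(50))
  w200 <- replicate(30, width(200))
  expect_lt(median(w200), median(w50))
})

test_that("Bland-Altman matches its closed form", {
  # all differences zero
  ba0 <- bland_altman(make_pairs(rep(95, 5), rep(95, 5)))
  expect_equal(unlist(ba0[c("mean_bias", "loa_lo", "loa_hi")]),
               c(mean_bias = 0, loa_lo = 0, loa_hi = 0))
  # two pairs, differences {0, 2}
  ba <- bland_altman(make_pairs(c(95, 97), c(95, 95)))
  expect_equal(ba$mean_bias, 1)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_lo, 1 - 1.96 * sqrt(2))
  expect_equal(ba$loa_hi, 1 + 1.96 * sqrt(2))
  # large-n Monte Carlo agreement with bias +/- 1.96 sd
  set.seed(3)
  pl <- random_pairs(1e4, bias = -1.9, sd = 2.7)
  bal <- bland_altman(pl)
  expect_equal(bal$loa_lo, -1.9 - 1.96 * 2.7, tolerance = 0.05)
  expect_equal(bal$loa_hi, -1.9 + 1.96 * 2.7, tolerance = 0.05)
  expect_error(bland_altman(make_pairs(95, 95)), "at least 2")
})

test_that("ISO compliance rule is inclusive at both thresholds", {
  rep_row <- function(rmse, hi) data.frame(rmse = rmse, rmse_hi = hi)
  expect_true(iso_compliance(rep_row(2.67, 3.06))$pass)
  v <- iso_compliance(rep_row(4.68, 7.72))
  expect_false(v$pass)
  expect_match(v$reasons, "RMSE 4.68")
  expect_true(iso_compliance(rep_row(4.0, 8.0))$pass)    # boundary
  expect_false(iso_compliance(rep_row(3.0, 8.01))$pass)
})

test_that("ISO sample check enforces count, subjects and balance", {
  set.seed(5)
  big <- do.call(rbind, lapply(1:33, function(i)
    make_pairs(runif(7, 80, 100), runif(7, 80, 100),
               session_id = sprintf("s%02d", i))))
  expect_true(iso_sample_check(big)$pass)            # 231 pairs, 33 subjects
  expect_false(iso_sample_check(big[1:199, ])$pass)  # count edge
  few <- big; few$session_id <- rep(c("a", "b"), length.out = nrow(big))
  expect_false(iso_sample_check(few)$pass)           # too few subjects
  lump <- big; lump$sao2 <- 100                      # all in one bin
  expect_false(iso_sample_check(lump)$pass)
  expect_match(iso_sample_check(lump)$reasons, "bin")
})

test_that("accuracy_table produces one row per device x stratum cell", {
  set.seed(9)
  pairs <- rbind(
    make_pairs(rnorm(20, 93, 2), rep(95, 20) + rnorm(20), device_id = "a",
               stratum = "rest"),
    make_pairs(rnorm(20, 88, 2), rep(90, 20) + rnorm(20), device_id = "a",
               stratum = "task"),
    make_pairs(rnorm(20, 94, 2), rep(95, 20) + rnorm(20), device_id = "b",
               stratum = "rest"))
  tab <- accuracy_table(pairs, reps = 200, seed = 4)
  expect_identical(nrow(tab), 3L)
  expect_setequal(paste(tab$device_id, tab$stratum),
                  c("a rest", "a task", "b rest"))
  expect_true(all(tab$rmse_lo <= tab$rmse & tab$rmse <= tab$rmse_hi))
  expect_true(all(tab$rmse >= abs(tab$mean_bias)))
  # deterministic under the same seed
  expect_identical(tab, accuracy_table(pairs, reps = 200, seed = 4))
})
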