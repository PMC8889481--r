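test_that("one-way ANOVA agrees with the linear-model oracle", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3)))
    names(groups) <- letters[seq_len(k)]
    res <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = rep(names(groups), lengths(groups)))
    oracle <- anova(lm(y ~ g, data = df))
    expect_equal(res$statistic, oracle$`F value`[1])
    expect_equal(res$p_value, oracle$`Pr(>F)`[1])
  }
})

test_that("two-group ANOVA F is the squared pooled t statistic", {
  set.seed(21)
  for (i in 1:10) {
    g <- list(a = rnorm(15, 0, 2), b = rnorm(25, 1, 2))
    res <- one_way_anova(g)
    tt <- t.test(g$a, g$b, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2)
    expect_equal(res$p_value, tt$p.value)
  }
})

test_that("ANOVA degenerate and invariance behaviour", {
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group variance")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
  set.seed(2)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  shifted <- lapply(g, `+`, 100)
  expect_equal(one_way_anova(shifted)$statistic,
               one_way_anova(g)$statistic)
  # equal means, large n: F near 1-ish, p far from 0
  gl <- list(a = rnorm(500), b = rnorm(500))
  expect_gt(one_way_anova(gl)$p_value, 0.001)
})

test_that("Tukey-Kramer agrees with TukeyHSD and detects a shifted group", {
  set.seed(33)
  for (i in 1:10) {
    groups <- list(a = rnorm(12), b = rnorm(18, 0.5), c = rnorm(15, 1))
    res <- tukey_kramer(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(names(groups), lengths(groups))))
    hsd <- TukeyHSD(aov(y ~ g, data = df))$g   # oracle
    key <- paste(res$pairs$g2, res$pairs$g1, sep = "-")
    expect_equal(unname(res$pairs$p_adj), unname(hsd[key, "p adj"]),
                 tolerance = 1e-6)
  }
  # one group shifted by 10 SDs: exactly its two pairs are significant
  set.seed(8)
  g3 <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 10))
  res3 <- tukey_kramer(g3)
  sig <- res3$pairs[res3$pairs$significant, ]
  expect_identical(nrow(sig), 2L)
  expect_true(all(apply(sig[c("g1", "g2")], 1, function(r) "c" %in% r)))
})

test_that("k=2 Tukey-Kramer significance matches the pooled t test", {
  set.seed(44)
  agree <- vapply(1:50, function(i) {
    g <- list(a = rnorm(12, 0, 2), b = rnorm(20, runif(1, 0, 2), 2))
    tk <- tukey_kramer(g)$pairs$significant
    tt <- t.test(g$a, g$b, var.equal = TRUE)$p.value < 0.05
    identical(tk, tt)
  }, logical(1))
  expect_true(all(agree))
})

test_that("Levene: location-shift invariance and spread sensitivity", {
  set.seed(55)
  base <- rnorm(40)
  # shifted copies have identical spreads: statistic exactly 0
  res0 <- levene(list(a = base, b = base + 5, c = base - 2))
  expect_equal(res0$statistic, 0)
  # per-group mean shifts leave the statistic unchanged
  g <- list(a = rnorm(30, 0, 1), b = rnorm(30, 0, 2))
  expect_equal(levene(list(a = g$a + 10, b = g$b - 3))$statistic,
               levene(g)$statistic)
  # SD ratio 3 at n=50: should reject most of the time
  rejections <- vapply(1:40, function(i) {
    levene(list(a = rnorm(50, 0, 1), b = rnorm(50, 0, 3)))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
  # Brown-Forsythe option
  expect_match(levene(g, center = "median")$test, "median")
  expect_error(levene(list(a = c(1, 1), b = c(2, 2))), "degenerate")
})

test_that("exact Wilcoxon matches brute-force sign enumeration, n <= 10", {
  brute_p <- function(d) {   # oracle: enumerate all 2^n sign patterns
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    ws <- vapply(0:(2^n - 1), function(mask) {
      signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
      sum(r[signs])
    }, numeric(1))
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  set.seed(66)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    d <- round(rnorm(n, 0, 2), 1)
    d[d == 0] <- 0.1
    if (i %% 3 == 0) d[1] <- d[min(2, n)]  # inject ties in |d|
    res <- wilcoxon_paired(rep(0, n), d)
    expect_equal(res$p_value, brute_p(d), tolerance = 1e-12)
  }
  # tie-free cases also agree with the base-R exact test
  for (i in 1:10) {
    d <- runif(12, -2, 2)
    expect_equal(wilcoxon_paired(rep(0, 12), d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("Wilcoxon handles the documented special cases", {
  x <- rnorm(15)
  expect_error(wilcoxon_paired(x, x), "all paired differences are zero")
  # constant positive shift, n = 15: p = 2 / 2^15
  res <- wilcoxon_paired(x, x + 1.87)
  expect_equal(res$p_value, 2 / 2^15)
  expect_lt(res$p_value, 0.001)
  # zeros dropped under the default convention
  res2 <- wilcoxon_paired(c(0, 0, 0, 0), c(0, 1, 2, 3))
  expect_identical(res2$n_used, 3L)
  # large-n path: close to the base-R normal approximation
  set.seed(9)
  d <- rnorm(60, 0.3)
  expect_equal(wilcoxon_paired(rep(0, 60), d)$p_value,
               wilcox.test(d, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("compare_strata dispatches the right battery per metric", {
  set.seed(13)
  pairs <- rbind(
    make_pairs(rnorm(25, 93, 1), rnorm(25, 95, 1), stratum = "rest"),
    make_pairs(rnorm(25, 87, 3), rnorm(25, 95, 1), stratum = "rubbing"),
    make_pairs(rnorm(25, 92, 1), rnorm(25, 95, 1), stratum = "tapping"))
  res_b <- compare_strata(pairs, "bias")
  expect_match(res_b$omnibus$test, "ANOVA")
  expect_lt(res_b$omnibus$p_value, 0.01)
  expect_true(any(res_b$tukey$pairs$significant))
  res_p <- compare_strata(pairs, "precision")
  expect_match(res_p$omnibus$test, "Levene")
  expect_null(res_p$tukey)
})
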