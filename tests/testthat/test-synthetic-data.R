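test_that("simulation is deterministic given (config, seed)", {
  cfg <- test_config()
  devs <- default_device_models()
  a <- simulate_study(cfg, devs, 2, seed = 123)
  b <- simulate_study(cfg, devs, 2, seed = 123)
  expect_identical(a, b)
  c <- simulate_study(cfg, devs, 2, seed = 124)
  expect_false(identical(a, c))
})

test_that("noise-free movement-phase trajectory is constant at baseline", {
  cfg <- test_config(sts_dip_mean = 0, sts_dip_sd = 0, plateau_noise_sd = 0,
                     baseline_sd = 0)
  traj <- simulate_sao2_trajectory(cfg, seed = 5)
  mov <- traj$t <= max(traj$annotations$stop)
  expect_equal(unique(traj$sao2[mov]), cfg$baseline_mean)
})

test_that("plateau means sit within 0.5% of their targets", {
  cfg <- test_config()
  for (seed in c(2, 31)) {
    traj <- simulate_sao2_trajectory(cfg, seed = seed)
    pl <- traj$plateaus
    levels <- c(traj$baseline, cfg$hypoxia_targets)
    for (i in seq_len(nrow(pl))) {
      sel <- traj$t >= pl$start[i] & traj$t <= pl$stop[i]
      expect_lt(abs(mean(traj$sao2[sel]) - levels[i]), 0.5)
    }
  }
})

test_that("trajectory respects configured durations and plateau count", {
  cfg <- test_config(hypoxia_targets = c(95, 90))
  traj <- simulate_sao2_trajectory(cfg, seed = 9)
  # 3 plateaus: baseline + 2 targets; detected by level-crossing
  expect_identical(nrow(traj$plateaus), 3L)
  expect_equal(max(traj$t), traj$plateaus$stop[3])
  crossings <- sum(diff(traj$sao2 < 92.5) != 0)
  expect_gte(crossings, 1)
  expect_error(protocol_config(plateau_duration = 30), "plateau_duration")
})

test_that("device model applies bias, smoothing, artifacts, dropout as stated", {
  cfg <- test_config(plateau_noise_sd = 0, sts_dip_mean = 0, sts_dip_sd = 0,
                     baseline_sd = 0)
  traj <- simulate_sao2_trajectory(cfg, seed = 3)

  # all-zero model: stream equals (here unsmoothed) trajectory
  s0 <- simulate_device_stream(traj, ideal_device(), seed = 4)
  expect_equal(s0$spo2, traj$sao2)

  # pure systematic bias: exact offset everywhere
  dev <- device_model("biased", systematic_bias = -1.92, scatter_sd = 0,
                      smoothing_window = 1)
  s1 <- simulate_device_stream(traj, dev, seed = 4)
  expect_equal(s1$spo2, pmax(0, traj$sao2 - 1.92))

  # dropout probability 1 inside rubbing window: no samples there
  dev2 <- device_model("droppy", dropout_prob_by_task = c(rubbing = 1))
  s2 <- simulate_device_stream(traj, dev2, seed = 4)
  ann <- traj$annotations
  rub <- ann[ann$label == "rubbing", ]
  inside <- s2$t >= rub$start & s2$t < rub$stop
  expect_true(all(is.na(s2$spo2[inside])))
  expect_true(all(!is.na(s2$spo2[!inside])))
})

test_that("session placement of references matches the protocol", {
  cfg <- test_config()
  s <- simulate_session(cfg, list(ideal_device()), seed = 21)
  refs <- s$references
  expect_identical(sum(refs$phase == "movement"), 7L)   # incl. at-rest
  expect_identical(sum(refs$phase == "hypoxia"), 7L)    # 100..80
  expect_setequal(refs$label[refs$phase == "hypoxia"], target_labels())

  s2 <- simulate_session(test_config(include_sts_midpoint = TRUE),
                         list(ideal_device()), seed = 21)
  expect_identical(sum(s2$references$kind == "mid-task"), 1L)
  expect_identical(nrow(s2$references), 15L)
})

test_that("noise-free end-to-end study yields zero RMSE", {
  cfg <- test_config(plateau_noise_sd = 0, abg_analyzer_sd = 0,
                     sts_dip_mean = 0, sts_dip_sd = 0)
  st <- simulate_study(cfg, list(ideal_device()), 2, seed = 8,
                       n_sts_midpoint = 0)
  ph <- match_study(st, "hypoxia")
  expect_equal(rmse(ph), 0)
  pm <- match_study(st, "movement")
  # movement windows see constant baseline; medians equal the reference
  expect_equal(rmse(pm), 0)
})

test_that("study-level bookkeeping: 33 sessions give 231 hypoxia references", {
  cfg <- test_config()
  st <- simulate_study(cfg, list(ideal_device()), 33, seed = 14,
                       n_sts_midpoint = 0)
  nh <- sum(vapply(st$sessions,
                   function(s) sum(s$references$phase == "hypoxia"),
                   integer(1)))
  expect_identical(nh, 231L)
})

test_that("downstream estimates recover injected device parameters", {
  # no-motion contract: >= 500 pairs, bias estimate within 3 SE of truth
  cfg <- test_config()
  dev <- device_model("d", systematic_bias = -1.5, scatter_sd = 2,
                      smoothing_window = 1)
  st <- simulate_study(cfg, list(dev), 75, seed = 99, n_sts_midpoint = 0)
  ph <- match_study(st, "hypoxia")
  expect_gte(nrow(ph), 500)
  d <- ph$spo2_median - ph$sao2
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (-1.5)), 3 * se)
})

test_that("motion artifacts with negative mean depress task-window bias", {
  cfg <- test_config()
  dev <- device_model("d", scatter_sd = 1, smoothing_window = 1,
                      artifact_bias_by_task = c(rubbing = -6, tapping = -4),
                      artifact_sd_by_task = c(rubbing = 3, tapping = 3))
  st <- simulate_study(cfg, list(dev), 10, seed = 5, n_sts_midpoint = 0)
  pm <- match_study(st, "movement")
  bias_by <- tapply(pm$spo2_median - pm$sao2, pm$stratum, mean)
  expect_lt(bias_by[["rubbing"]], bias_by[["at-rest"]])
  expect_lt(bias_by[["tapping"]], bias_by[["at-rest"]])
})
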