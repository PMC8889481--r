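#' Describe a simulated pulse-oximeter device
#'
#' The error model applied on top of the true SaO2 trajectory:
#' vendor-style moving-average smoothing, an additive systematic bias
#' (optionally varying linearly with SaO2), white measurement scatter,
#' task-specific motion artifacts (extra Gaussian noise with a usually
#' negative mean, modelling underestimation during motion), and
#' task-specific dropout.
#'
#' @param device_id Device label.
#' @param systematic_bias Additive bias at SaO2 = 100, percent.
#' @param bias_slope Change in bias per percent below 100 (0 = constant).
#' @param scatter_sd SD of the 1 Hz white measurement noise, percent.
#' @param smoothing_window Trailing moving-average length, seconds (>= 1).
#' @param artifact_bias_by_task,artifact_sd_by_task Named numeric vectors
#'   (task label -> percent) of artifact mean and SD inside task windows.
#' @param dropout_prob_by_task Named numeric vector of per-sample dropout
#'   probability inside task windows.
#' @param dropout_prob_base Baseline per-sample dropout probability.
#' @return An object of class `device_model`.
#' @export
device_model <- function(device_id, systematic_bias = 0, bias_slope = 0,
                         scatter_sd = 0, smoothing_window = 1,
                         artifact_bias_by_task = numeric(),
                         artifact_sd_by_task = numeric(),
                         dropout_prob_by_task = numeric(),
                         dropout_prob_base = 0) {
  stopifnot(scatter_sd >= 0, smoothing_window >= 1,
            all(artifact_sd_by_task >= 0),
            all(dropout_prob_by_task >= 0 & dropout_prob_by_task <= 1),
            dropout_prob_base >= 0, dropout_prob_base <= 1)
  for (v in list(artifact_bias_by_task, artifact_sd_by_task,
                 dropout_prob_by_task))
    if (length(v) && any(!names(v) %in% task_labels()))
      stop("unknown task label in device model: ",
           names(v)[which(!names(v) %in% task_labels())[1]], call. = FALSE)
  structure(list(device_id = device_id, systematic_bias = systematic_bias,
                 bias_slope = bias_slope, scatter_sd = scatter_sd,
                 smoothing_window = smoothing_window,
                 artifact_bias_by_task = artifact_bias_by_task,
                 artifact_sd_by_task = artifact_sd_by_task,
                 dropout_prob_by_task = dropout_prob_by_task,
                 dropout_prob_base = dropout_prob_base),
            class = "device_model")
}

#' Default roster of four simulated devices
#'
#' Hypoxia-phase bias and scatter magnitudes match the scale reported for a
#' bedside monitor and three finger-worn wearables in controlled-desaturation
#' validations (bias within about +-2\%, scatter near 3\%); motion-artifact
#' means follow the typical pattern where rubbing, tapping, page turning and
#' tablet use depress the reading while rest, sit-to-stand and drinking
#' barely do.
#'
#' @return Named list of [device_model()] objects.
#' @export
default_device_models <- function() {
  art <- function(...) c(...)
  list(
    bedside = device_model(
      "bedside", systematic_bias = 0.5, scatter_sd = 2.6,
      smoothing_window = 4,
      artifact_bias_by_task = art(rubbing = -6.0, tapping = -2.5,
                                  `turning-pages` = -3.5, tablet = -0.5),
      artifact_sd_by_task = art(rubbing = 6.5, tapping = 7.0,
                                `turning-pages` = 5.5, tablet = 1.5),
      dropout_prob_by_task = art(rubbing = 0.05, tapping = 0.05),
      dropout_prob_base = 0.01),
    "checkme-o2" = device_model(
      "checkme-o2", systematic_bias = -0.2, scatter_sd = 3.1,
      smoothing_window = 4,
      artifact_bias_by_task = art(rubbing = -6.2, tapping = -2.6,
                                  `turning-pages` = -6.0, tablet = -2.9),
      artifact_sd_by_task = art(rubbing = 5.8, tapping = 3.0,
                                `turning-pages` = 5.1, tablet = 2.9),
      dropout_prob_by_task = art(rubbing = 0.08, tapping = 0.08,
                                 `turning-pages` = 0.05),
      dropout_prob_base = 0.02),
    ap20 = device_model(
      "ap20", systematic_bias = -0.3, scatter_sd = 2.8,
      smoothing_window = 4,
      artifact_bias_by_task = art(rubbing = -9.9, tapping = -9.8,
                                  `turning-pages` = -6.5, tablet = -2.2),
      artifact_sd_by_task = art(rubbing = 6.9, tapping = 7.5,
                                `turning-pages` = 5.6, tablet = 7.9),
      dropout_prob_by_task = art(rubbing = 0.08, tapping = 0.10,
                                 `turning-pages` = 0.15),
      dropout_prob_base = 0.02),
    wristox = device_model(
      "wristox", systematic_bias = -1.9, scatter_sd = 2.7,
      smoothing_window = 4,
      artifact_bias_by_task = art(rubbing = -7.5, tapping = -4.6,
                                  `turning-pages` = -4.5, tablet = -1.8),
      artifact_sd_by_task = art(rubbing = 6.0, tapping = 5.7,
                                `turning-pages` = 4.4, tablet = 3.1),
      dropout_prob_by_task = art(rubbing = 0.10, tapping = 0.10,
                                 `turning-pages` = 0.20),
      dropout_prob_base = 0.02))
}

#' Study-protocol configuration for the simulator
#'
#' Encodes the two-phase session protocol: a movement phase (rest plus six
#' motion tasks at near-100\% saturation, with a transient desaturation dip
#' during sit-to-stand) and a controlled-hypoxia phase descending through
#' stable plateaus at the prespecified targets. Defaults follow the stated
#' protocol; free parameters (durations, plateau noise, analyzer noise) are
#' documented modelling choices.
#'
#' @param task_durations Named numeric vector, seconds per task, in protocol
#'   order. Defaults: at-rest 120 (the pre-first-ABG window), STS 90
#'   (20 repetitions), tapping 120 (2 min at 2 Hz), rubbing 120, drinking
#'   100 (20 sips), turning-pages 150 (50 pages), tablet 300.
#' @param task_gap Seconds of quiet rest between tasks.
#' @param hypoxia_targets Descending plateau targets, percent.
#' @param plateau_duration Seconds per plateau (must be >= 40, the pairing
#'   window length).
#' @param transition_duration Seconds per logistic descent between plateaus.
#' @param phase_gap Seconds between the movement and hypoxia phases
#'   (repositioning and mask fitting).
#' @param baseline_mean,baseline_sd Participant baseline SaO2 distribution.
#' @param sts_dip_mean,sts_dip_sd Mean/SD of the transient SaO2 dip at the
#'   middle of the STS task, percent.
#' @param plateau_noise_sd SD of the within-trajectory SaO2 jitter.
#' @param abg_analyzer_sd SD of the blood-gas analyzer reading error.
#' @param sample_rate_hz Stream sampling rate (fixed at 1).
#' @param include_sts_midpoint Add the extra mid-STS reference sample.
#' @param min_valid_samples Pairing threshold carried into matching.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(task_durations = c("at-rest" = 120, STS = 90,
                                               tapping = 120, rubbing = 120,
                                               drinking = 100,
                                               "turning-pages" = 150,
                                               tablet = 300),
                            task_gap = 30,
                            hypoxia_targets = c(95, 90, 87, 85, 83, 80),
                            plateau_duration = 90,
                            transition_duration = 30,
                            phase_gap = 300,
                            baseline_mean = 99.3, baseline_sd = 0.4,
                            sts_dip_mean = 1.87, sts_dip_sd = 0.87,
                            plateau_noise_sd = 0.3,
                            abg_analyzer_sd = 0.2,
                            sample_rate_hz = 1,
                            include_sts_midpoint = FALSE,
                            min_valid_samples = 20) {
  stopifnot(identical(names(task_durations), task_labels()),
            all(task_durations > 0), task_gap >= 0,
            all(diff(hypoxia_targets) < 0), all(hypoxia_targets >= 70),
            all(hypoxia_targets < 100),
            transition_duration > 0, phase_gap >= 40,
            plateau_noise_sd >= 0, abg_analyzer_sd >= 0,
            sample_rate_hz == 1)
  if (plateau_duration < 40)
    stop("plateau_duration must be >= 40 s (the pairing window length)",
         call. = FALSE)
  structure(list(task_durations = task_durations, task_gap = task_gap,
                 hypoxia_targets = hypoxia_targets,
                 plateau_duration = plateau_duration,
                 transition_duration = transition_duration,
                 phase_gap = phase_gap,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 sts_dip_mean = sts_dip_mean, sts_dip_sd = sts_dip_sd,
                 plateau_noise_sd = plateau_noise_sd,
                 abg_analyzer_sd = abg_analyzer_sd,
                 sample_rate_hz = sample_rate_hz,
                 include_sts_midpoint = include_sts_midpoint,
                 min_valid_samples = min_valid_samples),
            class = "protocol_config")
}

# task interval bookkeeping shared by trajectory and session simulation
protocol_schedule <- function(config) {
  labs <- names(config$task_durations)
  start <- numeric(length(labs)); stop <- numeric(length(labs))
  t0 <- 0
  for (i in seq_along(labs)) {
    start[i] <- t0
    stop[i] <- t0 + unname(config$task_durations[i])
    t0 <- stop[i] + config$task_gap
  }
  movement_end <- stop[length(stop)]
  hyp_start <- movement_end + config$phase_gap
  targets <- config$hypoxia_targets
  # baseline plateau (labelled "100") then each descending target
  plab <- c("100", as.character(targets))
  pstart <- numeric(length(plab)); pstop <- numeric(length(plab))
  t0 <- hyp_start
  for (i in seq_along(plab)) {
    pstart[i] <- t0
    pstop[i] <- t0 + config$plateau_duration
    t0 <- pstop[i] + if (i < length(plab)) config$transition_duration else 0
  }
  list(tasks = data.frame(label = labs, start = start, stop = stop,
                          stringsAsFactors = FALSE),
       movement_end = movement_end,
       plateaus = data.frame(label = plab, start = pstart, stop = pstop,
                             stringsAsFactors = FALSE),
       session_end = pstop[length(pstop)])
}

#' Simulate the true SaO2 trajectory of one session
#'
#' Produces a dense 1 Hz curve: the movement phase sits at the participant's
#' baseline with a raised-cosine transient dip centred on the STS task; the
#' hypoxia phase descends through stable plateaus at each target with
#' logistic transitions. Small white jitter (`plateau_noise_sd`) models
#' physiological fluctuation; the curve is clipped to \[70, 100\].
#'
#' @param config A [protocol_config()].
#' @param seed Integer seed.
#' @param baseline Optional fixed baseline SaO2; drawn from the configured
#'   distribution when `NULL`.
#' @return A list with `t`, `sao2`, the task `annotations`, the `plateaus`
#'   table, and the drawn `baseline` and `sts_dip`.
#' @export
simulate_sao2_trajectory <- function(config, seed, baseline = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  sched <- protocol_schedule(config)
  with_seed(seed, {
    if (is.null(baseline))
      baseline <- min(100, rnorm(1, config$baseline_mean, config$baseline_sd))
    sts_dip <- max(0, rnorm(1, config$sts_dip_mean, config$sts_dip_sd))
    t <- seq(0, sched$session_end, by = 1 / config$sample_rate_hz)
    sao2 <- rep(baseline, length(t))

    # transient STS dip: raised cosine, full depth at task midpoint,
    # recovered by the stop time (mid-task ABGs read lower than end-of-task)
    sts <- sched$tasks[sched$tasks$label == "STS", ]
    in_sts <- t >= sts$start & t <= sts$stop
    frac <- (t[in_sts] - sts$start) / (sts$stop - sts$start)
    sao2[in_sts] <- sao2[in_sts] - sts_dip * 0.5 * (1 - cos(2 * pi * frac))

    # hypoxia phase: exactly flat plateaus joined by normalized logistic
    # descents (rescaled so each transition meets its plateaus exactly)
    pl <- sched$plateaus
    levels <- c(baseline, config$hypoxia_targets)
    for (i in seq_len(nrow(pl))) {
      on_pl <- t >= pl$start[i] & t <= pl$stop[i]
      sao2[on_pl] <- levels[i]
      if (i < nrow(pl)) {
        in_tr <- t > pl$stop[i] & t < pl$start[i + 1L]
        u <- (t[in_tr] - pl$stop[i]) / (pl$start[i + 1L] - pl$stop[i])
        s <- (plogis(8 * (u - 0.5)) - plogis(-4)) / (plogis(4) - plogis(-4))
        sao2[in_tr] <- levels[i] + (levels[i + 1L] - levels[i]) * s
      }
    }

    if (config$plateau_noise_sd > 0)
      sao2 <- sao2 + rnorm(length(sao2), 0, config$plateau_noise_sd)
    sao2 <- pmin(100, pmax(70, sao2))

    list(t = t, sao2 = sao2,
         annotations = task_annotations(sched$tasks$label, sched$tasks$start,
                                        sched$tasks$stop),
         plateaus = pl, baseline = baseline, sts_dip = sts_dip)
  })
}

#' Simulate one device's SpO2 stream from a true trajectory
#'
#' Applies, in order: trailing moving-average smoothing (vendor data
#' averaging), the systematic bias (optionally SaO2-dependent), white
#' scatter, task-window artifact noise, clipping to \[0, 100\], and
#' task-window plus baseline dropout thinning (dropped seconds become `NA`).
#'
#' @param trajectory Output of [simulate_sao2_trajectory()].
#' @param device A [device_model()].
#' @param annotations Task annotations (defaults to the trajectory's own).
#' @param seed Integer seed.
#' @return An [spo2_stream()].
#' @export
simulate_device_stream <- function(trajectory, device,
                                   annotations = trajectory$annotations,
                                   seed) {
  stopifnot(inherits(device, "device_model"))
  with_seed(seed, {
    t <- trajectory$t
    n <- length(t)
    k <- max(1L, as.integer(round(device$smoothing_window)))
    smoothed <- if (k == 1L) trajectory$sao2 else {
      cs <- cumsum(trajectory$sao2)
      lag <- c(rep(0, k), cs[seq_len(n - k)])
      cnt <- pmin(seq_len(n), k)
      (cs - lag) / cnt
    }
    spo2 <- smoothed + device$systematic_bias +
      device$bias_slope * (smoothed - 100)
    if (device$scatter_sd > 0)
      spo2 <- spo2 + rnorm(n, 0, device$scatter_sd)

    drop_p <- rep(device$dropout_prob_base, n)
    for (i in seq_len(nrow(annotations))) {
      lab <- annotations$label[i]
      win <- t >= annotations$start[i] & t < annotations$stop[i]
      ab <- device$artifact_bias_by_task[lab]
      asd <- device$artifact_sd_by_task[lab]
      if (!is.na(ab) || !is.na(asd))
        spo2[win] <- spo2[win] + rnorm(sum(win),
                                       if (is.na(ab)) 0 else ab,
                                       if (is.na(asd)) 0 else asd)
      dp <- device$dropout_prob_by_task[lab]
      if (!is.na(dp)) drop_p[win] <- dp
    }
    spo2 <- pmin(100, pmax(0, spo2))
    spo2[runif(n) < drop_p] <- NA_real_
    spo2_stream(device$device_id, t, spo2)
  })
}

#' Simulate one study session
#'
#' Builds the SaO2 trajectory, one stream per device, and the reference ABG
#' table: one end-of-task sample per motion task (the at-rest sample closes
#' the pre-task rest window), an optional mid-STS sample, and one sample at
#' the midpoint of each hypoxia plateau (baseline "100" plateau included).
#' Reference SaO2 = trajectory value + analyzer noise.
#'
#' @param config A [protocol_config()].
#' @param devices List of [device_model()]s.
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @param demographics Optional pass-through metadata list.
#' @param baseline Optional fixed participant baseline.
#' @return An `oxival_session`.
#' @export
simulate_session <- function(config, devices, seed, session_id = "s001",
                             demographics = list(), baseline = NULL) {
  stopifnot(length(devices) >= 1L)
  seeds <- split_seed(seed, 2L + length(devices))
  traj <- simulate_sao2_trajectory(config, seeds[1], baseline = baseline)
  streams <- list()
  for (i in seq_along(devices)) {
    s <- simulate_device_stream(traj, devices[[i]], traj$annotations,
                                seed = seeds[1L + i])
    streams[[s$device_id]] <- s
  }
  traj_at <- function(tt) traj$sao2[match(round(tt), traj$t)]
  ann <- traj$annotations
  ref_t <- ann$stop
  ref_lab <- ann$label
  ref_kind <- rep("end-of-task", nrow(ann))
  if (isTRUE(config$include_sts_midpoint)) {
    sts <- ann[ann$label == "STS", ]
    ref_t <- c(ref_t, round((sts$start + sts$stop) / 2))
    ref_lab <- c(ref_lab, "STS")
    ref_kind <- c(ref_kind, "mid-task")
  }
  ref_phase <- rep("movement", length(ref_t))
  pl <- traj$plateaus
  pmid <- round((pl$start + pl$stop) / 2)
  ref_t <- c(ref_t, pmid)
  ref_lab <- c(ref_lab, pl$label)
  ref_kind <- c(ref_kind, rep("plateau", nrow(pl)))
  ref_phase <- c(ref_phase, rep("hypoxia", nrow(pl)))
  sao2 <- with_seed(seeds[length(seeds)],
                    traj_at(ref_t) + rnorm(length(ref_t), 0,
                                           config$abg_analyzer_sd))
  sao2 <- pmin(100, pmax(0, sao2))
  refs <- reference_samples(ref_t, sao2, ref_phase, ref_lab, ref_kind)
  session(session_id, streams, ann, refs, demographics = demographics)
}

#' Simulate a multi-participant study dataset
#'
#' Independent sessions with per-participant baseline jitter and simple
#' pass-through demographics. The extra mid-STS reference is taken for the
#' first `n_sts_midpoint` participants. Deterministic given `seed`.
#'
#' @param config A [protocol_config()].
#' @param devices List of [device_model()]s.
#' @param n_participants Number of sessions.
#' @param seed Integer master seed.
#' @param n_sts_midpoint How many participants get the mid-STS sample.
#' @return An `oxival_study`.
#' @export
simulate_study <- function(config, devices, n_participants, seed,
                           n_sts_midpoint = 15) {
  stopifnot(n_participants >= 1L)
  seeds <- split_seed(seed, n_participants + 1L)
  demo <- with_seed(seeds[n_participants + 1L], {
    data.frame(age = round(runif(n_participants, 20, 45)),
               sex = sample(c("F", "M"), n_participants, replace = TRUE),
               height_m = round(rnorm(n_participants, 1.70, 0.09), 2),
               weight_kg = round(rnorm(n_participants, 70, 10), 1),
               skin_type = sample(1:4, n_participants, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  sessions <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    cfg <- config
    cfg$include_sts_midpoint <- i <= n_sts_midpoint
    sessions[[i]] <- simulate_session(
      cfg, devices, seed = seeds[i],
      session_id = sprintf("s%03d", i),
      demographics = as.list(demo[i, , drop = FALSE]))
  }
  study_dataset(sessions)
}
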