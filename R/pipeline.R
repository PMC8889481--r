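#' Pipeline run configuration
#'
#' Validated settings for a full simulate/load -> match -> report run. A
#' seed is mandatory: there is no silent nondeterminism.
#'
#' @param out_dir Output directory for CSV tables and the manifest.
#' @param seed Master seed; expanded into per-stage child seeds via
#'   [split_seed()].
#' @param dataset_path Existing dataset directory to load; `NULL` to
#'   simulate.
#' @param config [protocol_config()] used when simulating.
#' @param devices List of [device_model()]s used when simulating.
#' @param n_participants Sessions to simulate.
#' @param reps Bootstrap repetitions (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param cutoff Hypoxemia detection cut-off.
#' @param min_valid_samples Pairing threshold.
#' @param verbose Stage-level logging.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed, dataset_path = NULL,
                       config = protocol_config(),
                       devices = default_device_models(),
                       n_participants = 33, reps = 10000, alpha = 0.05,
                       cutoff = 90, min_valid_samples = 20,
                       verbose = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("run_config requires an explicit seed", call. = FALSE)
  stopifnot(reps >= 1, alpha > 0, alpha < 1, n_participants >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 dataset_path = dataset_path, config = config,
                 devices = devices, n_participants = n_participants,
                 reps = reps, alpha = alpha, cutoff = cutoff,
                 min_valid_samples = min_valid_samples, verbose = verbose),
            class = "run_config")
}

stage_log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

run_stage <- function(cfg, name, code) {
  tryCatch(code, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full validation pipeline
#'
#' Simulates (or loads) a study dataset, matches both phases, and writes:
#' the pairs tables, movement (per device x task) and hypoxia (per device,
#' overall and per SaO2 subgroup) accuracy tables with ISO verdicts,
#' between-stratum comparison summaries, the mid-vs-end STS Wilcoxon
#' result, per-device Bland-Altman summaries, the hypoxemia detection
#' table, and a JSON run manifest. Rerunning with the same configuration
#' reproduces identical numbers.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with every table plus the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(cfg$seed, 6L)

  study <- run_stage(cfg, "dataset", {
    if (!is.null(cfg$dataset_path)) {
      stage_log(cfg, "loading dataset from ", cfg$dataset_path)
      read_study(cfg$dataset_path)
    } else {
      stage_log(cfg, "simulating ", cfg$n_participants, " sessions")
      simulate_study(cfg$config, cfg$devices, cfg$n_participants,
                     seed = seeds[1])
    }
  })

  pairs_mov <- run_stage(cfg, "match-movement",
    match_study(study, "movement",
                min_valid_samples = cfg$min_valid_samples,
                verbose = cfg$verbose))
  pairs_hyp <- run_stage(cfg, "match-hypoxia",
    match_study(study, "hypoxia",
                min_valid_samples = cfg$min_valid_samples,
                verbose = cfg$verbose))
  write_csv_plain(pairs_mov, file.path(cfg$out_dir, "pairs_movement.csv"))
  write_csv_plain(pairs_hyp, file.path(cfg$out_dir, "pairs_hypoxia.csv"))

  acc_mov <- run_stage(cfg, "accuracy-movement",
    accuracy_table(pairs_mov, by = c("device_id", "stratum"),
                   reps = cfg$reps, seed = seeds[2]))
  acc_hyp <- run_stage(cfg, "accuracy-hypoxia",
    accuracy_table(transform(pairs_hyp, stratum = "overall"),
                   by = c("device_id", "stratum"),
                   reps = cfg$reps, seed = seeds[3]))
  acc_sub <- run_stage(cfg, "accuracy-subgroup",
    accuracy_table(pairs_hyp, by = c("device_id", "subgroup"),
                   reps = cfg$reps, seed = seeds[4]))
  acc_hyp$iso_pass <- vapply(seq_len(nrow(acc_hyp)), function(i)
    iso_compliance(acc_hyp[i, ])$pass, logical(1))
  write_csv_plain(acc_mov, file.path(cfg$out_dir, "accuracy_movement.csv"))
  write_csv_plain(acc_hyp, file.path(cfg$out_dir, "accuracy_hypoxia.csv"))
  write_csv_plain(acc_sub, file.path(cfg$out_dir, "accuracy_subgroups.csv"))

  comparisons <- run_stage(cfg, "compare", {
    per_device <- lapply(split(pairs_mov, pairs_mov$device_id), function(p) {
      lapply(c(bias = "bias", absbias = "absbias", precision = "precision"),
             function(m) compare_strata(p, m, by = "stratum",
                                        alpha = cfg$alpha))
    })
    comp_rows <- do.call(rbind, lapply(names(per_device), function(dev) {
      do.call(rbind, lapply(names(per_device[[dev]]), function(m) {
        r <- per_device[[dev]][[m]]$omnibus
        data.frame(device_id = dev, metric = m, test = r$test,
                   statistic = r$statistic, p_value = r$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))
    write_csv_plain(comp_rows,
                    file.path(cfg$out_dir, "comparisons_movement.csv"))
    per_device
  })

  sts <- sts_midpoint_values(study)
  sts_test <- if (nrow(sts) >= 1L && any(sts$end != sts$mid))
    run_stage(cfg, "sts-wilcoxon", wilcoxon_paired(sts$mid, sts$end))
  else NULL

  ba <- run_stage(cfg, "bland-altman", {
    rows <- do.call(rbind, lapply(split(pairs_hyp, pairs_hyp$device_id),
      function(p) {
        b <- bland_altman(p)
        data.frame(device_id = p$device_id[1], mean_bias = b$mean_bias,
                   loa_lo = b$loa_lo, loa_hi = b$loa_hi, n = b$n,
                   stringsAsFactors = FALSE)
      }))
    write_csv_plain(rows, file.path(cfg$out_dir, "bland_altman.csv"))
    rows
  })

  detection <- run_stage(cfg, "detect", {
    dseeds <- split_seed(seeds[5], length(study$devices))
    reports <- list()
    rows <- list()
    for (i in seq_along(study$devices)) {
      dev <- study$devices[i]
      p <- pairs_hyp[pairs_hyp$device_id == dev, , drop = FALSE]
      r <- detection_report(p, cutoff = cfg$cutoff, reps = cfg$reps,
                            seed = dseeds[i])
      reports[[dev]] <- r
      fmt <- function(tab) {
        est <- setNames(tab$estimate, tab$metric)
        lo <- setNames(tab$ci_lo, paste0(tab$metric, "_lo"))
        hi <- setNames(tab$ci_hi, paste0(tab$metric, "_hi"))
        c(est, lo, hi)
      }
      rows[[dev]] <- data.frame(device_id = dev, cutoff = r$cutoff,
                                optimal_cutoff = r$optimal_cutoff,
                                auroc = r$auroc[["estimate"]],
                                auroc_lo = r$auroc[["ci_lo"]],
                                auroc_hi = r$auroc[["ci_hi"]],
                                n_positive = r$n_positive,
                                n_negative = r$n_negative,
                                t(fmt(r$at_cutoff)),
                                stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    write_csv_plain(tab, file.path(cfg$out_dir, "detection.csv"))
    list(reports = reports, table = tab)
  })

  manifest <- list(
    seed = cfg$seed, stage_seeds = seeds, reps = cfg$reps,
    alpha = cfg$alpha, cutoff = cfg$cutoff,
    min_valid_samples = cfg$min_valid_samples,
    n_participants = if (is.null(cfg$dataset_path)) cfg$n_participants
                     else length(study$sessions),
    dataset_path = cfg$dataset_path,
    devices = names(study$devices) %||% study$devices,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("oxival")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(study = study, pairs_movement = pairs_mov,
                 pairs_hypoxia = pairs_hyp, accuracy_movement = acc_mov,
                 accuracy_hypoxia = acc_hyp, accuracy_subgroups = acc_sub,
                 comparisons = comparisons, sts_wilcoxon = sts_test,
                 bland_altman = ba, detection = detection,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

need <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop("missing required option --", key, call. = FALSE)
  opts[[key]]
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `match`, `accuracy`, `compare`, `detect`,
#' `run`. Invoke as
#' `Rscript -e 'oxival::oxival_cli(exit = TRUE)' run --out <dir> --seed 1`.
#' All randomized subcommands require `--seed`.
#'
#' @param args Character vector of command-line arguments; defaults to the
#'   process arguments.
#' @param exit Terminate the R process with the status code (for use from
#'   `Rscript`); when `FALSE` (default) the status is returned instead.
#' @return Exit status (0 success, 1 validation failure), invisibly.
#' @export
oxival_cli <- function(args = commandArgs(trailingOnly = TRUE),
                       exit = FALSE) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: oxival <simulate|match|accuracy|compare|detect|run> [--options]",
           call. = FALSE)
    cmd <- args[1]
    opts <- cli_args_to_list(args[-1])
    seed_opt <- function() as.integer(need(opts, "seed"))
    reps_opt <- function() as.integer(opts[["reps"]] %||% 10000)
    read_pairs <- function() {
      path <- need(opts, "pairs")
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      df
    }
    switch(cmd,
      simulate = {
        study <- simulate_study(protocol_config(), default_device_models(),
                                as.integer(opts[["n"]] %||% 33),
                                seed = seed_opt())
        write_study(study, need(opts, "out"))
      },
      match = {
        study <- read_study(need(opts, "in"))
        pairs <- match_study(study, need(opts, "phase"),
                             verbose = TRUE)
        write_csv_plain(pairs, need(opts, "out"))
      },
      accuracy = {
        by <- strsplit(opts[["by"]] %||% "device_id,stratum", ",")[[1]]
        tab <- accuracy_table(read_pairs(), by = by, reps = reps_opt(),
                              seed = seed_opt())
        write_csv_plain(tab, need(opts, "out"))
      },
      compare = {
        pairs <- read_pairs()
        res <- compare_strata(pairs, opts[["metric"]] %||% "bias",
                              by = opts[["by"]] %||% "stratum")
        print(res$omnibus)
        if (!is.null(res$tukey)) print(res$tukey)
      },
      detect = {
        pairs <- read_pairs()
        rows <- lapply(split(pairs, pairs$device_id), function(p) {
          r <- detection_report(p, cutoff = as.numeric(opts[["cutoff"]] %||% 90),
                                reps = reps_opt(), seed = seed_opt())
          data.frame(device_id = p$device_id[1],
                     optimal_cutoff = r$optimal_cutoff,
                     auroc = r$auroc[["estimate"]],
                     sensitivity = r$at_cutoff$estimate[1],
                     specificity = r$at_cutoff$estimate[2],
                     stringsAsFactors = FALSE)
        })
        write_csv_plain(do.call(rbind, rows), need(opts, "out"))
      },
      run = {
        cfg <- run_config(out_dir = need(opts, "out"), seed = seed_opt(),
                          dataset_path = opts[["in"]],
                          n_participants = as.integer(opts[["n"]] %||% 33),
                          reps = reps_opt())
        run_pipeline(cfg)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  if (isTRUE(exit)) quit(status = status, save = "no")
  invisible(status)
}
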