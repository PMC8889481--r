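# shared fixture builders -- everything is generated in code at test time

# pairs table straight from spo2/sao2 vectors
make_pairs <- function(spo2, sao2, device_id = "dev", session_id = "s001",
                       phase = "hypoxia", stratum = "95",
                       subgroup = NA_character_, n_valid = 40L) {
  n <- length(spo2)
  data.frame(device_id = rep_len(device_id, n),
             session_id = rep_len(session_id, n),
             phase = rep_len(phase, n), stratum = rep_len(stratum, n),
             subgroup = rep_len(subgroup, n), spo2_median = spo2,
             sao2 = sao2, n_valid = rep_len(n_valid, n),
             stringsAsFactors = FALSE)
}

# pairs with differences drawn N(bias, sd) around a sao2 grid
random_pairs <- function(n, bias = 0, sd = 1, sao2_range = c(80, 100)) {
  sao2 <- runif(n, sao2_range[1], sao2_range[2])
  make_pairs(sao2 + rnorm(n, bias, sd), sao2)
}

# short but structurally complete protocol: full task vocabulary, all six
# targets, plateaus just long enough for the 40 s window
test_config <- function(...) {
  protocol_config(
    task_durations = c("at-rest" = 60, STS = 60, tapping = 60, rubbing = 60,
                       drinking = 60, "turning-pages" = 60, tablet = 60),
    task_gap = 10, plateau_duration = 60, transition_duration = 16,
    phase_gap = 60, ...)
}

# single noise-free pass-through device
ideal_device <- function(id = "ideal") {
  device_model(id, systematic_bias = 0, scatter_sd = 0, smoothing_window = 1)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
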