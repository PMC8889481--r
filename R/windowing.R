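#' SaO2 subgroup classification
#'
#' Severe hypoxia below 85\%, mild hypoxia 85\%-89\%, normoxia at or above
#' 90\%.
#'
#' @param sao2 Numeric vector of SaO2 percentages.
#' @return Character vector: `"severe"`, `"mild"`, or `"normoxia"`.
#' @export
sao2_subgroup <- function(sao2) {
  out <- rep("normoxia", length(sao2))
  out[sao2 < 90] <- "mild"
  out[sao2 < 85] <- "severe"
  out
}

window_median <- function(stream, lo, hi, right_closed) {
  sel <- if (right_closed) stream$t >= lo & stream$t <= hi
         else stream$t >= lo & stream$t < hi
  v <- stream$spo2[sel]
  v <- v[!is.na(v)]
  list(median = if (length(v)) stats::median(v) else NA_real_,
       n_valid = length(v))
}

make_pair <- function(device_id, session_id, phase, stratum, subgroup,
                      spo2_median, sao2, n_valid) {
  data.frame(device_id = device_id, session_id = session_id, phase = phase,
             stratum = stratum, subgroup = subgroup,
             spo2_median = spo2_median, sao2 = sao2, n_valid = n_valid,
             stringsAsFactors = FALSE)
}

#' Pair a movement-phase reference with its windowed SpO2 median
#'
#' The SpO2 value is the median over the 40-second window immediately before
#' the task stop time, `[stop - 40, stop)`, taken over non-missing samples
#' only. The pair is dropped (returns `NULL`) when fewer than
#' `min_valid_samples` samples survive.
#'
#' @param stream An [spo2_stream()].
#' @param annotation One-row task annotation matching the reference label.
#' @param reference One-row movement reference of kind `end-of-task`.
#' @param session_id Session identifier carried into the pair.
#' @param min_valid_samples Minimum non-missing samples required (default 20,
#'   half the window).
#' @return One-row pairs `data.frame`, or `NULL` when the window is too
#'   sparse.
#' @export
match_movement <- function(stream, annotation, reference,
                           session_id = "s", min_valid_samples = 20) {
  stopifnot(inherits(stream, "spo2_stream"))
  if (reference$kind != "end-of-task")
    stop("movement matching expects an end-of-task reference", call. = FALSE)
  if (annotation$label != reference$label)
    stop("alignment error: annotation '", annotation$label,
         "' does not match reference '", reference$label, "'", call. = FALSE)
  wm <- window_median(stream, annotation$stop - 40, annotation$stop,
                      right_closed = FALSE)
  if (wm$n_valid < min_valid_samples) return(NULL)
  make_pair(stream$device_id, session_id, "movement", reference$label,
            NA_character_, wm$median, reference$sao2, wm$n_valid)
}

#' Pair a hypoxia-phase reference with its windowed SpO2 median
#'
#' The window is the 40 seconds around the reference sample: 35 seconds
#' before through 5 seconds after, `[t - 35, t + 5]`, both ends included.
#' Windows truncated by the stream span are used as long as enough samples
#' remain. The SaO2 subgroup (severe/mild/normoxia) is attached.
#'
#' @inheritParams match_movement
#' @param reference One-row hypoxia-phase reference.
#' @return One-row pairs `data.frame`, or `NULL`.
#' @export
match_hypoxia <- function(stream, reference, session_id = "s",
                          min_valid_samples = 20) {
  stopifnot(inherits(stream, "spo2_stream"))
  if (reference$phase != "hypoxia")
    stop("hypoxia matching expects a hypoxia-phase reference", call. = FALSE)
  lo <- reference$t - 35; hi <- reference$t + 5
  if (length(stream$t) && (lo < min(stream$t) || hi > max(stream$t)))
    warning("hypoxia window truncated at the stream boundary (reference t=",
            reference$t, ")", call. = FALSE)
  wm <- window_median(stream, lo, hi, right_closed = TRUE)
  if (wm$n_valid < min_valid_samples) return(NULL)
  make_pair(stream$device_id, session_id, "hypoxia", reference$label,
            sao2_subgroup(reference$sao2), wm$median, reference$sao2,
            wm$n_valid)
}

#' Match all references of one session
#'
#' Movement metrics use end-of-task references only; mid-STS references are
#' reserved for the paired mid-vs-end comparison (see
#' [sts_midpoint_values()]) and never enter accuracy metrics.
#'
#' @param session An `oxival_session`.
#' @param phase `"movement"` or `"hypoxia"`.
#' @param min_valid_samples Minimum non-missing samples per window.
#' @return Pairs `data.frame` (possibly 0 rows) with a `dropped` attribute:
#'   named per-device count of references whose window was too sparse.
#' @export
match_session <- function(session, phase = c("movement", "hypoxia"),
                          min_valid_samples = 20) {
  phase <- match.arg(phase)
  refs <- session$references
  refs <- refs[refs$phase == phase & refs$kind != "mid-task", , drop = FALSE]
  out <- list()
  dropped <- setNames(integer(length(session$streams)),
                      names(session$streams))
  for (dev in names(session$streams)) {
    stream <- session$streams[[dev]]
    for (i in seq_len(nrow(refs))) {
      ref <- refs[i, ]
      pair <- if (phase == "movement") {
        ann <- session$annotations[session$annotations$label == ref$label, ]
        if (nrow(ann) != 1L)
          stop("alignment error: no annotation for reference label '",
               ref$label, "' in session '", session$session_id, "'",
               call. = FALSE)
        match_movement(stream, ann, ref, session$session_id,
                       min_valid_samples)
      } else {
        match_hypoxia(stream, ref, session$session_id, min_valid_samples)
      }
      if (is.null(pair)) dropped[dev] <- dropped[dev] + 1L
      else out[[length(out) + 1L]] <- pair
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    make_pair(character(), character(), character(), character(),
              character(), numeric(), numeric(), integer())
  attr(pairs, "dropped") <- dropped
  pairs
}

#' Match an entire study dataset
#'
#' Concatenates [match_session()] over all sessions and reports per-device
#' emitted/dropped bookkeeping (the "available SpO2 points" accounting).
#'
#' @param dataset An `oxival_study`.
#' @inheritParams match_session
#' @param verbose Print the per-device accounting.
#' @return Pairs `data.frame` with attributes `emitted` and `dropped`
#'   (named per-device counts; their sum equals references x sessions).
#' @export
match_study <- function(dataset, phase = c("movement", "hypoxia"),
                        min_valid_samples = 20, verbose = FALSE) {
  phase <- match.arg(phase)
  stopifnot(inherits(dataset, "oxival_study"))
  chunks <- lapply(dataset$sessions, match_session, phase = phase,
                   min_valid_samples = min_valid_samples)
  pairs <- do.call(rbind, chunks)
  rownames(pairs) <- NULL
  dropped <- Reduce(`+`, lapply(chunks, attr, "dropped"))
  emitted <- setNames(integer(length(dataset$devices)), dataset$devices)
  if (nrow(pairs)) {
    tab <- table(pairs$device_id)
    emitted[names(tab)] <- as.integer(tab)
  }
  if (verbose)
    for (dev in dataset$devices)
      message(sprintf("%-12s %s pairs: %d emitted, %d dropped",
                      dev, phase, emitted[dev], dropped[dev]))
  attr(pairs, "emitted") <- emitted
  attr(pairs, "dropped") <- dropped[dataset$devices]
  pairs
}

#' Extract paired mid-STS and end-of-STS reference SaO2 values
#'
#' Returns, for each session holding both samples, the SaO2 measured at the
#' middle of the sit-to-stand task and at its end — the input to the paired
#' Wilcoxon comparison of during-task versus post-task saturation.
#'
#' @param dataset An `oxival_study`.
#' @return `data.frame` with columns `session_id`, `mid`, `end`.
#' @export
sts_midpoint_values <- function(dataset) {
  out <- lapply(dataset$sessions, function(s) {
    r <- s$references
    m <- r[r$label == "STS" & r$kind == "mid-task", , drop = FALSE]
    e <- r[r$label == "STS" & r$kind == "end-of-task", , drop = FALSE]
    if (nrow(m) == 1L && nrow(e) == 1L)
      data.frame(session_id = s$session_id, mid = m$sao2, end = e$sao2,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(session_id = character(), mid = numeric(),
                               end = numeric(), stringsAsFactors = FALSE)
  else { rownames(out) <- NULL; out }
}
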