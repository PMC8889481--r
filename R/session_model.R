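#' Construct a 1 Hz SpO2 stream for one device
#'
#' A stream is a time-ordered series of SpO2 readings (% saturation) on a
#' common session clock in seconds. Missing values (`NA`) represent dropout:
#' seconds at which the device delivered no estimate. Gaps in `t` are also
#' permitted and mean the same thing.
#'
#' @param device_id Device label.
#' @param t Numeric vector, seconds from session start, strictly increasing.
#' @param spo2 Numeric vector of SpO2 percentages in \[0, 100\], `NA` for
#'   dropout.
#' @return An object of class `spo2_stream`.
#' @export
spo2_stream <- function(device_id, t, spo2) {
  stopifnot(is.character(device_id), length(device_id) == 1L,
            length(t) == length(spo2))
  t <- as.numeric(t); spo2 <- as.numeric(spo2)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("stream '", device_id, "': time must be strictly increasing",
         call. = FALSE)
  bad <- !is.na(spo2) & (spo2 < 0 | spo2 > 100)
  if (any(bad))
    stop("stream '", device_id, "': SpO2 outside [0, 100] at t=",
         t[which(bad)[1]], call. = FALSE)
  structure(list(device_id = device_id, t = t, spo2 = spo2),
            class = "spo2_stream")
}

#' @export
print.spo2_stream <- function(x, ...) {
  cat(sprintf("<spo2_stream '%s': %d samples, %d missing, span %.0f-%.0f s>\n",
              x$device_id, length(x$t), sum(is.na(x$spo2)),
              if (length(x$t)) min(x$t) else NA, if (length(x$t)) max(x$t) else NA))
  invisible(x)
}

#' Construct a table of reference SaO2 samples
#'
#' Each row is one arterial blood gas (ABG) result: the gold-standard SaO2
#' against which windowed SpO2 medians are compared. Movement-phase samples
#' carry a task label and kind `end-of-task` (or `mid-task`, STS only);
#' hypoxia-phase samples carry a target-level label and kind `plateau`.
#'
#' @param t Seconds from session start.
#' @param sao2 SaO2 percentage in \[0, 100\].
#' @param phase `"movement"` or `"hypoxia"`.
#' @param label Task name (movement) or target level (hypoxia).
#' @param kind `"end-of-task"`, `"mid-task"`, or `"plateau"`.
#' @return A validated `data.frame` of class `reference_samples`.
#' @export
reference_samples <- function(t, sao2, phase, label, kind) {
  df <- data.frame(t = as.numeric(t), sao2 = as.numeric(sao2),
                   phase = as.character(phase), label = as.character(label),
                   kind = as.character(kind), stringsAsFactors = FALSE)
  validate_references(df)
  class(df) <- c("reference_samples", "data.frame")
  df
}

validate_references <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$sao2 < 0 | df$sao2 > 100))
    stop("reference SaO2 outside [0, 100]: ",
         df$sao2[which(df$sao2 < 0 | df$sao2 > 100)[1]], call. = FALSE)
  if (!all(df$phase %in% c("movement", "hypoxia")))
    stop("reference phase must be 'movement' or 'hypoxia'", call. = FALSE)
  if (!all(df$kind %in% c("end-of-task", "mid-task", "plateau")))
    stop("reference kind not in vocabulary", call. = FALSE)
  mov <- df$phase == "movement"
  if (any(!df$label[mov] %in% task_labels()))
    stop("movement reference label not in task vocabulary: ",
         df$label[mov][which(!df$label[mov] %in% task_labels())[1]],
         call. = FALSE)
  if (any(!df$label[!mov] %in% target_labels()))
    stop("hypoxia reference label not in target vocabulary: ",
         df$label[!mov][which(!df$label[!mov] %in% target_labels())[1]],
         call. = FALSE)
  if (any(df$kind == "mid-task" & df$label != "STS"))
    stop("mid-task references are only valid for the STS task", call. = FALSE)
  if (any(df$kind == "plateau" & df$phase != "hypoxia"))
    stop("plateau references belong to the hypoxia phase", call. = FALSE)
  invisible(df)
}

#' Construct a table of motion-task annotations
#'
#' @param label Task labels (see [task_labels()]).
#' @param start,stop Task boundaries, seconds from session start.
#' @return A validated `data.frame` of class `task_annotations`.
#' @export
task_annotations <- function(label, start, stop) {
  df <- data.frame(label = as.character(label), start = as.numeric(start),
                   stop = as.numeric(stop), stringsAsFactors = FALSE)
  if (any(!df$label %in% task_labels()))
    stop("unknown task label: ",
         df$label[which(!df$label %in% task_labels())[1]], call. = FALSE)
  if (any(df$start >= df$stop))
    stop("task annotation with start >= stop", call. = FALSE)
  if (nrow(df) > 1L) {
    o <- order(df$start)
    if (any(df$start[o][-1] < df$stop[o][-nrow(df)]))
      stop("task annotations overlap", call. = FALSE)
  }
  class(df) <- c("task_annotations", "data.frame")
  df
}

#' Assemble a study session
#'
#' A session bundles everything recorded for one participant visit: one
#' stream per device, the motion-task annotations, the reference ABG table,
#' and pass-through demographics.
#'
#' @param session_id Session identifier.
#' @param streams Named list of [spo2_stream()] objects (names = device ids).
#' @param annotations A [task_annotations()] table.
#' @param references A [reference_samples()] table.
#' @param demographics Named list of pass-through metadata (age, sex, ...).
#' @return An object of class `oxival_session`.
#' @export
session <- function(session_id, streams, annotations, references,
                    demographics = list()) {
  stopifnot(length(streams) >= 1L)
  if (is.null(names(streams)) || any(names(streams) == ""))
    names(streams) <- vapply(streams, function(s) s$device_id, character(1))
  streams <- streams[order(names(streams))]  # canonical device order
  for (s in streams) stopifnot(inherits(s, "spo2_stream"))
  validate_references(references)
  # every reference must sit within a stream span, give or take one window
  spans <- range(unlist(lapply(streams, function(s) s$t)))
  if (nrow(references) > 0L &&
      any(references$t < spans[1] - 40 | references$t > spans[2] + 40))
    stop("reference time outside stream span (+/- 40 s)", call. = FALSE)
  structure(list(session_id = as.character(session_id), streams = streams,
                 annotations = annotations, references = references,
                 demographics = demographics),
            class = "oxival_session")
}

#' @export
print.oxival_session <- function(x, ...) {
  cat(sprintf("<oxival_session '%s': %d devices, %d annotations, %d references>\n",
              x$session_id, length(x$streams), nrow(x$annotations),
              nrow(x$references)))
  invisible(x)
}

#' Assemble a study dataset
#'
#' @param sessions List of [session()] objects.
#' @param devices Device roster; defaults to the devices of the first
#'   session. Every session must carry exactly this roster.
#' @return An object of class `oxival_study`.
#' @export
study_dataset <- function(sessions, devices = NULL) {
  stopifnot(length(sessions) >= 1L)
  if (is.null(devices)) devices <- names(sessions[[1]]$streams)
  for (s in sessions) {
    stopifnot(inherits(s, "oxival_session"))
    if (!setequal(names(s$streams), devices))
      stop("session '", s$session_id, "' does not carry the device roster",
           call. = FALSE)
  }
  names(sessions) <- vapply(sessions, function(s) s$session_id, character(1))
  structure(list(sessions = sessions, devices = devices),
            class = "oxival_study")
}

#' @export
print.oxival_study <- function(x, ...) {
  cat(sprintf("<oxival_study: %d sessions x %d devices>\n",
              length(x$sessions), length(x$devices)))
  invisible(x)
}

## ---- delimited-text session format ---------------------------------------
## Layout under one session directory:
##   streams/<device_id>.csv   columns t,spo2       (spo2 blank = dropout)
##   annotations.csv           columns label,start,stop
##   references.csv            columns t,sao2,phase,label,kind
##   session.yml               "key: value" metadata lines
## Comma-separated, header row, UTF-8, "." decimal, empty field = missing.

read_csv_strict <- function(path, cols) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) abort_parse(path, 0L, "empty file")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, cols))
    abort_parse(path, 1L, paste0("expected header '",
                                 paste(cols, collapse = ","), "'"))
  n <- length(lines) - 1L
  out <- matrix("", nrow = n, ncol = length(cols))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    # trailing empty field is dropped by strsplit; restore it
    length(fields) <- length(cols)
    fields[is.na(fields)] <- ""
    if (length(fields) != length(cols))
      abort_parse(path, i + 1L, "wrong field count")
    out[i, ] <- fields
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  names(df) <- cols
  attr(df, "source_path") <- path
  df
}

parse_num <- function(x, path, col, allow_na = FALSE) {
  blank <- x == ""
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !blank
  if (any(bad))
    abort_parse(path, which(bad)[1] + 1L,
                sprintf("non-numeric value '%s' in column '%s'",
                        x[which(bad)[1]], col))
  if (!allow_na && any(blank))
    abort_parse(path, which(blank)[1] + 1L,
                sprintf("missing value in column '%s'", col))
  v
}

#' Read a session from its directory
#'
#' Reads the delimited-text session layout (see Details) and returns a fully
#' validated [session()]. Blank SpO2 cells become missing samples (`NA`),
#' never zeros.
#'
#' @details Layout: `streams/<device_id>.csv` (columns `t,spo2`; seconds and
#'   percent), `annotations.csv` (`label,start,stop`), `references.csv`
#'   (`t,sao2,phase,label,kind`), and `session.yml` with `key: value`
#'   metadata lines. All files are comma-separated with a header row, UTF-8,
#'   `.` decimal separator, empty field = missing.
#'
#' @param path Session directory.
#' @return An `oxival_session`.
#' @seealso [write_session()]
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no such session directory: ", path,
                              call. = FALSE)
  meta_path <- file.path(path, "session.yml")
  meta <- list()
  if (file.exists(meta_path)) {
    for (ln in readLines(meta_path, encoding = "UTF-8")) {
      if (!nzchar(trimws(ln))) next
      kv <- regmatches(ln, regexec("^([^:]+):[ ]?(.*)$", ln))[[1]]
      if (length(kv) != 3L)
        abort_parse(meta_path, match(ln, readLines(meta_path)),
                    "expected 'key: value'")
      val <- kv[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[2])]] <- if (!is.na(num)) num else val
    }
  }
  session_id <- if (!is.null(meta$session_id)) as.character(meta$session_id)
                else basename(path)
  meta$session_id <- NULL
  if (length(meta) == 0L) meta <- list()  # drop empty names attribute

  sdir <- file.path(path, "streams")
  files <- sort(list.files(sdir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no stream files under ", sdir, call. = FALSE)
  streams <- list()
  for (f in files) {
    dev <- sub("\\.csv$", "", basename(f))
    df <- read_csv_strict(f, c("t", "spo2"))
    t <- parse_num(df$t, f, "t")
    v <- parse_num(df$spo2, f, "spo2", allow_na = TRUE)
    if (length(t) > 1L && any(diff(t) <= 0)) {
      i <- which(diff(t) <= 0)[1]
      stop(sprintf("validation error in %s, line %d: non-monotone time (%g after %g)",
                   f, i + 2L, t[i + 1L], t[i]), call. = FALSE)
    }
    streams[[dev]] <- spo2_stream(dev, t, v)
  }

  afile <- file.path(path, "annotations.csv")
  adf <- read_csv_strict(afile, c("label", "start", "stop"))
  ann <- task_annotations(adf$label,
                          parse_num(adf$start, afile, "start"),
                          parse_num(adf$stop, afile, "stop"))

  rfile <- file.path(path, "references.csv")
  rdf <- read_csv_strict(rfile, c("t", "sao2", "phase", "label", "kind"))
  refs <- reference_samples(parse_num(rdf$t, rfile, "t"),
                            parse_num(rdf$sao2, rfile, "sao2"),
                            rdf$phase, rdf$label, rdf$kind)

  session(session_id, streams, ann, refs, demographics = meta)
}

write_csv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, useBytes = TRUE)
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(x) if (is.numeric(x)) num_chr(x) else as.character(x))
    writeLines(do.call(paste, c(cols, sep = ",")), con, useBytes = TRUE)
  }
}

#' Write a session to a directory
#'
#' Serializes with full numeric precision so `read_session(write_session(s))`
#' reproduces `s` exactly, including dropout gaps.
#'
#' @param session An `oxival_session`.
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "oxival_session"))
  dir.create(file.path(path, "streams"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- c(list(session_id = session$session_id), session$demographics)
  writeLines(vapply(names(meta),
                    function(k) paste0(k, ": ", format(meta[[k]], digits = 17)),
                    character(1)),
             file.path(path, "session.yml"), useBytes = TRUE)
  for (s in session$streams)
    write_csv_plain(data.frame(t = s$t, spo2 = s$spo2),
                    file.path(path, "streams", paste0(s$device_id, ".csv")))
  write_csv_plain(as.data.frame(session$annotations),
                  file.path(path, "annotations.csv"))
  write_csv_plain(as.data.frame(session$references),
                  file.path(path, "references.csv"))
  invisible(path)
}

#' Read a study dataset (directory of session directories)
#' @param path Dataset directory; every subdirectory is read as one session.
#' @return An `oxival_study`.
#' @export
read_study <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (length(dirs) == 0L) stop("no session directories under ", path,
                               call. = FALSE)
  study_dataset(lapply(dirs, read_session))
}

#' Write a study dataset as a tree of session directories
#' @param study An `oxival_study`.
#' @param path Target directory.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "oxival_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in study$sessions)
    write_session(s, file.path(path, s$session_id))
  invisible(path)
}
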