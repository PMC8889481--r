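#' Derive reproducible child seeds from one master seed
#'
#' One global seed is expanded into per-stage (or per-session) child seeds so
#' that pipeline stages remain individually reproducible. The split is a
#' draw of `n` distinct integers from `[1, 2^31 - 2]` under the master seed,
#' so child streams are decoupled from how many draws each stage consumes.
#'
#' @param seed Master seed (single integer).
#' @param n Number of child seeds required.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# run code under a seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Motion-task label vocabulary
#'
#' The seven protocol tasks, in protocol order. Unknown labels are rejected
#' by the readers and constructors so reports stay well-typed.
#' @return Character vector of task labels.
#' @export
task_labels <- function() {
  c("at-rest", "STS", "tapping", "rubbing", "drinking",
    "turning-pages", "tablet")
}

#' Hypoxia target-level label vocabulary
#' @return Character vector of plateau target labels (percent SaO2).
#' @export
target_labels <- function() {
  c("100", "95", "90", "87", "85", "83", "80")
}

abort_parse <- function(file, line, msg) {
  stop(sprintf("parse error in %s, line %d: %s", file, line, msg),
       call. = FALSE)
}

# full-precision numeric serialization: round-trips doubles bit-exactly
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
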