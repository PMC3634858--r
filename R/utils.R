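# Shared internal helpers.

GROUPS <- c("0-day", "5-day-Reach", "5-day-Sham", "12-day-Reach", "12-day-Sham")
SLOT_ROWS <- c("near", "mid", "far")
SLOT_SIDES <- c("ipsi", "contra")
DIGIT_POSITIONS <- c("d1", "d2", "d3", "d4", "d5", "between", "palm")

slot_ids <- function() {
  as.vector(outer(SLOT_ROWS, SLOT_SIDES, paste, sep = "_"))
}

#' Derive a reproducible child seed from a master seed
#'
#' Each simulation stage draws its randomness from its own child seed so
#' that stages can be regenerated independently of one another. Child
#' seeds are a deterministic hash-free function of `(seed, stage)` kept
#' below `2^31` so they are valid R integer seeds.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (e.g. `"behavior"`, `"arrays"`).
#' @return A single integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + offs * 104729) %% .Machine$integer.max)
}

# Stage-level progress messages go to stderr so stdout stays clean for data.
stage_log <- function(...) {
  message(sprintf(...))
}

stop_input <- function(...) abort(sprintf(...), class = "skilledreach_input_error")
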