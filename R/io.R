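# File formats and the shared data model.
#
# Expression data travel as a wide tibble: probe_id, gene_symbol, then one
# numeric column per sample on the log2(cy5/cy3) scale. Per-probe quality
# flags ("present"/"marginal"/"absent") live in a parallel wide tibble.
# Behavioral trials travel as one row per trial.

#' Construct the five-group study design
#'
#' Builds the sample sheet for the common-reference two-color design:
#' naive baseline (day 0), Reach and Sham at day 5 and day 12, with
#' `n_per_group` animals in each group (4 in the original design).
#'
#' @param n_per_group Animals per group.
#' @return A tibble with columns `sample_id`, `group`, `day`, `condition`.
#' @export
#' @examples
#' design_sheet()
design_sheet <- function(n_per_group = 4) {
  stopifnot(n_per_group >= 1)
  purrr::map_dfr(GROUPS, function(g) {
    day <- as.integer(sub("-day.*", "", g))
    cond <- if (day == 0) "Naive-baseline" else sub(".*-", "", g)
    tag <- c("0-day" = "d0", "5-day-Reach" = "d5R", "5-day-Sham" = "d5S",
             "12-day-Reach" = "d12R", "12-day-Sham" = "d12S")[[g]]
    tibble(
      sample_id = paste0(tag, "_", seq_len(n_per_group)),
      group = g, day = day, condition = cond
    )
  })
}

validate_sheet <- function(sheet) {
  need <- c("sample_id", "group", "day", "condition")
  if (!all(need %in% names(sheet))) {
    stop_input("sample sheet must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop_input("duplicated sample_id in sheet")
  bad <- setdiff(unique(sheet$group), GROUPS)
  if (length(bad)) stop_input("unknown group(s): %s", paste(bad, collapse = ", "))
  invisible(sheet)
}

#' Read a sample sheet CSV
#'
#' @param path CSV with columns `sample_id`, `group`, `day`, `condition`.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  sheet$day <- as.integer(sheet$day)
  validate_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sheet(sheet)
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sample_cols <- function(expr) {
  setdiff(names(expr), c("probe_id", "gene_symbol"))
}

#' Read an expression matrix TSV
#'
#' The file must have a header row, with first two columns `probe_id`
#' and `gene_symbol`, then one column per sample holding log2(cy5/cy3)
#' ratios. Duplicated probe identifiers and sample columns not matching
#' the sheet are rejected.
#'
#' @param path TSV file path.
#' @param sheet Sample sheet the columns are checked against.
#' @param flags Optional wide tibble of quality flags (`probe_id` plus
#'   one character column per sample in `{present, marginal, absent}`),
#'   attached as the `"flags"` attribute.
#' @return A wide tibble: `probe_id`, `gene_symbol`, sample columns.
#' @export
read_expression_matrix <- function(path, sheet, flags = NULL) {
  validate_sheet(sheet)
  expr <- as_tibble(read.delim(path, check.names = FALSE,
                               stringsAsFactors = FALSE,
                               colClasses = c(probe_id = "character",
                                              gene_symbol = "character")))
  validate_expression(expr, sheet)
  if (!is.null(flags)) attr(expr, "flags") <- flags
  expr
}

validate_expression <- function(expr, sheet = NULL) {
  if (!identical(names(expr)[1:2], c("probe_id", "gene_symbol"))) {
    stop_input("expression table must start with columns probe_id, gene_symbol")
  }
  dup <- expr$probe_id[duplicated(expr$probe_id)]
  if (length(dup)) {
    stop_input("duplicated probe_id: %s", paste(unique(dup), collapse = ", "))
  }
  if (!is.null(sheet)) {
    miss <- setdiff(sample_cols(expr), sheet$sample_id)
    if (length(miss)) {
      stop_input("sample column(s) not in sheet: %s", paste(miss, collapse = ", "))
    }
  }
  invisible(expr)
}

#' @rdname read_expression_matrix
#' @param expr Expression tibble as returned by [read_expression_matrix()].
#' @export
write_expression_matrix <- function(expr, path) {
  validate_expression(expr)
  out <- expr
  out$gene_symbol[is.na(out$gene_symbol)] <- ""
  # full precision so values survive the text round trip bit-exactly
  for (s in sample_cols(out)) out[[s]] <- sprintf("%.17g", out[[s]])
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the probe quality-flag policy
#'
#' The default policy drops a probe from analysis when it is flagged
#' marginal or absent in any sample (the probe is omitted from further
#' analysis); `"per_sample"` instead masks only the flagged cells with
#' `NA`.
#'
#' @param expr Expression tibble with a `"flags"` attribute (if absent,
#'   returned unchanged).
#' @param policy `"any"` (drop probe) or `"per_sample"` (mask cells).
#' @return Filtered/masked expression tibble.
#' @export
apply_flag_policy <- function(expr, policy = c("any", "per_sample")) {
  policy <- match.arg(policy)
  flags <- attr(expr, "flags")
  if (is.null(flags)) return(expr)
  samples <- intersect(sample_cols(expr), names(flags))
  fm <- as.matrix(flags[match(expr$probe_id, flags$probe_id), samples])
  bad <- fm != "present"
  bad[is.na(bad)] <- FALSE
  if (policy == "any") {
    out <- expr[rowSums(bad) == 0, , drop = FALSE]
    attr(out, "flags") <- NULL
    out
  } else {
    vm <- as.matrix(expr[samples])
    vm[bad] <- NA_real_
    out <- expr
    out[samples] <- as_tibble(vm)
    out
  }
}

TRIAL_COLS <- c("rat_id", "day", "slot_row", "slot_side", "n_reaches",
                "success", "dropped", "digit_position",
                "strategy_under_finger", "strategy_proximal_pip",
                "trial_duration_s")

validate_trials <- function(trials) {
  need <- c("rat_id", "day", "slot_row", "slot_side", "n_reaches",
            "success", "dropped")
  if (!all(need %in% names(trials))) {
    stop_input("trials must have columns %s", paste(need, collapse = ", "))
  }
  bad <- which(trials$dropped & !trials$success)
  if (length(bad)) {
    stop_input("row %d: dropped=1 requires success=1", bad[1])
  }
  bad <- which(trials$success & trials$n_reaches < 1)
  if (length(bad)) {
    stop_input("row %d: success=1 requires n_reaches >= 1", bad[1])
  }
  bad <- which(!(trials$slot_row %in% SLOT_ROWS) |
                 !(trials$slot_side %in% SLOT_SIDES))
  if (length(bad)) {
    stop_input("row %d: slot must be one of %s x %s", bad[1],
               paste(SLOT_ROWS, collapse = "/"), paste(SLOT_SIDES, collapse = "/"))
  }
  invisible(trials)
}

#' Read behavioral trial records
#'
#' One row per trial; booleans coded 0/1. Records violating the trial
#' invariants (a dropped pellet implies a successful grasp; a success
#' implies at least one reach; slots are the six row-by-side positions)
#' are rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return A tibble of validated trial records.
#' @export
read_trials <- function(path) {
  tr <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  for (col in c("success", "dropped", "strategy_under_finger", "strategy_proximal_pip")) {
    if (col %in% names(tr)) tr[[col]] <- as.logical(tr[[col]])
  }
  if ("digit_position" %in% names(tr)) {
    tr$digit_position[tr$digit_position == ""] <- NA_character_
  }
  validate_trials(tr)
  tr
}

#' @rdname read_trials
#' @param trials Trial tibble.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials
  for (col in c("success", "dropped", "strategy_under_finger", "strategy_proximal_pip")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a deterministic analysis report
#'
#' Serializes any subset of stage outputs (differential-expression
#' probe tables, model-fit tables, QC summaries, ...) to a directory as
#' TSV files plus a JSON manifest. Tables are sorted (ascending p-value
#' where present, then probe/first identifier) so identical inputs give
#' byte-identical output.
#'
#' @param results Named list of data frames (and/or scalar lists, which
#'   go into the manifest).
#' @param path Output directory, created if needed.
#' @param manifest Optional named list (config echo, seed, versions)
#'   written as `manifest.json`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, path, manifest = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in sort(names(results))) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      ord <- order_for_report(x)
      x <- x[ord, , drop = FALSE]
      f <- file.path(path, paste0(nm, ".tsv"))
      write.table(x, f, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    } else {
      manifest[[nm]] <- x
    }
  }
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, mf)
  invisible(written)
}

order_for_report <- function(x) {
  pcol <- intersect(c("p_value", "p"), names(x))
  idcol <- intersect(c("probe_id", "gene", "gene_symbol", "rat_id"), names(x))
  keys <- list()
  if (length(pcol)) keys <- c(keys, list(x[[pcol[1]]]))
  if (length(idcol)) keys <- c(keys, list(x[[idcol[1]]]))
  if (!length(keys)) return(seq_len(nrow(x)))
  do.call(order, keys)
}
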