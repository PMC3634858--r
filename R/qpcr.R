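# qPCR validation workflow.
#
# C_T data travel long: one row per (gene, sample, replicate) threshold
# cycle. Triplicates are aggregated by mean (an optional outlier-cycle
# rejection is available), normalized to a reference gene (delta-Ct),
# and compared across conditions via 2^-delta(delta-Ct) fold changes and
# Kruskal-Wallis tests. Amplification efficiency comes from the slope of
# the standard curve over a dilution series.

#' Amplification efficiency from a dilution series
#'
#' OLS slope of mean C_T against log10(relative input) over the
#' dilution series; efficiency (%) = (10^(-1/slope) - 1) x 100. The
#' textbook slope of -3.3219 (= -1/log10(2)) corresponds to perfect
#' doubling, 100%.
#'
#' @param series Tibble with `dilution_step` (0, 1, 2, ... consecutive
#'   dilutions) and `ct`; replicate rows per step are averaged.
#' @param dilution_factor Fold dilution per step (default 5).
#' @return Tibble `slope`, `efficiency` (%), `r_squared`, `valid`
#'   (FALSE when the slope is non-negative).
#' @export
efficiency_from_dilution <- function(series, dilution_factor = 5) {
  pts <- series %>%
    group_by(.data$dilution_step) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  if (nrow(pts) < 3) stop_input("need at least 3 dilution points")
  log_input <- -pts$dilution_step * log10(dilution_factor)
  fit <- lm(pts$ct ~ log_input)
  slope <- unname(coef(fit)[2])
  valid <- slope < 0
  tibble(
    slope = slope,
    efficiency = if (valid) (10^(-1 / slope) - 1) * 100 else NA_real_,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    valid = valid
  )
}

#' Slope of the standard curve implied by an efficiency
#'
#' Inverse of the efficiency formula, for round-trip checks and
#' simulation: slope = -1 / log10(1 + E/100).
#'
#' @param efficiency Percent efficiency.
#' @return Slope in cycles per log10 input.
#' @export
slope_from_efficiency <- function(efficiency) {
  -1 / log10(1 + efficiency / 100)
}

mean_ct <- function(ct, reject_outliers = FALSE, max_dev = 0.5) {
  ct %>%
    group_by(.data$gene, .data$sample_id) %>%
    summarise(ct = {
      v <- .data$ct
      if (reject_outliers && length(v) >= 3) {
        v <- v[abs(v - median(v)) <= max_dev]
      }
      mean(v)
    }, .groups = "drop")
}

#' Select reference genes by C_T-versus-concentration correlation
#'
#' A good reference gene's C_T should track the amount of input RNA
#' and nothing else. Per candidate, the Pearson correlation of mean
#' C_T against log10(RNA concentration) is computed across samples;
#' candidates are ranked by |r| (the correlation is naturally negative)
#' and the top two returned, ties broken lexicographically. Candidates
#' with constant C_T are excluded with a warning.
#'
#' @param ct Long C_T tibble (`gene`, `sample_id`, `replicate`, `ct`).
#' @param conc Tibble `sample_id`, `rna_conc` (A260-derived, positive).
#' @param candidates Candidate reference gene ids.
#' @return List with `references` (the two selected ids) and `ranking`
#'   (tibble `gene`, `r`, `abs_r`).
#' @export
select_references <- function(ct, conc, candidates) {
  mc <- mean_ct(ct %>% filter(.data$gene %in% candidates))
  ranking <- mc %>%
    left_join(conc, by = "sample_id") %>%
    group_by(.data$gene) %>%
    summarise(
      r = {
        ok <- !is.na(.data$ct) & !is.na(.data$rna_conc)
        if (sum(ok) >= 3 && sd(.data$ct[ok]) > 0)
          cor(.data$ct[ok], log10(.data$rna_conc[ok])) else NA_real_
      },
      .groups = "drop"
    ) %>%
    mutate(abs_r = abs(.data$r)) %>%
    arrange(dplyr::desc(.data$abs_r), .data$gene)
  if (any(is.na(ranking$r))) {
    warn(sprintf("candidate(s) excluded (constant C_T or <3 samples): %s",
                 paste(ranking$gene[is.na(ranking$r)], collapse = ", ")))
  }
  ok <- ranking[!is.na(ranking$r), ]
  if (nrow(ok) < 2) stop_input("fewer than 2 valid reference candidates")
  list(references = ok$gene[1:2], ranking = ranking)
}

#' Normalize C_T values to a reference gene
#'
#' delta-Ct(gene, sample) = mean triplicate C_T of the gene minus mean
#' triplicate C_T of the reference in the same sample. Samples missing
#' the reference get `NA`.
#'
#' @inheritParams select_references
#' @param reference Reference gene id.
#' @param reject_outliers Drop replicate cycles more than `max_dev`
#'   from the within-well median before averaging (default off).
#' @param max_dev Outlier threshold in cycles (default 0.5).
#' @return Tibble `gene`, `sample_id`, `dct`.
#' @export
normalize_ct <- function(ct, reference, reject_outliers = FALSE, max_dev = 0.5) {
  mc <- mean_ct(ct, reject_outliers, max_dev)
  ref <- mc %>% filter(.data$gene == reference) %>%
    select("sample_id", ref_ct = "ct")
  if (nrow(ref) == 0) stop_input("reference gene %s not measured", reference)
  mc %>%
    left_join(ref, by = "sample_id") %>%
    mutate(dct = .data$ct - .data$ref_ct) %>%
    select("gene", "sample_id", "dct")
}

#' Fold change by the 2^-delta(delta-Ct) method
#'
#' `fold = 2^-(mean(dct_a) - mean(dct_b))`, condition A relative to
#' condition B.
#'
#' @param dct_a,dct_b Numeric delta-Ct vectors for the two conditions.
#' @return The linear fold change.
#' @seealso [signed_fold()] for the direction-comparison convention.
#' @export
fold_change_ddct <- function(dct_a, dct_b) {
  dct_a <- dct_a[!is.na(dct_a)]; dct_b <- dct_b[!is.na(dct_b)]
  if (!length(dct_a) || !length(dct_b)) stop_input("empty condition")
  2^-(mean(dct_a) - mean(dct_b))
}

#' Signed fold-change convention
#'
#' Maps a linear fold f < 1 to its negative reciprocal -1/f, so that a
#' positive ratio of two signed folds indicates directional agreement.
#'
#' @param fold Linear fold change(s), positive.
#' @return Signed fold(s).
#' @export
signed_fold <- function(fold) {
  ifelse(fold >= 1, fold, -1 / fold)
}

#' Condition test on normalized C_T values
#'
#' Kruskal-Wallis test that the 5-day-Reach normalized C_T values
#' differ from the other conditions, run once per candidate reference;
#' the reported p is the smaller of the two and the winning reference
#' is recorded (the reference used for that gene's fold changes).
#'
#' @param ct Long C_T tibble.
#' @param gene Gene to test.
#' @param sheet Sample sheet restricted to the assayed conditions.
#' @param references One or two reference gene ids.
#' @return Tibble `gene`, `reference`, `p_value` (one row: the winning
#'   reference).
#' @export
condition_test <- function(ct, gene, sheet, references) {
  res <- purrr::map_dfr(references, function(ref) {
    dct <- normalize_ct(ct, ref) %>%
      filter(.data$gene == !!gene) %>%
      left_join(sheet[, c("sample_id", "group")], by = "sample_id") %>%
      filter(!is.na(.data$dct), !is.na(.data$group))
    groups <- split(dct$dct, dct$group)
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 2) {
      return(tibble(gene = gene, reference = ref, p_value = NA_real_))
    }
    tibble(gene = gene, reference = ref,
           p_value = kruskal_wallis(groups)$p_value)
  })
  res %>% arrange(.data$p_value, .data$reference) %>% dplyr::slice(1)
}

#' Agreement between qPCR and array fold changes
#'
#' Joins matched (gene, comparison) fold changes from the two
#' platforms, converts both to the signed convention, and reports
#' per-comparison sign agreement plus the total count. Optionally, a
#' per-gene Pearson correlation between sample-level array log2
#' intensities and sign-inverted qPCR delta-Ct values.
#'
#' @param qpcr_folds Tibble `gene`, `comparison`, `fold` (linear) from
#'   qPCR.
#' @param array_folds Tibble `gene`, `comparison`, `fold` (linear) from
#'   the arrays.
#' @return List with `comparisons` (tibble `gene`, `comparison`,
#'   `fold_qpcr`, `fold_array` signed, `ratio`, `agree`) and `summary`
#'   (tibble `n`, `n_agree`).
#' @export
array_agreement <- function(qpcr_folds, array_folds) {
  joined <- dplyr::inner_join(
    qpcr_folds %>% rename(fold_qpcr = "fold"),
    array_folds %>% rename(fold_array = "fold"),
    by = c("gene", "comparison")
  )
  n_dropped <- nrow(qpcr_folds) - nrow(joined)
  if (n_dropped > 0) warn(sprintf("%d unmatched comparison(s) excluded", n_dropped))
  comp <- joined %>%
    mutate(
      fold_qpcr = signed_fold(.data$fold_qpcr),
      fold_array = signed_fold(.data$fold_array),
      ratio = .data$fold_qpcr / .data$fold_array,
      agree = .data$ratio > 0
    )
  list(comparisons = comp,
       summary = tibble(n = nrow(comp), n_agree = sum(comp$agree)))
}

#' Per-gene correlation between array intensity and qPCR expression
#'
#' Pearson correlation, across matched samples, of the array log2
#' intensity against -delta-Ct (so both scales increase with
#' expression).
#'
#' @param array_values Tibble `sample_id`, `value` (log2 intensity).
#' @param dct Tibble `sample_id`, `dct` for the same gene.
#' @return Tibble `r`, `p_value`, `n`.
#' @export
array_qpcr_correlation <- function(array_values, dct) {
  joined <- dplyr::inner_join(array_values, dct, by = "sample_id") %>%
    filter(!is.na(.data$value), !is.na(.data$dct))
  if (nrow(joined) < 3) stop_input("need at least 3 matched samples")
  ct <- cor.test(joined$value, -joined$dct)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(joined))
}
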