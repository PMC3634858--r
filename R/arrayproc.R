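# Two-channel array preprocessing and quality control.
#
# Raw arrays are long tibbles: one row per (sample_id, probe_id) with
# positive cy5 ("red", sample) and cy3 ("green", common reference)
# intensities. Each array is normalized within itself: M = log2(R/G) is
# corrected for intensity-dependent dye bias by a robust locally
# weighted regression of M on A = (log2 R + log2 G) / 2.

#' Background-subtract channel intensities
#'
#' Subtracts a per-channel constant floor (the given low percentile of
#' that channel, per array) and clips so intensities stay positive.
#'
#' @param raw Long raw-array tibble (`sample_id`, `probe_id`, `red`,
#'   `green`).
#' @param percentile Floor percentile per channel (default 5).
#' @param floor Minimum retained intensity (default 1).
#' @return The tibble with corrected `red`/`green`.
#' @export
background_subtract <- function(raw, percentile = 5, floor = 1) {
  raw %>%
    group_by(.data$sample_id) %>%
    mutate(
      red = pmax(.data$red - quantile(.data$red, percentile / 100), floor),
      green = pmax(.data$green - quantile(.data$green, percentile / 100), floor)
    ) %>%
    ungroup()
}

#' Lowess MA normalization of one two-color array
#'
#' Computes M = log2(red/green) and A = (log2 red + log2 green)/2 and
#' removes the intensity-dependent trend fitted by lowess (tricube
#' locally weighted regression with robustness iterations) of M on A.
#' With fewer than 10 probes no trend can be estimated; the raw M is
#' returned with a warning.
#'
#' @param array_tbl Tibble for a single array: `probe_id`, `red`,
#'   `green` (both positive).
#' @param span Lowess smoother span (default 0.3).
#' @param iterations Robustness iterations (default 3).
#' @return Tibble `probe_id`, `A`, `M`, `M_norm`.
#' @export
normalize_lowess <- function(array_tbl, span = 0.3, iterations = 3) {
  stopifnot(all(array_tbl$red > 0), all(array_tbl$green > 0))
  M <- log2(array_tbl$red / array_tbl$green)
  A <- 0.5 * (log2(array_tbl$red) + log2(array_tbl$green))
  if (nrow(array_tbl) < 10) {
    warn("fewer than 10 probes: returning unnormalized log ratios")
    return(tibble(probe_id = array_tbl$probe_id, A = A, M = M, M_norm = M))
  }
  fit <- lowess(A, M, f = span, iter = iterations)
  trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2)$y
  tibble(probe_id = array_tbl$probe_id, A = A, M = M, M_norm = M - trend)
}

#' Normalize every array into an expression matrix
#'
#' Applies [normalize_lowess()] per sample and assembles the wide
#' log2-ratio expression tibble.
#'
#' @param raw Long raw-array tibble.
#' @param annotation Optional tibble `probe_id`, `gene_symbol`.
#' @inheritParams normalize_lowess
#' @return Wide expression tibble (`probe_id`, `gene_symbol`, samples).
#' @export
normalize_arrays <- function(raw, annotation = NULL, span = 0.3, iterations = 3) {
  norm <- raw %>%
    group_by(.data$sample_id) %>%
    dplyr::group_modify(~ normalize_lowess(.x, span = span, iterations = iterations)) %>%
    ungroup()
  wide <- norm %>%
    select("probe_id", "sample_id", "M_norm") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "M_norm")
  if (is.null(annotation)) {
    annotation <- tibble(probe_id = wide$probe_id, gene_symbol = NA_character_)
  }
  annotation %>%
    dplyr::inner_join(wide, by = "probe_id")
}

#' Cross-array channel variability at signal percentiles
#'
#' For each requested percentile of the raw signal distribution, takes
#' each array's percentile of the red (sample) and green (reference)
#' channel and computes the standard deviation across arrays, with a
#' two-sided F test of variance equality on (n-1, n-1) degrees of
#' freedom. In a common-reference design the red channel should be the
#' dominant source of inter-array variability.
#'
#' @param raw Long raw-array tibble; at least 3 arrays.
#' @param percentiles Percentiles of the signal distribution
#'   (default 25, 50, 75).
#' @return Tibble `percentile`, `sd_red`, `sd_green`, `f_statistic`,
#'   `p_value`.
#' @export
channel_variability <- function(raw, percentiles = c(25, 50, 75)) {
  n_arrays <- dplyr::n_distinct(raw$sample_id)
  if (n_arrays < 3) stop_input("need at least 3 arrays")
  per_array <- raw %>%
    group_by(.data$sample_id) %>%
    summarise(
      red_q = list(quantile(.data$red, percentiles / 100, names = FALSE)),
      green_q = list(quantile(.data$green, percentiles / 100, names = FALSE)),
      .groups = "drop"
    )
  purrr::map_dfr(seq_along(percentiles), function(i) {
    r <- purrr::map_dbl(per_array$red_q, i)
    g <- purrr::map_dbl(per_array$green_q, i)
    fstat <- var(r) / var(g)
    # two-sided p for H0: equal variances
    p <- 2 * min(pf(fstat, n_arrays - 1, n_arrays - 1),
                 pf(fstat, n_arrays - 1, n_arrays - 1, lower.tail = FALSE))
    tibble(percentile = percentiles[i], sd_red = sd(r), sd_green = sd(g),
           f_statistic = fstat, p_value = min(p, 1))
  })
}

#' Hybridization consistency across groups
#'
#' Per-array ordinary least squares slope of log10(red) on log10(green)
#' over all probes, followed by a one-way ANOVA of the slopes across
#' experimental groups. Consistent hybridization quality shows as
#' slopes that do not differ across groups. Arrays with a degenerate
#' (constant) channel are excluded with a warning; when every slope is
#' identical the ANOVA is flagged degenerate.
#'
#' @param raw Long raw-array tibble.
#' @param sheet Sample sheet mapping `sample_id` to `group`.
#' @return List with `slopes` (tibble `sample_id`, `group`, `slope`)
#'   and `anova` (tibble `statistic`, `df1`, `df2`, `p_value`,
#'   `degenerate`).
#' @export
hybridization_consistency <- function(raw, sheet) {
  validate_sheet(sheet)
  slopes <- raw %>%
    group_by(.data$sample_id) %>%
    summarise(slope = {
      lg <- log10(.data$green); lr <- log10(.data$red)
      if (sd(lg) == 0 || sd(lr) == 0) NA_real_ else
        unname(coef(lm(lr ~ lg))[2])
    }, .groups = "drop") %>%
    left_join(sheet[, c("sample_id", "group")], by = "sample_id")
  if (anyNA(slopes$slope)) {
    warn("array(s) with a constant channel excluded from slope ANOVA")
    slopes_ok <- slopes[!is.na(slopes$slope), ]
  } else slopes_ok <- slopes
  if (dplyr::n_distinct(slopes_ok$group) < 2 ||
      any(table(slopes_ok$group) < 2)) {
    stop_input("need >= 2 groups with >= 2 arrays each")
  }
  if (sd(slopes_ok$slope) == 0) {
    av <- tibble(statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                 p_value = NA_real_, degenerate = TRUE)
  } else {
    tab <- anova(aov(slope ~ group, data = slopes_ok))
    av <- tibble(statistic = tab[1, "F value"], df1 = tab[1, "Df"],
                 df2 = tab[2, "Df"], p_value = tab[1, "Pr(>F)"],
                 degenerate = tab[2, "Mean Sq"] == 0)
  }
  list(slopes = slopes, anova = av)
}
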