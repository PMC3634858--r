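# Behavioral learning measures.
#
# Two per-day measures of skill acquisition: the percentage of successful
# trials in which the pellet was dropped after grasping (movement quality,
# pooled across all slots), and successes per reach (task-goal achievement,
# computable for any slot subset). Slots are classified Learned vs
# Not-Learned by the Pearson trend of the smoothed per-slot curve.

curve_groups <- function(curve) {
  intersect(c("rat_id", "slot", "slot_set"), names(curve))
}

#' Percentage of successful trials with dropped pellets, per day
#'
#' Movement-quality learning measure: for each rat and day,
#' 100 x (successful trials with a drop) / (successful trials), computed
#' across all slots together since dropping is a post-grasp event. Days
#' with no successful trial get a missing value and are excluded from
#' downstream trend tests and fits.
#'
#' @param trials Trial tibble (see [read_trials()]).
#' @return A tibble `rat_id`, `day`, `value` (percent), `n_trials`
#'   (successful trials that day).
#' @export
drop_percentage <- function(trials) {
  validate_trials(trials)
  trials %>%
    group_by(.data$rat_id, .data$day) %>%
    summarise(
      value = if (sum(.data$success) == 0) NA_real_ else
        100 * sum(.data$success & .data$dropped) / sum(.data$success),
      n_trials = sum(.data$success),
      .groups = "drop"
    )
}

#' Successes per reach, per day
#'
#' Task-goal achievement measure: pellets retrieved in the session
#' divided by the total number of reaches displayed, an empirical
#' estimate of the probability that any single reach retrieves the
#' pellet. Days with zero reaches get a missing value.
#'
#' @param trials Trial tibble.
#' @param slots Optional character vector of slot ids (`"row_side"`,
#'   e.g. `"near_ipsi"`) to restrict to; default all slots.
#' @return A tibble `rat_id`, `day`, `value` (probability), `n_trials`.
#' @export
success_per_reach <- function(trials, slots = NULL) {
  validate_trials(trials)
  tr <- trials %>% mutate(slot = paste(.data$slot_row, .data$slot_side, sep = "_"))
  if (!is.null(slots)) tr <- tr %>% filter(.data$slot %in% slots)
  tr %>%
    group_by(.data$rat_id, .data$day) %>%
    summarise(
      value = if (sum(.data$n_reaches) == 0) NA_real_ else
        sum(.data$success) / sum(.data$n_reaches),
      n_trials = n(),
      .groups = "drop"
    )
}

#' Smooth a learning curve with a moving-average filter
#'
#' Centered moving average of the given (odd) window width. At the ends
#' of the series the window truncates to the available days; missing
#' values are skipped. `window = 1` is the identity.
#'
#' @param curve Tibble with `day` and `value` columns (plus optional
#'   grouping columns `rat_id`/`slot`, smoothed independently).
#' @param window Odd integer window width in days (default 3).
#' @param edges `"truncate"` (default) shrinks the window at the series
#'   ends; `"valid"` leaves end values at positions without a full
#'   window as `NA`.
#' @return The curve with `value` replaced by its smoothed version.
#' @export
moving_average <- function(curve, window = 3, edges = c("truncate", "valid")) {
  edges <- match.arg(edges)
  if (nrow(curve) == 0) stop_input("empty curve")
  stopifnot(window >= 1, window %% 2 == 1)
  half <- (window - 1) / 2
  smooth_one <- function(df) {
    df <- df[order(df$day), , drop = FALSE]
    v <- df$value
    out <- vapply(seq_along(v), function(i) {
      lo <- max(1, i - half); hi <- min(length(v), i + half)
      if (edges == "valid" && (hi - lo + 1) < window) return(NA_real_)
      w <- v[lo:hi]
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, numeric(1))
    df$value <- out
    df
  }
  grp <- curve_groups(curve)
  if (length(grp)) {
    curve %>% group_by(across(all_of(grp))) %>%
      dplyr::group_modify(~ smooth_one(.x)) %>% ungroup()
  } else {
    as_tibble(smooth_one(as.data.frame(curve)))
  }
}

#' Pearson trend of a learning curve
#'
#' Pearson correlation of value against day with the two-sided p-value
#' from the t transform on n - 2 degrees of freedom. A curve with zero
#' variance (or fewer than 3 non-missing days) is reported as
#' non-significant with `r = NA`.
#'
#' @param curve Tibble with `day` and `value` (grouping columns
#'   `rat_id`/`slot` handled per group).
#' @return Tibble with `r`, `p_value`, `n` per group.
#' @export
pearson_trend <- function(curve) {
  trend_one <- function(df) {
    ok <- !is.na(df$value)
    x <- df$day[ok]; y <- df$value[ok]
    if (length(y) < 3 || sd(y) == 0 || sd(x) == 0) {
      return(tibble(r = NA_real_, p_value = 1, n = length(y)))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(y))
  }
  grp <- curve_groups(curve)
  if (length(grp)) {
    curve %>% group_by(across(all_of(grp))) %>%
      dplyr::group_modify(~ trend_one(.x)) %>% ungroup()
  } else {
    trend_one(curve)
  }
}

#' Classify slots as Learned or Not-Learned
#'
#' Per rat and slot: compute the per-slot success-per-reach curve,
#' smooth it with a moving-average filter, and test its Pearson trend.
#' A slot with a positive and significant (p < `alpha`) coefficient is
#' Learned. Pooled curves are then re-computed over the Learned and
#' Not-Learned slot sets on the original un-smoothed trial data.
#'
#' @param trials Trial tibble.
#' @param alpha Significance level (default 0.05).
#' @param window Moving-average window in days (default 3).
#' @return A list with `classification` (tibble `rat_id`, `slot`, `r`,
#'   `p_value`, `learned`) and `pooled` (tibble `rat_id`, `slot_set` in
#'   `{Learned, NotLearned}`, `day`, `value`, `n_trials`; empty slot sets
#'   are omitted).
#' @export
classify_slots <- function(trials, alpha = 0.05, window = 3) {
  validate_trials(trials)
  tr <- trials %>% mutate(slot = paste(.data$slot_row, .data$slot_side, sep = "_"))
  per_slot <- tr %>%
    group_by(.data$rat_id, .data$slot, .data$day) %>%
    summarise(
      value = if (sum(.data$n_reaches) == 0) NA_real_ else
        sum(.data$success) / sum(.data$n_reaches),
      .groups = "drop"
    )
  cls <- per_slot %>%
    moving_average(window = window) %>%
    pearson_trend() %>%
    mutate(learned = !is.na(.data$r) & .data$r > 0 & .data$p_value < alpha) %>%
    select("rat_id", "slot", "r", "p_value", "learned")
  pooled <- purrr::map_dfr(split(cls, cls$rat_id), function(cl) {
    rat_tr <- trials %>% filter(.data$rat_id == cl$rat_id[1])
    purrr::map_dfr(c("Learned", "NotLearned"), function(set) {
      slots <- if (set == "Learned") cl$slot[cl$learned] else cl$slot[!cl$learned]
      if (!length(slots)) return(tibble())
      success_per_reach(rat_tr, slots = slots) %>%
        mutate(slot_set = set, .after = "rat_id")
    })
  })
  list(classification = cls, pooled = pooled)
}

#' First-block versus last-block one-way ANOVA
#'
#' Compares two blocks of per-day values (e.g. first five vs last five
#' training days, pooled across rats) with a one-way fixed-effects
#' ANOVA, equivalently a two-sample F test on means.
#'
#' @param block_a,block_b Numeric vectors of un-smoothed values.
#' @return Tibble `statistic` (F), `df1`, `df2`, `p_value`, `degenerate`
#'   (TRUE when within-group variance is zero).
#' @export
block_anova <- function(block_a, block_b) {
  block_a <- block_a[!is.na(block_a)]; block_b <- block_b[!is.na(block_b)]
  if (length(block_a) < 2 || length(block_b) < 2) {
    stop_input("each block needs at least 2 values")
  }
  y <- c(block_a, block_b)
  df1 <- 1L; df2 <- length(y) - 2L
  if (var(block_a) == 0 && var(block_b) == 0) {
    # zero within-group variance: flagged degenerate; with equal means
    # there is neither effect nor noise
    if (mean(block_a) == mean(block_b)) {
      return(tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                    degenerate = TRUE))
    }
    return(tibble(statistic = Inf, df1 = df1, df2 = df2, p_value = 0,
                  degenerate = TRUE))
  }
  g <- factor(rep(c("a", "b"), c(length(block_a), length(block_b))))
  tab <- suppressWarnings(anova(aov(y ~ g)))
  tibble(statistic = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
         p_value = tab[1, "Pr(>F)"], degenerate = FALSE)
}

#' Determine limb preference from pre-training reach counts
#'
#' A rat prefers a limb if, on two consecutive days each with at least
#' 50 total reaches, more than 80% of the reaches came from that side.
#'
#' @param counts Tibble with `day`, `left`, `right` reach counts.
#' @param min_reaches Per-day total threshold (default 50).
#' @param frac Side fraction threshold, strict (default 0.8).
#' @return `"left"`, `"right"`, or `"undetermined"`.
#' @export
handedness <- function(counts, min_reaches = 50, frac = 0.8) {
  counts <- counts[order(counts$day), , drop = FALSE]
  if (nrow(counts) < 2) return("undetermined")
  tot <- counts$left + counts$right
  for (side in c("left", "right")) {
    ok <- tot >= min_reaches & counts[[side]] / tot > frac
    consec <- ok[-length(ok)] & ok[-1] & diff(counts$day) == 1
    if (any(consec)) return(side)
  }
  "undetermined"
}

#' Digit-placement frequencies in successful trials
#'
#' Relative frequency, per slot side, of the hand position over the
#' pellet immediately before grasping (one of the five digits, between
#' digits, or under the palm). Rows sum to 1.
#'
#' @param trials Trial tibble with `digit_position` annotated.
#' @return Tibble `slot_side`, one column per position; empty when no
#'   annotated successful trials exist.
#' @export
digit_use <- function(trials) {
  ok <- trials %>%
    filter(.data$success, !is.na(.data$digit_position))
  if (nrow(ok) == 0) return(tibble())
  ok %>%
    count(.data$slot_side, .data$digit_position) %>%
    group_by(.data$slot_side) %>%
    mutate(freq = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    mutate(digit_position = factor(.data$digit_position, levels = DIGIT_POSITIONS)) %>%
    tidyr::pivot_wider(names_from = "digit_position", values_from = "freq",
                       values_fill = 0, names_expand = TRUE)
}

#' Success rates with and without the hand-placement strategies
#'
#' Compares the success rate of trials in which the pellet was both
#' directly under a finger and proximal to the PIP joint at maximal
#' extension ("both" strategies) against trials employing neither, for
#' the near, mid and far slot rows. Per-rat cell rates feed a two-way
#' fixed-effects ANOVA (row x strategy, with interaction).
#'
#' @param trials Trial tibble with the two strategy flags annotated.
#' @return List with `rates` (per `slot_row` x `strategy` mean rate and
#'   n) and `anova` (tidy two-way ANOVA table).
#' @export
strategy_success <- function(trials) {
  tr <- trials %>%
    filter(!is.na(.data$strategy_under_finger), !is.na(.data$strategy_proximal_pip)) %>%
    mutate(strategy = dplyr::case_when(
      .data$strategy_under_finger & .data$strategy_proximal_pip ~ "both",
      !.data$strategy_under_finger & !.data$strategy_proximal_pip ~ "neither",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$strategy))
  cells <- tr %>%
    group_by(.data$rat_id, .data$slot_row, .data$strategy) %>%
    summarise(rate = mean(.data$success), n = n(), .groups = "drop")
  rates <- cells %>%
    group_by(.data$slot_row, .data$strategy) %>%
    summarise(rate = mean(.data$rate), n = sum(.data$n), .groups = "drop")
  fit <- aov(rate ~ slot_row * strategy, data = cells)
  tab <- suppressWarnings(anova(fit))
  anova_tbl <- tibble(
    term = rownames(tab),
    df = tab$Df, sumsq = tab$`Sum Sq`, statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  list(rates = rates, anova = anova_tbl)
}
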