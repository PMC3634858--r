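# Behavioral learning measures and supporting statistics.

mk_trials <- function(success, dropped = rep(FALSE, length(success)),
                      n_reaches = rep(1L, length(success)),
                      day = rep(1L, length(success)),
                      slot_row = "near", slot_side = "ipsi") {
  tibble::tibble(rat_id = "r1", day = day, slot_row = slot_row,
                 slot_side = slot_side, n_reaches = n_reaches,
                 success = success, dropped = dropped)
}

test_that("drop percentage is drops over successes, with boundary cases", {
  tr <- mk_trials(success = c(TRUE, TRUE, TRUE, TRUE),
                  dropped = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(drop_percentage(tr)$value, 50)
  expect_equal(drop_percentage(mk_trials(rep(TRUE, 3), rep(TRUE, 3)))$value, 100)
  expect_equal(drop_percentage(mk_trials(rep(TRUE, 3)))$value, 0)
  # day without successes is missing, not zero
  expect_true(is.na(drop_percentage(mk_trials(c(FALSE, FALSE)))$value))
})

test_that("drop percentage matches the generating drop rate", {
  cfg <- behavior_sim_config(n_rats = 1, n_days = 1, drop_init = 0.3,
                             drop_asym = 0.3)
  sim <- simulate_behavior(cfg, seed = 9)
  dp <- drop_percentage(sim$trials)
  n_succ <- dp$n_trials
  ci <- qbinom(c(0.005, 0.995), n_succ, 0.3) / n_succ * 100
  expect_gte(dp$value, ci[1])
  expect_lte(dp$value, ci[2])
})

test_that("success per reach divides successes by total reaches", {
  tr <- mk_trials(success = rep(c(TRUE, FALSE), c(10, 10)),
                  n_reaches = rep(2L, 20))
  expect_equal(success_per_reach(tr)$value, 0.25)
  expect_equal(success_per_reach(mk_trials(rep(FALSE, 5)))$value, 0)
  # invariant to trial order within a day
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(success_per_reach(shuffled)$value, 0.25)
  # slot restriction
  tr2 <- dplyr::bind_rows(tr, mk_trials(rep(TRUE, 4), slot_row = "far"))
  expect_equal(success_per_reach(tr2, slots = "far_ipsi")$value, 1)
})

test_that("moving average truncates at the edges and handles windows", {
  cv <- tibble::tibble(day = 1:3, value = c(1, 2, 3))
  expect_equal(moving_average(cv, 3)$value, c(1.5, 2, 2.5))
  const <- tibble::tibble(day = 1:6, value = rep(2.5, 6))
  expect_equal(moving_average(const, 3)$value, rep(2.5, 6))
  expect_equal(moving_average(cv, 1)$value, cv$value)
  # valid-only mode leaves incomplete windows missing
  expect_equal(moving_average(cv, 3, edges = "valid")$value, c(NA, 2, NA))
  # missing values are skipped, not propagated
  cv$value[2] <- NA
  expect_equal(moving_average(cv, 3)$value, c(1, 2, 3))
  expect_error(moving_average(cv[0, ], 3), "empty")
})

test_that("pearson trend reproduces the closed-form t-transform p", {
  cv <- tibble::tibble(day = 1:12, value = 1:12)
  pt <- pearson_trend(cv)
  expect_equal(pt$r, 1)
  # r = 0.576 at n = 12 sits just below the 0.05 threshold
  # (frozen from 2*pt(-r*sqrt(10/(1-r^2)), 10) = 0.0499917)
  r <- 0.576
  y <- r * scale(1:12)[, 1] + sqrt(1 - r^2) *
    scale(stats::resid(lm(rnorm(12) ~ seq_len(12))))[, 1]
  pt2 <- pearson_trend(tibble::tibble(day = 1:12, value = y))
  expect_equal(pt2$r, r, tolerance = 1e-10)
  expect_equal(pt2$p_value, 0.04999165, tolerance = 1e-5)
  expect_lt(pt2$p_value, 0.05)
  # zero variance is non-significant
  flat <- pearson_trend(tibble::tibble(day = 1:5, value = rep(1, 5)))
  expect_true(is.na(flat$r))
  expect_equal(flat$p_value, 1)
})

test_that("slot classification matches the brute-force oracle", {
  for (seed in 1:5) {
    cfg <- behavior_sim_config(n_rats = 2, n_days = 10,
                               trials_per_slot = 8,
                               learned_slot_fraction = 0.5)
    sim <- simulate_behavior(cfg, seed = seed)
    got <- classify_slots(sim$trials)$classification
    want <- bf_classify_slots(sim$trials)
    merged <- merge(as.data.frame(got), want, by = c("rat_id", "slot"),
                    suffixes = c("", "_bf"))
    expect_equal(nrow(merged), 12)
    expect_equal(merged$r, merged$r_bf, tolerance = 1e-12)
    expect_equal(merged$p_value, merged$p_value_bf, tolerance = 1e-12)
    expect_identical(merged$learned, merged$learned_bf)
  }
})

test_that("a strongly learned planted slot is classified Learned", {
  cfg <- behavior_sim_config(n_rats = 1, learned_slot_fraction = 1,
                             sigmoid_a = c(0.34, 0.35), sigmoid_c = c(0.9, 1),
                             sigmoid_d = c(0.01, 0.02))
  sim <- simulate_behavior(cfg, seed = 21)
  cls <- classify_slots(sim$trials)$classification
  expect_true(all(cls$learned))
  pooled <- classify_slots(sim$trials)$pooled
  expect_true(all(pooled$slot_set == "Learned"))
})

test_that("all-flat slots leave the Learned pool empty (un-smoothed rule)", {
  cfg <- behavior_sim_config(n_rats = 1, learned_slot_fraction = 0,
                             sigmoid_d = c(0.05, 0.05))
  sim <- simulate_behavior(cfg, seed = 2)
  cls <- classify_slots(sim$trials, window = 1)
  expect_false(any(cls$classification$learned))
  expect_false("Learned" %in% cls$pooled$slot_set)
})

test_that("block ANOVA matches the hand-computed F", {
  # SSB = 13.5, SSW = 4 on 4 df -> F = 13.5
  res <- block_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  ident <- block_anova(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_true(ident$degenerate)
})

test_that("handedness rule matches brute-force enumeration", {
  expect_equal(handedness(tibble::tibble(day = 1:2, left = c(45, 48),
                                         right = c(5, 2))), "left")
  expect_equal(handedness(tibble::tibble(day = 1, left = 40, right = 9)),
               "undetermined")
  # 41/51 = 0.804 > 0.8 on both days -> left
  expect_equal(handedness(tibble::tibble(day = 1:2, left = c(41, 41),
                                         right = c(10, 10))), "left")
  # exactly 80% fails the strict rule
  expect_equal(handedness(tibble::tibble(day = 1:2, left = c(40, 40),
                                         right = c(10, 10))), "undetermined")
  # non-consecutive qualifying days do not count
  expect_equal(handedness(tibble::tibble(day = c(1, 3), left = c(48, 48),
                                         right = c(2, 2))), "undetermined")
  # randomized brute-force check
  set.seed(7)
  for (i in 1:50) {
    days <- 1:4
    l <- rpois(4, 40); r <- rpois(4, 15)
    got <- handedness(tibble::tibble(day = days, left = l, right = r))
    want <- "undetermined"
    for (side in c("left", "right")) {
      cnt <- if (side == "left") l else r
      ok <- (l + r) >= 50 & cnt / (l + r) > 0.8
      if (any(ok[-4] & ok[-1])) { want <- side; break }
    }
    expect_equal(got, want)
  }
})

test_that("digit-use rows are normalized frequencies", {
  tr <- mk_trials(rep(TRUE, 1))
  tr$digit_position <- "d3"
  du <- digit_use(tr)
  expect_equal(du$d3, 1)
  expect_equal(sum(du[, -1]), 1)
  # simulated distributions recovered within multinomial tolerance
  sim <- simulate_behavior(behavior_sim_config(n_rats = 2,
                                               learned_slot_fraction = 1,
                                               sigmoid_d = c(0.2, 0.2)),
                           seed = 4)
  du2 <- digit_use(sim$trials)
  expect_equal(rowSums(du2[, -1]), rep(1, nrow(du2)), ignore_attr = TRUE)
  ipsi <- du2[du2$slot_side == "ipsi", ]
  expect_equal(ipsi$d3, 0.4, tolerance = 0.2)
  expect_equal(which.max(as.numeric(ipsi[, -1])),
               which(names(ipsi)[-1] == "d3"))
  none <- mk_trials(FALSE)
  none$digit_position <- NA_character_
  expect_equal(nrow(digit_use(none)), 0)
})

test_that("strategy success rates and two-way ANOVA behave", {
  # all strategy trials succeed, all others fail
  n <- 24
  tr <- tibble::tibble(
    rat_id = rep(c("r1", "r2"), each = n / 2),
    day = 1L,
    slot_row = rep(c("near", "mid", "far"), length.out = n),
    slot_side = "ipsi",
    n_reaches = 1L,
    success = rep(c(TRUE, FALSE), each = n / 2),
    dropped = FALSE,
    strategy_under_finger = rep(c(TRUE, FALSE), each = n / 2),
    strategy_proximal_pip = rep(c(TRUE, FALSE), each = n / 2)
  )
  res <- strategy_success(tr)
  expect_equal(res$rates$rate[res$rates$strategy == "both"], rep(1, 3))
  expect_equal(res$rates$rate[res$rates$strategy == "neither"], rep(0, 3))

  # balanced 2x3 table with hand-computable sums of squares
  cells <- expand.grid(rat_id = c("r1", "r2"), slot_row = c("near", "mid", "far"),
                       strategy = c(TRUE, FALSE))
  rate <- c(0.8, 0.9, 0.7, 0.8, 0.6, 0.7, 0.4, 0.5, 0.3, 0.4, 0.2, 0.3)
  # build one success/failure trial pair per cell encoding these rates via
  # 10 trials per cell
  tr2 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    k <- round(rate[i] * 10)
    tibble::tibble(rat_id = as.character(cells$rat_id[i]), day = 1L,
                   slot_row = as.character(cells$slot_row[i]),
                   slot_side = "ipsi", n_reaches = 1L,
                   success = rep(c(TRUE, FALSE), c(k, 10 - k)),
                   dropped = FALSE,
                   strategy_under_finger = cells$strategy[i],
                   strategy_proximal_pip = cells$strategy[i])
  }))
  res2 <- strategy_success(tr2)
  # hand computation on the 12 cell rates:
  # strategy means 0.75 vs 0.35 -> SS_strategy = 12 * (0.2^2) = 0.48
  tab <- res2$anova
  expect_equal(tab$sumsq[tab$term == "strategy"], 0.48, tolerance = 1e-12)
  # row means near 0.65, mid 0.55, far 0.45 -> SS_row = 4*sum((m-0.55)^2)
  expect_equal(tab$sumsq[tab$term == "slot_row"],
               4 * sum((c(0.65, 0.55, 0.45) - 0.55)^2), tolerance = 1e-12)
  expect_equal(tab$df, c(2, 1, 2, 6))
})
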