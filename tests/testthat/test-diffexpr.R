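# Differential-expression screen, subtraction, dynamics and rankings.

test_that("Kruskal-Wallis H matches the hand-ranked formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  # rank sums 3, 7, 11: H = 12/42 * (9/2 + 49/2 + 121/2) - 21 = 32/7
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$statistic, bf_kruskal_H(groups), tolerance = 1e-12)
  # identical values: no evidence
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$p_value, 1)
  # tie correction agrees with the oracle on random tied data
  set.seed(3)
  for (i in 1:20) {
    g <- split(sample(1:5, 12, replace = TRUE), rep(1:3, each = 4))
    expect_equal(kruskal_wallis(g)$statistic, bf_kruskal_H(g),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values track the chi-square approximation", {
  set.seed(4)
  g <- list(rnorm(4), rnorm(4) + 2, rnorm(4))
  chisq <- kruskal_wallis(g)$p_value
  perm <- kruskal_wallis(g, p_method = "permutation", n_perm = 500)$p_value
  expect_lt(abs(perm - chisq), 0.08)
})

test_that("the fold filter is >log2(fold) on the largest pair difference", {
  sheet <- design_sheet(2)
  # probe 1: means (0, 0.7, 0) over the Reach triple -> 2^0.7 = 1.62 passes
  # probe 2: means (0, 0.5, 0.2) -> max diff 0.5 -> 1.41 fails
  expr <- tibble::tibble(probe_id = c("A", "B"), gene_symbol = c("a", "b"))
  means <- list(A = c("0-day" = 0, "5-day-Reach" = 0.7, "12-day-Reach" = 0),
                B = c("0-day" = 0, "5-day-Reach" = 0.5, "12-day-Reach" = 0.2))
  for (i in seq_len(nrow(sheet))) {
    g <- sheet$group[i]
    expr[[sheet$sample_id[i]]] <- c(
      ifelse(g %in% names(means$A), means$A[g], 0),
      ifelse(g %in% names(means$B), means$B[g], 0)
    ) + c(0.001, -0.001) * i  # break ties without moving means appreciably
  }
  scr <- screen_modulated(expr, sheet, "Reach", alpha = 1.1, fold = 1.5)
  expect_equal(scr$max_pair_fold[1], 2^0.7, tolerance = 0.02)
  expect_true(scr$passes[1])
  expect_false(scr$passes[2])
})

test_that("list subtraction partitions reach, sham and both", {
  res <- subtract_lists(c("A", "B", "C"), "B")
  expect_equal(res$reach_specific, c("A", "C"))
  expect_equal(res$sham_specific, character())
  expect_equal(res$both, "B")
  disj <- subtract_lists(c("A", "B"), c("C", "D"))
  expect_equal(disj$reach_specific, c("A", "B"))
  expect_equal(disj$sham_specific, c("C", "D"))
  expect_equal(disj$counts$n, c(2, 2, 2, 2, 0))
})

test_that("delta dynamics subtract the sham (or reach) reference", {
  sheet <- design_sheet(2)
  set.seed(9)
  expr <- make_expr_fixture(6, sheet, effect_probes = 1:2,
                            effect_group = "5-day-Reach", effect = 1,
                            noise_sd = 0.05)
  dd <- delta_dynamics(expr, sheet, expr$probe_id, reference = "sham")
  expect_equal(dd$delta5[1:2], c(1, 1), tolerance = 0.2)
  expect_equal(dd$delta12[1:2], c(0, 0), tolerance = 0.2)
  # reference flip negates both deltas
  flip <- delta_dynamics(expr, sheet, expr$probe_id, reference = "reach")
  expect_equal(flip$delta5, -dd$delta5, tolerance = 1e-12)
  expect_equal(flip$delta12, -dd$delta12, tolerance = 1e-12)
})

test_that("dynamic typing matches a brute-force truth table", {
  expect_equal(as.character(classify_dynamics(0.8, 0.1)), "up5")
  expect_equal(as.character(classify_dynamics(-0.8, 0.1)), "down5")
  expect_equal(as.character(classify_dynamics(0.1, -0.8)), "down12")
  # both zero: up5 by convention; ties go to day 5
  expect_equal(as.character(classify_dynamics(0, 0)), "up5")
  expect_equal(as.character(classify_dynamics(0.5, -0.5)), "up5")
  expect_equal(as.character(classify_dynamics(0.5, -0.5, tie = "day12")),
               "down12")
  set.seed(12)
  d5 <- rnorm(500); d12 <- rnorm(500)
  got <- as.character(classify_dynamics(d5, d12))
  want <- mapply(function(a, b) {
    if (abs(a) >= abs(b)) { if (a >= 0) "up5" else "down5" }
    else { if (b > 0) "up12" else "down12" }
  }, d5, d12)
  expect_identical(got, unname(want))
  # the partition is exhaustive
  expect_false(anyNA(got))
})

test_that("delta correlation recovers an exact linear relation", {
  d5 <- seq(-1, 1, length.out = 20)
  res <- delta_correlation(tibble::tibble(delta5 = d5, delta12 = 0.28 * d5))
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 0.28, tolerance = 1e-12)
  degen <- delta_correlation(tibble::tibble(delta5 = d5, delta12 = 0))
  expect_true(is.na(degen$r))
})

test_that("the pipeline equals the brute-force oracle on random fixtures", {
  sheet <- design_sheet()
  for (seed in 1:4) {
    set.seed(seed)
    expr <- make_expr_fixture(40, sheet,
                              effect_probes = sample(40, 6),
                              effect_group = sample(c("5-day-Reach",
                                                      "5-day-Sham"), 1),
                              effect = 1.2, noise_sd = 0.3)
    de <- run_de(expr, sheet)
    bf <- bf_de_pipeline(expr, sheet)
    expect_identical(de$lists$reach_specific, bf$reach_specific)
    expect_identical(de$lists$sham_specific, bf$sham_specific)
    expect_identical(de$lists$both, bf$both)
    res <- tidy(de)
    if (!is.null(bf$dyn_reach)) {
      sub <- res[match(bf$dyn_reach$probe_id, res$probe_id), ]
      expect_equal(sub$delta5, bf$dyn_reach$delta5, tolerance = 1e-12)
      expect_equal(sub$delta12, bf$dyn_reach$delta12, tolerance = 1e-12)
      expect_identical(as.character(sub$dyn_type), bf$dyn_reach$dyn_type)
    }
  }
})

test_that("threshold sweep counts are non-increasing and oracle-consistent", {
  sheet <- design_sheet()
  set.seed(31)
  expr <- make_expr_fixture(60, sheet, effect_probes = 1:10,
                            effect_group = "5-day-Reach",
                            effect = 1, noise_sd = 0.25)
  # plant a few stronger effects so the sweep actually thins the list
  for (s in sheet$sample_id[sheet$group == "5-day-Reach"]) {
    expr[[s]][1:3] <- expr[[s]][1:3] + 1
  }
  sens <- threshold_sensitivity(expr, sheet, thresholds = c(1.5, 1.75, 2))
  expect_true(all(diff(sens$n_genes_up5) <= 0))
  expect_true(all(diff(sens$n_probes_up5) <= 0))
  # at threshold 1 every p-passing probe passes the fold filter
  scr <- screen_modulated(expr, sheet, "Reach", fold = 1 + 1e-9)
  expect_equal(sum(scr$passes),
               sum(scr$p_value < 0.05 & scr$max_pair_fold > 1 + 1e-9))
})

test_that("top rankings are deterministic with lexicographic ties", {
  res <- tibble::tibble(
    probe_id = c("P3", "P1", "P2", "P4"),
    gene_symbol = c("c", "a", "b", "d"),
    delta5 = c(0.5, 0.9, -0.9, 0.1),
    delta12 = c(0, 0.2, 0.2, 0)
  )
  top1 <- top_differential(res, "delta5", k = 1)
  expect_equal(top1$probe_id, "P1")  # |0.9| twice, P1 < P2
  top3 <- top_differential(res, "delta5", k = 3)
  expect_equal(top3$probe_id, c("P1", "P2", "P3"))
  byd <- top_differential(res, "delta5_minus_delta12", k = 2)
  expect_equal(byd$probe_id, c("P2", "P1"))  # |-1.1| > |0.7|
  expect_warning(all4 <- top_differential(res, "delta5", k = 10), "returning all")
  expect_equal(nrow(all4), 4)
  ov <- top_differential_overlap(res, k = 2)
  expect_equal(sort(ov$overlap), c("P1", "P2"))
  # brute-force sort oracle on random fixtures
  set.seed(2)
  for (i in 1:10) {
    rr <- tibble::tibble(probe_id = sprintf("P%02d", sample(20)),
                         delta5 = rnorm(20), delta12 = rnorm(20))
    got <- top_differential(rr, "delta5", k = 5)$probe_id
    want <- rr$probe_id[order(-abs(rr$delta5), rr$probe_id)][1:5]
    expect_identical(got, want)
  }
})

test_that("printed fold-change cells reproduce from group means", {
  means <- tibble::tibble(
    gene_symbol = c("ctnnd1", "stx16", "epha4", "adcy1"),
    `0-day` = c(0.33, 0.30, -0.07, 1.54),
    `5-day-Reach` = c(1.07, 1.00, 0.55, 1.98),
    `12-day-Reach` = c(0.03, -0.01, -0.16, 0.65)
  )
  folds <- table3_folds(means)
  expect_equal(folds$`5-day-Reach vs 0-day`, c(1.67, 1.62, 1.54, 1.36))
  # adcy1's day-12 cell is only self-consistent from unrounded means,
  # so only the first three rows are asserted against that column
  expect_equal(folds$`5-day-Reach vs 12-day-Reach`[1:3], c(2.06, 2.01, 1.64))
  # equal means give unit fold
  expect_equal(table3_folds(c(`0-day` = 0.5, `5-day-Reach` = 0.5,
                              `12-day-Reach` = 0.5))[[1]], 1)
})

test_that("fold filter and pairwise folds agree on the same probe", {
  sheet <- design_sheet(2)
  set.seed(14)
  expr <- make_expr_fixture(30, sheet, noise_sd = 0.5)
  scr <- screen_modulated(expr, sheet, "Reach", alpha = 1.1, fold = 1.5)
  gm <- group_means(expr, sheet)
  pairs <- list(c("5-day-Reach", "0-day"), c("12-day-Reach", "0-day"),
                c("5-day-Reach", "12-day-Reach"))
  tf <- table3_folds(gm, pairs = pairs)
  fold_cols <- as.matrix(tf[, sapply(tf, is.numeric)])
  passes_tf <- apply(fold_cols, 1, function(f) any(f > 1.5 | f < 1 / 1.5))
  passes_scr <- scr$max_pair_fold > 1.5
  # the two routes may only disagree within rounding distance of 1.5
  boundary <- abs(scr$max_pair_fold - 1.5) < 0.01
  expect_identical(passes_tf[!boundary], passes_scr[!boundary])
})

test_that("glance and autoplot summarize a run", {
  sheet <- design_sheet()
  set.seed(77)
  expr <- make_expr_fixture(50, sheet, effect_probes = 1:8,
                            effect_group = "5-day-Reach", effect = 1.5,
                            noise_sd = 0.2)
  de <- run_de(expr, sheet)
  gl <- glance(de)
  expect_equal(gl$n_reach_specific, length(de$lists$reach_specific))
  expect_s3_class(autoplot(de), "ggplot")
  expect_output(print(de), "reach_de")
})
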