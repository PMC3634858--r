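# Two-step differential-expression procedure.
#
# Step 1: per probe, a Kruskal-Wallis test over the three Reach groups
# (0-day / 5-day-Reach / 12-day-Reach) and over the three Sham groups,
# each screen filtered by "greater than 1.5-fold in at least one of the
# three group-pairs"; the Sham list is subtracted from the Reach list
# (and vice versa) to isolate condition-specific probes.
# Step 2: per specific probe, the Reach-minus-Sham mean difference at
# day 5 and day 12 (delta5, delta12), the four-way dynamic typing, and
# the delta5/delta12 correlation contrast.

#' Kruskal-Wallis three-group test
#'
#' Rank-based H statistic with tie correction and p-value from the
#' chi-square approximation on k - 1 degrees of freedom (the behavior
#' of the commercial screening tools this pipeline emulates). A
#' Monte-Carlo permutation p-value is available for the small group
#' sizes (n = 4) where the chi-square approximation is rough.
#'
#' @param groups List of numeric vectors, one per group (each n >= 2).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Permutations for `"permutation"` (default 2000).
#' @param perm_seed Seed for the permutation draw, so results are
#'   reproducible (default 1).
#' @return Tibble `statistic` (H), `p_value`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 2000, perm_seed = 1) {
  p_method <- match.arg(p_method)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  y <- unlist(groups, use.names = FALSE)
  if (length(unique(y)) == 1) return(tibble(statistic = 0, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(y, g)
  H <- unname(kt$statistic)
  if (p_method == "chisq") {
    return(tibble(statistic = H, p_value = kt$p.value))
  }
  obs_stats <- withr::with_seed(perm_seed, {
    vapply(seq_len(n_perm), function(i) {
      unname(kruskal.test(sample(y), g)$statistic)
    }, numeric(1))
  })
  tibble(statistic = H, p_value = (1 + sum(obs_stats >= H - 1e-12)) / (n_perm + 1))
}

group_matrix <- function(expr, sheet, group) {
  ids <- sheet$sample_id[sheet$group == group]
  ids <- intersect(ids, sample_cols(expr))
  if (!length(ids)) stop_input("no samples for group %s", group)
  as.matrix(expr[, ids, drop = FALSE])
}

#' Per-group mean log2 expression
#'
#' @param expr Expression tibble.
#' @param sheet Sample sheet.
#' @param groups Groups to include (default all five).
#' @return Tibble `probe_id`, `gene_symbol`, one mean column per group.
#' @export
group_means <- function(expr, sheet, groups = unique(sheet$group)) {
  out <- expr[, c("probe_id", "gene_symbol")]
  for (g in groups) out[[g]] <- rowMeans(group_matrix(expr, sheet, g))
  out
}

triple_for <- function(condition) {
  c("0-day", paste0(c("5-day-", "12-day-"), condition))
}

#' Screen probes modulated across a three-group comparison
#'
#' A probe passes when its Kruskal-Wallis p over the three groups is
#' below `alpha` AND the largest absolute difference of group mean
#' log2 ratios over the three group-pairs exceeds log2(`fold`)
#' (strictly greater, i.e. a >1.5-fold change on the linear scale at
#' the default). Flagged probes should be removed beforehand via
#' [apply_flag_policy()].
#'
#' @param expr Expression tibble.
#' @param sheet Sample sheet.
#' @param condition `"Reach"` or `"Sham"`: selects the triple
#'   0-day / 5-day-x / 12-day-x.
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param fold Linear fold-change threshold (default 1.5).
#' @param p_method Passed to [kruskal_wallis()].
#' @return Tibble `probe_id`, `p_value`, `max_pair_fold` (linear scale,
#'   >= 1), `passes`.
#' @export
screen_modulated <- function(expr, sheet, condition = c("Reach", "Sham"),
                             alpha = 0.05, fold = 1.5,
                             p_method = "chisq") {
  condition <- match.arg(condition)
  validate_sheet(sheet)
  groups <- triple_for(condition)
  mats <- lapply(groups, function(g) group_matrix(expr, sheet, g))
  n <- nrow(expr)
  p <- numeric(n); maxdiff <- numeric(n)
  for (i in seq_len(n)) {
    vals <- lapply(mats, function(m) m[i, ][!is.na(m[i, ])])
    means <- vapply(vals, mean, numeric(1))
    maxdiff[i] <- max(abs(c(means[1] - means[2], means[1] - means[3],
                            means[2] - means[3])))
    p[i] <- if (any(lengths(vals) < 2)) NA_real_ else
      kruskal_wallis(vals, p_method = p_method)$p_value
  }
  tibble(
    probe_id = expr$probe_id,
    p_value = p,
    max_pair_fold = 2^maxdiff,
    passes = !is.na(p) & p < alpha & maxdiff > log2(fold)
  )
}

#' Subtract the Sham probe list from the Reach list (and vice versa)
#'
#' @param reach_set,sham_set Character vectors of probe ids passing the
#'   Reach-triple and Sham-triple screens.
#' @return List `reach_specific`, `sham_specific`, `both`, and a
#'   `counts` tibble.
#' @export
subtract_lists <- function(reach_set, sham_set) {
  rs <- sort(setdiff(reach_set, sham_set))
  ss <- sort(setdiff(sham_set, reach_set))
  bo <- sort(intersect(reach_set, sham_set))
  list(
    reach_specific = rs, sham_specific = ss, both = bo,
    counts = tibble(
      set = c("reach", "sham", "reach_specific", "sham_specific", "both"),
      n = c(length(reach_set), length(sham_set), length(rs), length(ss),
            length(bo))
    )
  )
}

#' Differential-expression dynamics at day 5 and day 12
#'
#' For Reach-specific probes (`reference = "sham"`): delta5 is the
#' 5-day-Reach minus 5-day-Sham difference of mean log2 ratios, and
#' delta12 the day-12 analogue, so each delta is the expression change
#' attributable to skill learning over and above the sham condition at
#' that time point. For Sham-specific probes the roles reverse.
#'
#' @param expr Expression tibble.
#' @param sheet Sample sheet.
#' @param probes Probe ids to compute deltas for.
#' @param reference `"sham"` (Reach minus Sham) or `"reach"` (Sham
#'   minus Reach).
#' @return Tibble `probe_id`, `delta5`, `delta12`.
#' @export
delta_dynamics <- function(expr, sheet, probes, reference = c("sham", "reach")) {
  reference <- match.arg(reference)
  sub <- expr[match(probes, expr$probe_id), , drop = FALSE]
  m <- function(g) rowMeans(group_matrix(sub, sheet, g), na.rm = TRUE)
  sgn <- if (reference == "sham") 1 else -1
  tibble(
    probe_id = probes,
    delta5 = sgn * (m("5-day-Reach") - m("5-day-Sham")),
    delta12 = sgn * (m("12-day-Reach") - m("12-day-Sham"))
  )
}

#' Classify the dynamic type of a modulated probe
#'
#' Four-way typing by which day carries the larger magnitude of
#' differential expression and its direction: `up5`/`down5` when
#' |delta5| dominates, `up12`/`down12` otherwise. Exact magnitude ties
#' are assigned to day 5 by default; a zero delta on the dominant day
#' can only occur when both deltas are zero, which is assigned `up5` by
#' convention.
#'
#' @param delta5,delta12 Numeric vectors (log2 units).
#' @param tie `"day5"` (default) or `"day12"`: which day wins exact
#'   magnitude ties.
#' @return Factor with levels `up5`, `down5`, `up12`, `down12`.
#' @export
classify_dynamics <- function(delta5, delta12, tie = c("day5", "day12")) {
  tie <- match.arg(tie)
  stopifnot(length(delta5) == length(delta12))
  m5 <- abs(delta5); m12 <- abs(delta12)
  dom5 <- if (tie == "day5") m5 >= m12 else m5 > m12
  out <- ifelse(dom5,
                ifelse(delta5 >= 0, "up5", "down5"),
                ifelse(delta12 > 0, "up12", "down12"))
  factor(out, levels = c("up5", "down5", "up12", "down12"))
}

#' Correlation between day-5 and day-12 differential expression
#'
#' Pearson r (two-sided p) plus the OLS slope of delta12 on delta5.
#' The contrast between an uncorrelated Reach-specific cloud and a
#' positively correlated Sham-specific cloud is the signature of
#' distinct temporal processes in the two conditions.
#'
#' @param deltas Tibble with `delta5`, `delta12` (>= 3 rows).
#' @return Tibble `r`, `p_value`, `slope`, `n`.
#' @export
delta_correlation <- function(deltas) {
  ok <- complete.cases(deltas[, c("delta5", "delta12")])
  d <- deltas[ok, ]
  if (nrow(d) < 3) stop_input("need at least 3 delta pairs")
  if (sd(d$delta5) == 0 || sd(d$delta12) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, slope = NA_real_,
                  n = nrow(d)))
  }
  ct <- cor.test(d$delta5, d$delta12)
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(coef(lm(delta12 ~ delta5, data = d))[2]),
         n = nrow(d))
}

#' Run the full two-step differential-expression pipeline
#'
#' Screens the Reach and Sham triples, subtracts the lists, computes
#' delta dynamics and dynamic types for the condition-specific probes,
#' and assembles the per-probe result table. A Benjamini-Hochberg
#' adjusted p-value column is emitted for reference but plays no part
#' in selection (the screening procedure is raw p < alpha plus the
#' fold filter).
#'
#' @inheritParams screen_modulated
#' @param flag_policy Probe-flag policy, see [apply_flag_policy()].
#' @return An object of class `reach_de`: list with `results` (one row
#'   per analyzed probe), `lists` (from [subtract_lists()]), and
#'   `params`.
#' @export
run_de <- function(expr, sheet, alpha = 0.05, fold = 1.5,
                   p_method = "chisq", flag_policy = "any") {
  expr <- apply_flag_policy(expr, flag_policy)
  scr_r <- screen_modulated(expr, sheet, "Reach", alpha, fold, p_method)
  scr_s <- screen_modulated(expr, sheet, "Sham", alpha, fold, p_method)
  lists <- subtract_lists(scr_r$probe_id[scr_r$passes],
                          scr_s$probe_id[scr_s$passes])
  res <- tibble(
    probe_id = expr$probe_id,
    gene_symbol = expr$gene_symbol,
    p_reach = scr_r$p_value,
    p_sham = scr_s$p_value,
    p_reach_bh = stats::p.adjust(scr_r$p_value, "BH"),
    max_fold_reach = scr_r$max_pair_fold,
    max_fold_sham = scr_s$max_pair_fold,
    membership = dplyr::case_when(
      probe_id %in% lists$reach_specific ~ "reach_specific",
      probe_id %in% lists$sham_specific ~ "sham_specific",
      probe_id %in% lists$both ~ "both",
      TRUE ~ "neither"
    ),
    delta5 = NA_real_, delta12 = NA_real_
  )
  for (side in c("reach", "sham")) {
    probes <- lists[[paste0(side, "_specific")]]
    if (!length(probes)) next
    dd <- delta_dynamics(expr, sheet, probes,
                         reference = if (side == "reach") "sham" else "reach")
    idx <- match(dd$probe_id, res$probe_id)
    res$delta5[idx] <- dd$delta5
    res$delta12[idx] <- dd$delta12
  }
  res$dyn_type <- factor(NA, levels = levels(classify_dynamics(0, 0)))
  spec <- res$membership %in% c("reach_specific", "sham_specific")
  res$dyn_type[spec] <- classify_dynamics(res$delta5[spec], res$delta12[spec])
  structure(
    list(results = res, lists = lists,
         params = list(alpha = alpha, fold = fold, p_method = p_method,
                       flag_policy = flag_policy)),
    class = "reach_de"
  )
}

#' @export
print.reach_de <- function(x, ...) {
  cat("<reach_de>\n")
  print(x$lists$counts)
  invisible(x)
}

#' Per-probe results of the differential-expression pipeline
#'
#' @param x A `reach_de` object.
#' @param ... Unused.
#' @return The per-probe result tibble.
#' @export
tidy.reach_de <- function(x, ...) x$results

#' Dataset-level summary of the differential-expression pipeline
#'
#' Reports list sizes and, for the Reach-specific probes, the fractions
#' dominated by day-5 regulation and their up/down split.
#'
#' @param x A `reach_de` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.reach_de <- function(x, ...) {
  rs <- x$results[x$results$membership == "reach_specific", ]
  n <- nrow(rs)
  tibble(
    n_reach = length(x$lists$reach_specific) + length(x$lists$both),
    n_sham = length(x$lists$sham_specific) + length(x$lists$both),
    n_reach_specific = length(x$lists$reach_specific),
    n_sham_specific = length(x$lists$sham_specific),
    n_both = length(x$lists$both),
    frac_day5_dominant = if (n) mean(rs$dyn_type %in% c("up5", "down5")) else NA_real_,
    frac_up5 = if (n) mean(rs$dyn_type == "up5") else NA_real_,
    frac_down5 = if (n) mean(rs$dyn_type == "down5") else NA_real_
  )
}

#' Scatter plot of day-12 versus day-5 differential expression
#'
#' @param object A `reach_de` object.
#' @param membership Which specific list to plot (default
#'   `"reach_specific"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reach_de <- function(object, membership = "reach_specific", ...) {
  d <- object$results[object$results$membership == membership, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta5, y = .data$delta12,
                                  colour = .data$dyn_type)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = expression(Delta * "5day (log2)"),
                  y = expression(Delta * "12day (log2)"),
                  colour = "dynamic type", title = membership)
}

#' Sensitivity of the gene counts to the fold-change threshold
#'
#' Re-runs the full screen / subtract / dynamics pipeline at each
#' fold-change threshold and reports the number of unique annotated
#' genes up-regulated at day 5 among the Reach-specific probes (probes
#' sharing a gene symbol collapse to one gene; unannotated probes are
#' counted separately). Counts are non-increasing in the threshold by
#' construction.
#'
#' @inheritParams run_de
#' @param thresholds Increasing linear fold-change thresholds
#'   (default 1.5, 1.75, 2.0).
#' @return Tibble `threshold`, `n_probes_up5`, `n_genes_up5`,
#'   `n_unannotated_up5`.
#' @export
threshold_sensitivity <- function(expr, sheet, thresholds = c(1.5, 1.75, 2),
                                  alpha = 0.05, p_method = "chisq",
                                  flag_policy = "any") {
  stopifnot(all(diff(thresholds) > 0))
  purrr::map_dfr(thresholds, function(th) {
    de <- run_de(expr, sheet, alpha = alpha, fold = th, p_method = p_method,
                 flag_policy = flag_policy)
    up5 <- de$results[de$results$membership == "reach_specific" &
                        !is.na(de$results$dyn_type) &
                        de$results$dyn_type == "up5", ]
    ann <- up5$gene_symbol[!is.na(up5$gene_symbol) & up5$gene_symbol != ""]
    tibble(threshold = th, n_probes_up5 = nrow(up5),
           n_genes_up5 = length(unique(ann)),
           n_unannotated_up5 = nrow(up5) - length(ann))
  })
}

#' Top differentially expressed genes
#'
#' Ranks probes by the absolute value of the chosen criterion:
#' `"delta5"` (differential expression at day 5 versus day 0, whose own
#' differential is zero by definition) or `"delta5_minus_delta12"`.
#' Ties break lexicographically by probe id so the ranking is
#' deterministic.
#'
#' @param results Per-probe tibble with `probe_id`, `delta5`,
#'   `delta12` (e.g. `tidy(run_de(...))` filtered to a membership).
#' @param criterion Ranking criterion.
#' @param k List length (default 30); if `k` exceeds the number of
#'   probes, all are returned with a warning.
#' @return The top-k rows with a `rank` and `score` column.
#' @export
top_differential <- function(results, criterion = c("delta5", "delta5_minus_delta12"),
                             k = 30) {
  criterion <- match.arg(criterion)
  d <- results[!is.na(results$delta5), , drop = FALSE]
  score <- if (criterion == "delta5") abs(d$delta5) else abs(d$delta5 - d$delta12)
  if (k > nrow(d)) {
    warn(sprintf("k = %d exceeds %d probes: returning all", k, nrow(d)))
    k <- nrow(d)
  }
  ord <- order(-score, d$probe_id)
  out <- d[ord[seq_len(k)], , drop = FALSE]
  out$score <- score[ord[seq_len(k)]]
  out$rank <- seq_len(k)
  out
}

#' Overlap between the two top-gene rankings
#'
#' @inheritParams top_differential
#' @return List `by_delta5`, `by_delta5_minus_delta12`, `overlap`
#'   (shared probe ids).
#' @export
top_differential_overlap <- function(results, k = 30) {
  a <- top_differential(results, "delta5", k)
  b <- top_differential(results, "delta5_minus_delta12", k)
  list(by_delta5 = a, by_delta5_minus_delta12 = b,
       overlap = intersect(a$probe_id, b$probe_id))
}

#' Pairwise linear fold changes from group mean log2 ratios
#'
#' Converts differences of group mean log2 ratios into linear fold
#' changes, `fold(g1 vs g2) = 2^(mean_g1 - mean_g2)`, reported to two
#' decimals — the reconstruction that reproduces published per-gene
#' fold-change tables from their printed group means.
#'
#' @param means Tibble of group mean log2 ratios (e.g. from
#'   [group_means()]), or a named numeric vector for a single probe.
#' @param pairs List of 2-element character vectors `c(g1, g2)`;
#'   default compares 5-day-Reach against 0-day and 12-day-Reach.
#' @return Tibble with one fold column per pair (named `g1_vs_g2`).
#' @export
table3_folds <- function(means,
                         pairs = list(c("5-day-Reach", "0-day"),
                                      c("5-day-Reach", "12-day-Reach"))) {
  if (is.numeric(means)) means <- as_tibble(as.list(means))
  out <- means[, intersect(c("probe_id", "gene_symbol"), names(means)), drop = FALSE]
  for (pr in pairs) {
    if (!all(pr %in% names(means))) stop_input("missing group(s): %s",
                                               paste(pr, collapse = ", "))
    out[[paste(pr[1], "vs", pr[2])]] <- round(2^(means[[pr[1]]] - means[[pr[2]]]), 2)
  }
  as_tibble(out)
}
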