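# Independent brute-force oracles, coded directly from the defining
# formulas with no shared code paths with the package implementation.

# Kruskal-Wallis H with tie correction, straight from the rank formula.
bf_kruskal_H <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  r <- rank(y)
  N <- length(y)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(y)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

bf_kruskal_p <- function(groups) {
  stats::pchisq(bf_kruskal_H(groups), df = length(groups) - 1,
                lower.tail = FALSE)
}

# Full DE pipeline oracle: loops and base R only.
bf_de_pipeline <- function(expr, sheet, alpha = 0.05, fold = 1.5) {
  samples_of <- function(g) sheet$sample_id[sheet$group == g]
  passes <- function(triple) {
    out <- logical(nrow(expr))
    for (i in seq_len(nrow(expr))) {
      vals <- lapply(triple, function(g)
        as.numeric(expr[i, samples_of(g), drop = TRUE]))
      means <- sapply(vals, mean)
      md <- max(abs(outer(means, means, "-")))
      out[i] <- bf_kruskal_p(vals) < alpha && md > log2(fold)
    }
    out
  }
  reach <- expr$probe_id[passes(c("0-day", "5-day-Reach", "12-day-Reach"))]
  sham <- expr$probe_id[passes(c("0-day", "5-day-Sham", "12-day-Sham"))]
  rs <- setdiff(reach, sham)
  ss <- setdiff(sham, reach)
  gmean <- function(p, g) mean(as.numeric(expr[expr$probe_id == p,
                                               samples_of(g), drop = TRUE]))
  ddyn <- function(p, sgn) {
    d5 <- sgn * (gmean(p, "5-day-Reach") - gmean(p, "5-day-Sham"))
    d12 <- sgn * (gmean(p, "12-day-Reach") - gmean(p, "12-day-Sham"))
    ty <- if (abs(d5) >= abs(d12)) {
      if (d5 >= 0) "up5" else "down5"
    } else {
      if (d12 > 0) "up12" else "down12"
    }
    data.frame(probe_id = p, delta5 = d5, delta12 = d12, dyn_type = ty)
  }
  list(
    reach = reach, sham = sham,
    reach_specific = sort(rs), sham_specific = sort(ss),
    both = sort(intersect(reach, sham)),
    dyn_reach = if (length(rs)) do.call(rbind, lapply(sort(rs), ddyn, sgn = 1)) else NULL,
    dyn_sham = if (length(ss)) do.call(rbind, lapply(sort(ss), ddyn, sgn = -1)) else NULL
  )
}

# Slot classification oracle: per-slot curves, truncated moving average,
# Pearson r and its t-transform p, all by hand.
bf_classify_slots <- function(trials, alpha = 0.05, window = 3) {
  half <- (window - 1) / 2
  out <- list()
  for (rat in sort(unique(trials$rat_id))) {
    for (sl in sort(unique(paste(trials$slot_row, trials$slot_side, sep = "_")))) {
      keep <- trials$rat_id == rat &
        paste(trials$slot_row, trials$slot_side, sep = "_") == sl
      tr <- trials[keep, ]
      days <- sort(unique(tr$day))
      v <- sapply(days, function(d) {
        td <- tr[tr$day == d, ]
        if (sum(td$n_reaches) == 0) NA_real_ else
          sum(td$success) / sum(td$n_reaches)
      })
      sm <- sapply(seq_along(v), function(i) {
        w <- v[max(1, i - half):min(length(v), i + half)]
        if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
      })
      ok <- !is.na(sm)
      x <- days[ok]; y <- sm[ok]
      if (length(y) < 3 || stats::sd(y) == 0) {
        r <- NA_real_; p <- 1
      } else {
        r <- sum((x - mean(x)) * (y - mean(y))) /
          sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
        tt <- r * sqrt((length(y) - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tt), length(y) - 2)
      }
      out[[length(out) + 1]] <- data.frame(
        rat_id = rat, slot = sl, r = r, p_value = p,
        learned = !is.na(r) && r > 0 && p < alpha
      )
    }
  }
  do.call(rbind, out)
}

# Small random expression fixture with optional planted group effects.
make_expr_fixture <- function(n_probes, sheet, effect_probes = integer(),
                              effect_group = "5-day-Reach", effect = 1,
                              noise_sd = 0.3) {
  expr <- tibble::tibble(
    probe_id = sprintf("P%03d", seq_len(n_probes)),
    gene_symbol = sprintf("g%03d", seq_len(n_probes))
  )
  for (i in seq_len(nrow(sheet))) {
    v <- rnorm(n_probes, 0, noise_sd)
    if (sheet$group[i] == effect_group && length(effect_probes)) {
      v[effect_probes] <- v[effect_probes] + effect
    }
    expr[[sheet$sample_id[i]]] <- v
  }
  expr
}
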