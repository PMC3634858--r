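# Synthetic behavioral data.
#
# Emulates the training design: 120 trials per day (20 per slot, six
# slots in a seeded uniform randomized order), 12 days. Each rat has a
# per-slot Learned status; Learned slots follow a sigmoid success-per-
# reach curve, Not-Learned slots a flat baseline. Within a trial the
# number of reach attempts is 1 + a truncated geometric draw, each
# attempt succeeding with the slot's current per-reach probability; a
# retrieved pellet is dropped with a probability that decays over days.

#' Behavioral simulation configuration
#'
#' Defaults reproduce the study design: 4 rats, 12 days, 20 trials per
#' slot per day over 6 slots. Per-rat, per-slot sigmoid parameters are
#' drawn uniformly from the given ranges; the defaults put the onset of
#' improvement (t10%-max) in the day 3-6 range.
#'
#' @param n_rats Number of rats.
#' @param n_days Training days.
#' @param trials_per_slot Daily trials per slot (6 slots).
#' @param learned_slot_fraction Probability each slot is a Learned slot.
#' @param sigmoid_a,sigmoid_b,sigmoid_c,sigmoid_d Ranges `c(lo, hi)` for
#'   the per-slot sigmoid parameters (amplitude, center day, rate,
#'   baseline).
#' @param drop_init,drop_asym,drop_decay_days Initial and asymptotic
#'   drop probability for successful trials and the decay constant in
#'   days.
#' @param p_contact Geometric parameter for extra reach attempts; the
#'   attempt count is `1 + Geom(p_contact)` truncated at `max_reaches`.
#' @param max_reaches Cap on reach attempts per trial.
#' @param digit_ipsi,digit_contra Named categorical distributions over
#'   hand positions for successful ipsi-/contralateral trials.
#' @param strategy_rate Probability a trial employs both hand-placement
#'   strategies (otherwise neither).
#' @param strategy_multiplier Per-reach success multipliers
#'   `c(with, without)` for strategy/no-strategy trials.
#' @param duration_mean,duration_sd Trial duration (s).
#' @return Config list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_rats = 4, n_days = 12, trials_per_slot = 20,
                                learned_slot_fraction = 0.4,
                                sigmoid_a = c(0.2, 0.35),
                                sigmoid_b = c(5, 7),
                                sigmoid_c = c(0.7, 1),
                                sigmoid_d = c(0.01, 0.04),
                                drop_init = 0.5, drop_asym = 0.05,
                                drop_decay_days = 2,
                                p_contact = 0.5, max_reaches = 6,
                                digit_ipsi = c(d1 = 0.05, d2 = 0.2, d3 = 0.4,
                                               d4 = 0.15, d5 = 0.05,
                                               between = 0.1, palm = 0.05),
                                digit_contra = c(d1 = 0.15, d2 = 0.4, d3 = 0.2,
                                                 d4 = 0.1, d5 = 0.05,
                                                 between = 0.05, palm = 0.05),
                                strategy_rate = 0.5,
                                strategy_multiplier = c(with = 1.4, without = 0.6),
                                duration_mean = 20, duration_sd = 4) {
  cfg <- as.list(environment())
  stopifnot(trials_per_slot >= 1, n_days >= 1,
            learned_slot_fraction >= 0, learned_slot_fraction <= 1,
            drop_init >= 0, drop_init <= 1, drop_asym >= 0, drop_asym <= 1,
            p_contact > 0, p_contact <= 1,
            abs(sum(digit_ipsi) - 1) < 1e-8, abs(sum(digit_contra) - 1) < 1e-8)
  structure(cfg, class = "behavior_sim_config")
}

runif_range <- function(n, range) runif(n, range[1], range[2])

#' Simulate behavioral trial records with planted ground truth
#'
#' @param cfg A [behavior_sim_config()].
#' @param seed Master seed; the behavioral child seed is derived from it.
#' @return List with `trials` (tibble, one row per trial) and `truth`
#'   (tibble `rat_id`, `slot`, `learned_true`, `a`, `b`, `c`, `d`).
#' @export
simulate_behavior <- function(cfg = behavior_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  if (cfg$trials_per_slot < 1) stop_input("need at least one trial per slot per day")
  set.seed(child_seed(seed, "behavior"))
  slots <- slot_ids()
  truth <- purrr::map_dfr(seq_len(cfg$n_rats), function(ri) {
    tibble(
      rat_id = sprintf("rat%02d", ri),
      slot = slots,
      learned_true = runif(length(slots)) < cfg$learned_slot_fraction,
      a = runif_range(length(slots), cfg$sigmoid_a),
      b = runif_range(length(slots), cfg$sigmoid_b),
      c = runif_range(length(slots), cfg$sigmoid_c),
      d = runif_range(length(slots), cfg$sigmoid_d)
    )
  })
  trials <- purrr::map_dfr(seq_len(nrow(truth) / length(slots)), function(ri) {
    rat <- sprintf("rat%02d", ri)
    tr_rat <- truth[truth$rat_id == rat, ]
    purrr::map_dfr(seq_len(cfg$n_days), function(day) {
      # uniform randomized slot sequence for the day's 6 x trials_per_slot trials
      seq_slots <- sample(rep(slots, cfg$trials_per_slot))
      p_drop <- cfg$drop_asym + (cfg$drop_init - cfg$drop_asym) *
        exp(-(day - 1) / cfg$drop_decay_days)
      n <- length(seq_slots)
      idx <- match(seq_slots, tr_rat$slot)
      p_reach <- ifelse(tr_rat$learned_true[idx],
                        sigmoid_fn(day, tr_rat$a[idx], tr_rat$b[idx],
                                   tr_rat$c[idx], tr_rat$d[idx]),
                        tr_rat$d[idx])
      strat <- runif(n) < cfg$strategy_rate
      mult <- ifelse(strat, cfg$strategy_multiplier[["with"]],
                     cfg$strategy_multiplier[["without"]])
      p_eff <- pmin(1, pmax(0, p_reach * mult))
      attempts <- pmin(1 + rgeom(n, cfg$p_contact), cfg$max_reaches)
      cap <- cfg$max_reaches
      hits <- (matrix(runif(n * cap), n, cap) < p_eff) &
        (col(matrix(0, n, cap)) <= attempts)
      success <- rowSums(hits) > 0
      first_hit <- max.col(hits, ties.method = "first")
      n_reaches <- ifelse(success, first_hit, attempts)
      side <- sub(".*_", "", seq_slots)
      digit <- rep(NA_character_, n)
      for (s in c("ipsi", "contra")) {
        pick <- success & side == s
        dist <- if (s == "ipsi") cfg$digit_ipsi else cfg$digit_contra
        digit[pick] <- sample(names(dist), sum(pick), replace = TRUE, prob = dist)
      }
      tibble(
        rat_id = rat, day = day,
        slot_row = sub("_.*", "", seq_slots), slot_side = side,
        n_reaches = n_reaches, success = success,
        dropped = success & runif(n) < p_drop,
        digit_position = digit,
        strategy_under_finger = strat, strategy_proximal_pip = strat,
        trial_duration_s = pmax(1, rnorm(n, cfg$duration_mean, cfg$duration_sd))
      )
    })
  })
  list(trials = trials, truth = truth)
}
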