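# Synthetic two-color array data.
#
# Each sample's clean log2(cy5/cy3) ratio is a per-probe baseline plus
# Normal noise plus any planted group effect. Raw channel intensities
# wrap that ratio in the technical structure the preprocessing has to
# handle: a shared green (reference) intensity profile with small
# cross-array jitter, a per-array red gain (the dominant, biological
# source of cross-array variability), and an intensity-dependent dye
# bias for the lowess normalization to remove.

#' Array simulation configuration
#'
#' Defaults emulate the study structure at desk scale: 4,000 probes
#' (scaled down from the 41,012-probe whole-genome design), five groups
#' of four samples, planted Reach-specific regulation at day 5 split
#' 69% up / 24% down / 7% day-12-dominant, and Sham-specific regulation
#' whose day-12 effect follows its day-5 effect with slope 0.28.
#'
#' @param n_probes Number of probes.
#' @param n_reach_specific,n_sham_specific Planted probes per class.
#' @param reach_split Fractions `c(up5, down5, day12)` of the planted
#'   Reach-specific set.
#' @param sham_up_frac Fraction of Sham-specific probes up-regulated.
#' @param delta5_effect Planted day-5 effect magnitude (log2 units).
#' @param sham_delta_slope Day-12 over day-5 effect slope for the
#'   Sham-specific probes.
#' @param sham_delta_noise SD of the day-12 effect residual (log2).
#' @param noise_sd Within-group sample noise SD (log2); a free
#'   parameter of the design, set so planted 1.5-2-fold effects are
#'   detectable at n = 4.
#' @param probe_baseline_sd SD of per-probe baseline log2 ratios
#'   (default 0: the baseline ratio model is pure Normal(0, noise_sd)
#'   noise around a common-reference null; raise for per-probe mean
#'   offsets, at the cost of a genuine expression-intensity trend that
#'   within-array normalization then removes).
#' @param dye_bias Amplitude of the sinusoidal intensity-dependent dye
#'   bias on M (log2); 0 disables it.
#' @param green_meanlog,green_sdlog Log-normal reference-channel
#'   intensity profile across probes.
#' @param green_jitter_sd Cross-array jitter of the reference channel
#'   (log2; small, the reference is the same RNA on every array).
#' @param red_gain_sd Per-array red-channel gain SD (log2; the sample
#'   channel varies across animals).
#' @param flag_rate Probability a (probe, sample) cell is flagged
#'   `marginal` or `absent`.
#' @return Config list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_probes = 4000,
                             n_reach_specific = 120, n_sham_specific = 120,
                             reach_split = c(up5 = 0.69, down5 = 0.24, day12 = 0.07),
                             sham_up_frac = 0.7,
                             delta5_effect = 1.0,
                             sham_delta_slope = 0.28, sham_delta_noise = 0.08,
                             noise_sd = 0.15, probe_baseline_sd = 0,
                             dye_bias = 0.3,
                             green_meanlog = log(1000), green_sdlog = 1,
                             green_jitter_sd = 0.03, red_gain_sd = 0.25,
                             flag_rate = 0.002) {
  cfg <- as.list(environment())
  stopifnot(n_probes >= n_reach_specific + n_sham_specific,
            delta5_effect > 0, abs(sum(reach_split) - 1) < 1e-8,
            noise_sd > 0)
  structure(cfg, class = "array_sim_config")
}

#' Simulate the 20-sample two-color array dataset
#'
#' @param cfg An [array_sim_config()].
#' @param sheet Sample sheet with all five groups (default the 4-per-
#'   group design).
#' @param seed Master seed; the array child seed is derived from it.
#' @return List with `expr` (clean wide log2-ratio tibble, the planted
#'   ground truth the raw data are built around, with quality flags
#'   attached as the `"flags"` attribute), `raw` (long tibble
#'   `sample_id`, `probe_id`, `red`, `green`), `flags` (wide flag
#'   tibble), and `truth` (tibble `probe_id`, `planted_class`,
#'   `delta5_true`, `delta12_true`).
#' @export
simulate_arrays <- function(cfg = array_sim_config(), sheet = design_sheet(),
                            seed = 1) {
  stopifnot(inherits(cfg, "array_sim_config"))
  validate_sheet(sheet)
  if (!all(GROUPS %in% sheet$group)) stop_input("sheet must contain all five groups")
  set.seed(child_seed(seed, "arrays"))
  np <- cfg$n_probes
  probe_ids <- sprintf("P%05d", seq_len(np))

  # planted classes (disjoint by construction)
  n_r <- cfg$n_reach_specific; n_s <- cfg$n_sham_specific
  n_up5 <- round(n_r * cfg$reach_split[["up5"]])
  n_dn5 <- round(n_r * cfg$reach_split[["down5"]])
  n_d12 <- n_r - n_up5 - n_dn5
  planted_class <- rep("null", np)
  planted_class[seq_len(n_up5)] <- "reach_up5"
  planted_class[n_up5 + seq_len(n_dn5)] <- "reach_down5"
  if (n_d12 > 0) planted_class[n_up5 + n_dn5 + seq_len(n_d12)] <- "reach_day12"
  planted_class[n_r + seq_len(n_s)] <- "sham"

  eff <- cfg$delta5_effect
  d5_true <- d12_true <- numeric(np)
  d5_true[planted_class == "reach_up5"] <- eff
  d5_true[planted_class == "reach_down5"] <- -eff
  d12_true[planted_class == "reach_day12"] <-
    eff * sign(runif(sum(planted_class == "reach_day12")) - 0.3)
  is_sham <- planted_class == "sham"
  d5_true[is_sham] <- eff * ifelse(runif(sum(is_sham)) < cfg$sham_up_frac, 1, -1)
  d12_true[is_sham] <- cfg$sham_delta_slope * d5_true[is_sham] +
    rnorm(sum(is_sham), 0, cfg$sham_delta_noise)

  # per-group effect on the log2 ratio
  effect_for <- function(group) {
    e <- numeric(np)
    reach <- startsWith(planted_class, "reach")
    if (group == "5-day-Reach") e[reach] <- d5_true[reach]
    if (group == "12-day-Reach") e[reach] <- d12_true[reach]
    if (group == "5-day-Sham") e[is_sham] <- d5_true[is_sham]
    if (group == "12-day-Sham") e[is_sham] <- d12_true[is_sham]
    e
  }

  baseline <- rnorm(np, 0, cfg$probe_baseline_sd)
  green_profile <- rlnorm(np, cfg$green_meanlog, cfg$green_sdlog)
  # Planted group effects are made orthogonal to the (centered) log
  # intensity profile, so group structure cannot leak into the per-array
  # red~green regression slope: the hybridization-consistency QC is null
  # by construction, as in a well-behaved common-reference experiment.
  l2g <- log2(green_profile); l2g <- l2g - mean(l2g)
  orthogonalize <- function(e) e - l2g * sum(e * l2g) / sum(l2g^2)

  expr <- tibble(probe_id = probe_ids,
                 gene_symbol = sprintf("gene%04d", rep(seq_len(ceiling(np / 1.05)),
                                                       length.out = np)))
  raw <- vector("list", nrow(sheet))
  flags <- tibble(probe_id = probe_ids)
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$sample_id[i]
    value <- baseline + orthogonalize(effect_for(sheet$group[i])) +
      rnorm(np, 0, cfg$noise_sd)
    expr[[s]] <- value
    gain <- rnorm(1, 0, cfg$red_gain_sd)
    green <- green_profile * 2^rnorm(np, 0, cfg$green_jitter_sd)
    m_tech <- value + gain
    # intensity-dependent dye bias: a smooth single-arch function of spot
    # intensity (via the reference channel), identical in form across arrays
    a0 <- log2(green)
    bias <- if (cfg$dye_bias == 0) 0 else
      cfg$dye_bias * sin(pi * (a0 - min(a0)) / diff(range(a0)))
    raw[[i]] <- tibble(sample_id = s, probe_id = probe_ids,
                       red = green * 2^(m_tech + bias), green = green)
    fl <- sample(c("present", "marginal", "absent"), np, replace = TRUE,
                 prob = c(1 - cfg$flag_rate, cfg$flag_rate / 2, cfg$flag_rate / 2))
    flags[[s]] <- fl
  }
  attr(expr, "flags") <- flags
  list(
    expr = expr,
    raw = dplyr::bind_rows(raw),
    flags = flags,
    truth = tibble(probe_id = probe_ids, planted_class = planted_class,
                   delta5_true = d5_true, delta12_true = d12_true)
  )
}
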