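# Synthetic qPCR data.
#
# The threshold cycle is linear in the log of the input quantity:
#   C_T = intercept - log(conc * 2^expr) / log(1 + E/100) / log(10)...
# operationally, C_T = c0 - log10(input) / log10(f) with f = 1 + E/100
# the per-cycle amplification factor, input = rna_conc * 2^expr.
# Reference genes have zero condition effect and track input tightly;
# target genes add their group's true log2 expression. A dilution
# series per gene encodes the configured efficiency for the standard
# curve to recover.

#' qPCR simulation configuration
#'
#' @param gene_effects Tibble `gene`, `group`, `log2_expr`: the true
#'   per-condition mean log2 expression of each target gene (relative
#'   units; `0-day` is the natural baseline). Groups default to the
#'   four assayed conditions.
#' @param reference_genes Ids of the two stable reference genes
#'   (planted with zero condition effect; a nonzero configured fold for
#'   a reference is rejected).
#' @param noisy_candidates Extra unstable reference candidates.
#' @param reference_true_fold Must be 0: planted condition effect of
#'   the reference genes, exposed only so misconfiguration fails loudly.
#' @param efficiency Named per-gene percent efficiencies; unnamed
#'   single value recycles to all genes (default 100).
#' @param ct_noise_sd Replicate C_T noise SD (cycles).
#' @param bio_sd Per-sample biological SD around the group mean (log2).
#' @param candidate_instability_sd Extra per-sample SD for the noisy
#'   reference candidates (log2).
#' @param n_replicates Wells per (gene, sample) (default 3).
#' @param dilution_factor,n_dilution_points Standard-curve series.
#' @param conc_meanlog,conc_sdlog Log-normal RNA concentration across
#'   samples (ng/uL scale).
#' @param ct_intercept Baseline C_T at unit input.
#' @return Config list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(gene_effects = default_gene_effects(),
                            reference_genes = c("ref1", "ref2"),
                            noisy_candidates = c("cand1", "cand2", "cand3", "cand4"),
                            reference_true_fold = 0,
                            efficiency = 100,
                            ct_noise_sd = 0.15,
                            bio_sd = 0.1,
                            candidate_instability_sd = 0.5,
                            n_replicates = 3,
                            dilution_factor = 5, n_dilution_points = 5,
                            conc_meanlog = log(500), conc_sdlog = 0.3,
                            ct_intercept = 28) {
  cfg <- as.list(environment())
  if (reference_true_fold != 0) {
    stop_input("reference genes must have zero true fold change")
  }
  stopifnot(all(c("gene", "group", "log2_expr") %in% names(gene_effects)),
            n_replicates >= 1, n_dilution_points >= 3,
            all(efficiency > 50), all(efficiency < 150))
  structure(cfg, class = "qpcr_sim_config")
}

#' Default planted qPCR gene effects
#'
#' Twelve target genes up-regulated in the 5-day-Reach condition
#' (log2 effects 0.4-1.2) against the 0-day, 5-day-Sham, and
#' 12-day-Reach conditions, mirroring the validated array pattern of
#' day-5 specific up-regulation.
#'
#' @param n_genes Number of target genes.
#' @param effects Log2 up-regulation in 5-day-Reach per gene (recycled).
#' @return Tibble `gene`, `group`, `log2_expr`.
#' @export
default_gene_effects <- function(n_genes = 12,
                                 effects = seq(0.4, 1.2, length.out = n_genes)) {
  groups <- c("0-day", "5-day-Reach", "5-day-Sham", "12-day-Reach")
  purrr::map_dfr(seq_len(n_genes), function(i) {
    tibble(gene = sprintf("tgt%02d", i), group = groups,
           log2_expr = c(0, rep_len(effects, n_genes)[i], 0, 0))
  })
}

#' Simulate a qPCR dataset with dilution series and reference genes
#'
#' @param cfg A [qpcr_sim_config()].
#' @param sheet Sample sheet; only the groups present in
#'   `cfg$gene_effects` are assayed.
#' @param seed Master seed; the qPCR child seed is derived from it.
#' @return List with `ct` (long tibble `gene`, `sample_id`,
#'   `replicate`, `ct`), `conc` (tibble `sample_id`, `rna_conc`),
#'   `dilution` (tibble `gene`, `dilution_step`, `replicate`, `ct`),
#'   `genes` (metadata: `gene`, `role`, `efficiency`), and `sheet`
#'   (the assayed subset).
#' @export
simulate_qpcr <- function(cfg = qpcr_sim_config(), sheet = design_sheet(),
                          seed = 1) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  set.seed(child_seed(seed, "qpcr"))
  groups <- unique(cfg$gene_effects$group)
  sheet <- sheet[sheet$group %in% groups, , drop = FALSE]
  targets <- unique(cfg$gene_effects$gene)
  genes <- tibble(
    gene = c(targets, cfg$reference_genes, cfg$noisy_candidates),
    role = c(rep("target", length(targets)),
             rep("reference", length(cfg$reference_genes)),
             rep("candidate", length(cfg$noisy_candidates)))
  )
  eff <- cfg$efficiency
  genes$efficiency <- if (is.null(names(eff))) rep_len(eff, nrow(genes)) else
    unname(eff[genes$gene])
  cycles_per_log10 <- function(e) 1 / log10(1 + e / 100)

  conc <- tibble(sample_id = sheet$sample_id,
                 rna_conc = rlnorm(nrow(sheet), cfg$conc_meanlog, cfg$conc_sdlog))

  ct <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    g <- genes$gene[gi]
    cl10 <- cycles_per_log10(genes$efficiency[gi])
    expr <- numeric(nrow(sheet))
    if (genes$role[gi] == "target") {
      ge <- cfg$gene_effects[cfg$gene_effects$gene == g, ]
      expr <- ge$log2_expr[match(sheet$group, ge$group)] +
        rnorm(nrow(sheet), 0, cfg$bio_sd)
    } else if (genes$role[gi] == "candidate") {
      expr <- rnorm(nrow(sheet), 0, cfg$candidate_instability_sd)
    }
    input_log10 <- log10(conc$rna_conc) + expr * log10(2)
    base_ct <- cfg$ct_intercept - cl10 * input_log10
    purrr::map_dfr(seq_len(cfg$n_replicates), function(rep_i) {
      tibble(gene = g, sample_id = sheet$sample_id, replicate = rep_i,
             ct = base_ct + rnorm(nrow(sheet), 0, cfg$ct_noise_sd))
    })
  })

  dilution <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    cl10 <- cycles_per_log10(genes$efficiency[gi])
    steps <- seq_len(cfg$n_dilution_points) - 1
    base_ct <- cfg$ct_intercept + cl10 * steps * log10(cfg$dilution_factor)
    purrr::map_dfr(seq_len(cfg$n_replicates), function(rep_i) {
      tibble(gene = genes$gene[gi], dilution_step = steps, replicate = rep_i,
             ct = base_ct + rnorm(length(steps), 0, cfg$ct_noise_sd))
    })
  })

  list(ct = ct, conc = conc, dilution = dilution, genes = genes, sheet = sheet)
}
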