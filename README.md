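# skilledreach

Analysis pipeline linking rodent reach-and-grasp skill acquisition to
motor-cortex transcriptome dynamics.

## The problem

When an animal learns a fine motor skill, performance on a
reach-and-grasp task follows a sigmoid time course: days of little
improvement, then a sharp rise, then a plateau. The scientific question
is what happens in the forelimb motor cortex transcriptome *before* the
rise — the hypothesis being that circuit remodeling accumulates until
performance can improve. Answering it requires stitching together three
very different analyses, which this package provides as composable,
tibble-first functions:

1. **Behavior** — per-day learning measures (successes per reach, drop
   percentage), classification of pellet positions into Learned /
   Not-Learned slots by the Pearson trend of the smoothed per-slot
   curve, and bounded nonlinear least-squares fits of sigmoid vs
   stretched-exponential learning models, compared by R². The sigmoid
   fit P(t) = d + a/(1 + e^(−c(t−b))) yields the onset day
   **t10%-max = b − ln(9)/c**, the day the curve reaches 10% of its
   asymptotic amplitude.
2. **Two-color arrays** — channel-level QC (cross-array SD of red vs
   green signal at percentiles, per-array log-log regression slopes),
   lowess MA normalization, and a two-step differential-expression
   procedure: per-probe Kruskal-Wallis screening over
   {0-day, day-5, day-12} triples with a >1.5-fold filter, **Reach
   minus Sham gene-list subtraction**, then per-probe
   Δ5day/Δ12day = Reach−Sham mean differences with four-way dynamic
   typing (up5 / down5 / up12 / down12).
3. **qPCR validation** — amplification efficiency from dilution-series
   slopes (E% = (10^(−1/slope) − 1)·100), reference-gene selection by
   C_T-vs-concentration correlation, 2^−ΔΔCt fold changes, and
   sign-agreement with the array folds.

A synthetic-data generator (`simulate_behavior()`, `simulate_arrays()`,
`simulate_qpcr()`) emulates the full five-group study design (Reach and
Sham at days 5 and 12, plus naive baseline, n = 4 each; 120 trials/day
over 6 slots; planted expression effects with the Reach/Sham dynamics
contrast) so that every stage can be exercised against known ground
truth.

## Worked example

```r
library(skilledreach)
library(dplyr)

# -- arrays: simulate raw two-color data, normalize, run the DE pipeline
sheet <- design_sheet()                       # 5 groups x 4 samples
arr   <- simulate_arrays(array_sim_config(), sheet, seed = 42)
expr  <- normalize_arrays(arr$raw,
                          annotation = arr$expr[, c("probe_id", "gene_symbol")])
attr(expr, "flags") <- arr$flags
de <- run_de(expr, sheet, alpha = 0.05, fold = 1.5)
glance(de)
#>   n_reach n_sham n_reach_specific n_sham_specific n_both frac_day5_dominant
#> 1     118    115              118             115      0              0.932
#>   frac_up5 frac_down5
#> 1    0.686      0.246

delta_correlation(filter(tidy(de), membership == "sham_specific"))
#>       r  p_value slope     n
#> 1 0.907 2.53e-44 0.290   115
```

Of the probes the pipeline isolates as Reach-specific, 93% are
modulated predominantly at day 5 (69% up-, 25% down-regulated) — the
day-5 concentration of expression change that precedes the performance
rise — while the Sham-specific probes show the correlated Δ12 ≈ 0.29·Δ5
dynamics planted by the generator (`autoplot(de)` draws the Δ scatter).

```r
# -- behavior: classify slots, fit the pooled Learned curve
beh <- simulate_behavior(seed = 42)
cls <- classify_slots(beh$trials, alpha = 0.05, window = 3)
head(cls$classification, 3)
#>   rat_id slot           r     p_value learned
#> 1 rat01  far_contra 0.966 0.000000329 TRUE
#> 2 rat01  far_ipsi   0.750 0.00494     TRUE
#> 3 rat01  mid_contra 0.303 0.338       FALSE

fit <- fit_sigmoid(filter(cls$pooled, rat_id == "rat01", slot_set == "Learned"))
fit
#> <learning_fit: sigmoid>
#>   params: a=0.1705, b=6.334, c=0.9845, d=0.03361
#>   R^2 = 0.9425, converged = TRUE
#>   t10%-max = 4.10 days
```

The fitted onset (day ~4) reproduces the qualitative finding that
performance starts to rise around day 4–5; `autoplot(fit)` overlays the
fit and onset line on the daily data.

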