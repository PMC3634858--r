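Package: skilledreach
Title: Skilled-Reach Learning Curves and Motor-Cortex Transcriptome Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking rodent reach-and-grasp skill
    acquisition to motor-cortex gene-expression dynamics. Provides
    sigmoid and stretched-exponential learning-curve fits with the
    t10%-max onset statistic, per-slot Learned/Not-Learned
    classification by smoothed Pearson trend, two-color microarray
    quality control and lowess MA normalization, a two-step
    differential-expression procedure (Kruskal-Wallis screening with a
    fold-change filter, Reach-versus-Sham gene-list subtraction, and
    day-5/day-12 dynamics typing), delta-delta-Ct qPCR validation with
    reference-gene selection and amplification-efficiency estimation,
    and a synthetic-data generator that emulates the full study design
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
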