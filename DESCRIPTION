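Package: bfrenergetics
Title: Energy System Partitioning for Low-Intensity Cycling with Blood-Flow Restriction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the aerobic, anaerobic alactic, and anaerobic
    lactic energy system contributions to low-intensity cycling exercise, with
    or without limb blood-flow restriction. Reads breath-by-breath gas-exchange
    and blood-lactate tables, fits mono-exponential oxygen-uptake off-kinetics
    to recovery data, converts net lactate accumulation to an oxygen
    equivalent, and assembles per-session energy partitions. Includes
    incremental-test utilities (ramp protocol construction, maximality
    criteria, segmented-regression ventilatory threshold detection,
    cuff-pressure prescription), crossover-trial statistics (paired t,
    two-way repeated-measures ANOVA with Bonferroni post hoc, typical error),
    and a seeded synthetic crossover-trial generator that provides ground
    truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
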