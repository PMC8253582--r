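Package: qorscore
Title: Composite Quality-of-Recovery Scoring for Rodent Abdominal Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute a composite quality-of-recovery (QoR) score for
    preclinical abdominal-surgery studies. Six behavioral domains (food intake,
    intestinal transit, sucrose preference, mechanical allodynia, locomotion,
    juvenile social exploration) are rescaled to percent maximum possible
    effect (%MPE) against fixed maximum-deficit anchors, binned into 0-3 domain
    scores, and summed into a 0-18 daily composite. Includes an up-down
    (Dixon) staircase estimator for the 50% von Frey withdrawal threshold,
    trajectory area-under-the-curve summaries, tie-corrected Kruskal-Wallis
    and Dunn post-hoc comparisons with exact small-sample permutation
    p-values, a calibrated synthetic-cohort generator for power and type-I
    studies, and a validated long-format CSV interchange with a reproducible
    pipeline runner.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
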