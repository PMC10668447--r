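Package: neglectvr
Title: Normative Modelling of Immersive Virtual-Reality Visual-Search Gameplay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes visuospatial attention metrics from immersive
    virtual-reality visual-search telemetry (trial records and 90 Hz
    headset/controller raycast orientation traces) and flags "visuospatial
    atypicality" with a double-reference Tukey-fence rule: a player's metric
    is atypical when it lies beyond 1.5 x IQR fences of both the control and
    the patient reference distributions. Includes per-level accuracy,
    outlier-trimmed reaction time and raycast orientation means, pooled
    spatial-preference difference scores across quadrants and eccentricities,
    player-by-metric summary matrices, group-level nonparametric statistics
    (chi-square on typicality counts, Wilcoxon and Levene comparisons),
    feasibility questionnaire scoring (SSQ, GEQ-R, SUS, FIM), a generative
    gameplay simulator for end-to-end testing without clinical data, and
    case-report and raycast-histogram exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
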