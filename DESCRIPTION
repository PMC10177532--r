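Package: aemark
Title: Adverse-Event-Derived Biomarkers for Clinical Outcome Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw longitudinal adverse-event (AE) records graded under
    CTCAE into a panel of 24 patient-level biomarkers that combine grade
    class (any, low, high), treatment relatedness, and four measurements
    (occurrence, unique-term count, event count, total duration), at the
    overall, toxicity-category, and individual-AE levels. Supports landmark
    ("early AE") windows to avoid guarantee-time bias, and runs a global
    discovery battery of each biomarker against progression-free survival,
    overall survival, disease control, and duration of treatment via
    univariate Cox models, Welch t-tests, and Pearson correlation, with
    effect-size summary plots, Kaplan-Meier displays, and significant-AE
    reports. Includes a synthetic AE cohort simulator with configurable
    hazard links for calibration and power studies.
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
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
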