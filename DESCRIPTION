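Package: ThermoFly
Title: Locomotor Activity, Sleep and Temperature Preference Analysis for
    Drosophila Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparative behavioral chronobiology and thermal
    physiology of Drosophila. Reads Drosophila Activity Monitor (DAM)
    beam-break recordings into a SummarizedExperiment-derived container,
    scores sleep by the five-minute immobility rule, computes daily
    activity and sleep summaries, profiles and day/night splits, fits
    thermal performance curves with AIC model selection, quantifies
    temperature-gradient preference assays (nine-range distributions and
    per-assay median preferred temperatures), and provides first-principles
    nonparametric statistics (Kruskal-Wallis with tie correction, Dunn's
    post hoc with Bonferroni adjustment, Mann-Whitney U, Spearman rank
    correlation). A synthetic-data generator produces activity tables and
    gradient assays with the statistical structure the analyses assume, so
    the full pipeline is testable without instrument recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
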