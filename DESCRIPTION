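Package: npscout
Title: Prioritization of Natural-Extract Libraries by Structural-Novelty Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks crude natural-product extracts profiled by untargeted
    LC-MS/MS according to their potential to contain structurally novel
    compounds. Four per-extract component scores are computed from an aligned
    feature table, spectral-library and in-silico annotations, predicted
    chemical classes, and offline literature occurrence counts: a Feature
    Component (fraction of detected features that are extract-specific and
    unannotated), a Literature Component (penalising well-studied taxa), a
    Class Component (predicted chemical classes unreported for the taxon) and
    a Similarity Component (spectral outlier status from an MS2 fingerprint
    built of binned fragment peaks and neutral losses, mined by an ensemble of
    local outlier factor, one-class SVM and isolation-forest detectors).
    Their weighted sum, the Priority Score, ranks the library. Includes a
    deterministic synthetic-data generator with planted ground truth for
    validation at desk scale.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
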