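Package: microresist
Title: Gut Microbiome Stability and Responsiveness to Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the temporal stability of longitudinal gut-microbiome
    profiles with intraclass correlation coefficients (two-way random-effects,
    absolute-agreement, mean-rating form with subject-level bootstrap
    confidence intervals), derives responder / partial-responder /
    non-responder calls for intervention subjects from the day-to-day
    Bray-Curtis fluctuation of no-intervention cohorts, identifies taxonomic
    and functional biomarkers of responsiveness (PERMANOVA, proportional-odds
    ordinal regression, Wilcoxon tests, chi-square enrichment, Spearman
    species-pathway association, stratified contribution linking, SparCC
    co-abundance networks), and trains a baseline-microbiome response
    classifier (recursive feature elimination plus grid-tuned gradient
    boosting over repeated train/test splits). Ships a synthetic longitudinal
    study generator with known ground truth so the whole pipeline is testable
    without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    phangorn,
    igraph,
    xgboost,
    caret,
    pROC,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
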