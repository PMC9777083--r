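Package: reosurv
Title: Rank-Based Gene-Pair Prognostic Signatures for Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds qualitative prognostic biomarkers from within-sample
    relative expression orderings (REOs) of gene pairs, in the style of
    top-scoring-pairs classifiers adapted to right-censored survival data.
    Provides cohort preprocessing for multi-platform expression studies,
    univariate Cox screening of genes and gene pairs with Benjamini-Hochberg
    control, a greedy concordance-maximizing combination search with test-set
    selection, a majority-vote risk classifier that works one sample at a
    time, cohort-level evaluation (Kaplan-Meier, hazard ratios, IPCW
    time-dependent AUC, drug-response contingency analysis), and a synthetic
    multi-cohort generator with planted prognostic structure for end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
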