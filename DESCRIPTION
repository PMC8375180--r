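Package: xcnv
Title: Copy-Number Variant Unification and Pathogenicity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-wide assessment of copy-number variant (CNV)
    pathogenicity. Unifies redundant CNV calls with discordant breakpoints by
    iterative maximal-clique extraction on a breakpoint-distance graph, computes
    per-ethnic-group population allele frequencies via reciprocal-overlap
    matching against a reference CNV database, assembles a 30-column annotation
    feature matrix (universal, coding, noncoding and genome-wide features),
    trains a gradient-boosted classifier whose probabilistic output is the
    meta-voting prediction (MVP) score, derives five-tier pathogenicity
    cutoffs by sensitivity-specificity balancing, and evaluates predictions
    with MCC, accuracy, F1, Fowlkes-Mallows, sensitivity, specificity and
    rank-based AUC. A synthetic-data module generates CNV populations and
    annotation bundles with controllable signal so the whole pipeline is
    exercisable end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
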