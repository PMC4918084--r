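Package: adegea
Title: Adverse Drug Event Signal Detection by Generalized Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects associations between drugs (or ATC drug classes) and
    adverse events from article-term annotation corpora such as MEDLINE MeSH
    indexing. Builds reference statistics (ancestor-propagated term
    frequencies, information content, pairwise co-frequencies) over a
    MeSH-like terminology, aggregates adverse event terms onto abstraction
    levels of uniform information content, and scores drug-event enrichment
    with a conditional hypergeometric test that corrects for known term
    dependencies. A proportional reporting ratio (PRR) baseline with
    zero-cell correction, evaluation against drug-outcome gold standards
    (confusion matrices, precision/recall/F1, ROC AUC), and a synthetic
    corpus generator with planted associations are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
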