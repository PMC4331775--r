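Package: sensigo
Title: Dual-Contrast Hormone-Sensitivity Classification and GO Enrichment
    for Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline that separates androgen-sensitive from
    follistatin-sensitive transcripts in a two-tissue, four-condition
    (sham / castrated / castrated+testosterone / castrated+follistatin)
    mouse design. Provides RMA-style probe-level preprocessing (convolution
    background correction, quantile normalization, median-polish
    summarization), per-gene linear models with empirical-Bayes moderated
    t-statistics and Benjamini-Hochberg adjustment, the dual-contrast
    q-value classification rule, and a self-contained Gene Ontology
    enrichment engine (OBO/GAF parsing, annotation propagation to
    ancestors, term-frequency filtering, upper-tail hypergeometric
    scoring). A synthetic-data module generates probe-level expression
    data with planted condition effects and a synthetic ontology so that
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
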