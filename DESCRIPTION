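Package: bmetlung
Title: Classification and Exact Contingency Inference for Lung Cancer Brain
    Metastasis Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the neuroanatomical distribution of lung cancer
    brain metastases from surgical-neuropathology free-text reports. Provides
    a synthetic report-corpus generator with ground-truth labels, a
    hierarchical free-text string-matching classifier for diagnostic category,
    primary site, lung-cancer subtype and neuroanatomical location codes,
    immunostain-based subtype refinement (TTF-1/p63) and lung biomarker
    extraction with PD-L1 tumour proportion score binning, cohort tabulation
    (site-overlap matrices, subtype-by-site lesion tables, biomarker tables),
    and an exact inference engine: two-sided Fisher tests for 2x2 tables,
    the Freeman-Halton exact r x c test by full enumeration with a
    fixed-margin Monte-Carlo fallback, all-pairs 2x2 decompositions and
    p-value binning for clustered heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
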