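Package: stromaMedOr
Title: Median-Ordering Confidence Statements and Marker-Pair Classification
    of Chemotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonparametric classification of tumor samples by response to
    neoadjuvant chemotherapy from stromal-cell expression profiles. Implements
    an exact order-statistic confidence statement for the ordering of two
    population medians (MedOr), per-marker two-group screening of expression
    matrices, greedy sequential selection of over/under-expressed marker pairs
    into a composite ratio-of-products index with a stopping rule, and
    threshold-based classification. Includes parsing of clinical cohort tables
    with derivation of downstaging and pathological-complete-response labels
    from ypTN staging, and a synthetic microarray cohort generator with
    planted differential markers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, S4Vectors, SummarizedExperiment
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
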