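Package: cnvreporter
Title: Clinical Copy Number Variant Interpretation and Automated Diagnostic Reporting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An automated postdetection pipeline for clinical copy number
    variant (CNV) reporting in prenatal and products-of-conception diagnosis.
    Mines historical clinical reports into a labeled corpus (sentence
    segmentation, CNV-paragraph relation scoring and matching, six-category
    sentence classification with active-learning candidate selection), builds
    six clinical evidence knowledge bases (Polymorphism, Aneuploid, Syndrome,
    Gene, Paper, Patient), scores CNVs against them and classifies variants
    into the ACMG five-tier scheme via configurable evidence rules, and
    composes reviewable diagnostic reports. Ships seeded synthetic-corpus and
    interpretation-benchmark generators so every stage is testable without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
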