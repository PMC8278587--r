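Package: bbdburden
Title: Gene-Level Somatic Mutation Burden Analysis for FFPE Benign Breast
    Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted-panel somatic variant calls from
    formalin-fixed paraffin-embedded (FFPE) benign breast disease tissue and
    their association with future breast cancer. Provides FFPE-aware variant
    quality control (technical-flag removal, liberal/classical/strict
    alternate-allele-fraction filters, per-category false-discovery-rate
    estimation from paired FFPE/frozen tissue, replicate-identity and
    population-allele-frequency concordance checks), variant prioritization,
    gene-level burden association by logistic regression and SKAT-O under
    twelve filter-by-method combinations, consensus counting with
    label-permutation empirical significance, de-novo mutational signature
    extraction by non-negative matrix factorization with consensus
    clustering, cohort descriptive statistics, and immunohistochemistry
    associations. A synthetic cohort generator with ground-truth labels
    (germline, true somatic, FFPE artifact) supports end-to-end validation
    without access to protected sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
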