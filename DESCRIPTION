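Package: alcodoc
Title: Rule-Based Phenotyping and Clustered Models of Alcohol Documentation in Primary-Care EMRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how alcohol use is documented in primary-care
    electronic medical records. Provides a deterministic rule-based classifier
    that maps free-text risk-factor entries to guideline-anchored consumption
    categories (non-drinker, light, moderate, heavy, past, unknown), a cohort
    builder that applies eligibility rules and derives analysis covariates, and
    provider-clustered marginal logistic models (generalized estimating
    equations with robust standard errors) of documentation and of heightened
    alcohol-related risk. A multi-table synthetic EMR generator with known
    ground truth makes every stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
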