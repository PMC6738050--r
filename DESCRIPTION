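Package: kinmr
Title: Mendelian Randomisation for Time-to-Event Outcomes in Ascertained
    Mutation-Carrier Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Mendelian-randomisation analysis of quantitative
    traits against time-to-event cancer outcomes in clinic-ascertained
    BRCA1/2 mutation-carrier cohorts. Builds weighted polygenic scores from
    genotype dosages and rescales them to trait units among unaffected
    carriers; constructs kin-cohort ascertainment weights from external
    age-specific incidence; expands carriers into counting-process episodes
    with time-varying menopausal status and fits weighted Cox models with
    family-clustered robust variance; combines per-variant associations by
    the inverse-variance-weighted estimator with MR-Egger and Cochran Q /
    I-squared diagnostics; and performs two-stage residual-inclusion
    instrumental-variable estimation with family-level bootstrap confidence
    intervals. A seeded synthetic-cohort generator with family-structured
    genotypes, case oversampling, and configurable confounding supports
    testing of every stage without access to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
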