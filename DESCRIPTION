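Package: lfspectrum
Title: Li-Fraumeni Spectrum Classification of Pedigree-Structured Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("LFS", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule engine that assigns individuals and families in a
    germline TP53 cohort to the categories of the Li-Fraumeni spectrum
    (phenotypic LFS, LFS, attenuated LFS, incidental LFS, and cancer-free
    carrier states), built on clinical genetic-testing criteria (classic
    Li-Fraumeni criteria and Chompret categories A and B), pedigree
    kinship-degree computation, and TP53 protein-variant annotation
    (hotspot codons, protein domains, the Brazilian p.R337H founder
    variant). Includes two-group tumor-pattern contingency analysis
    (Pearson chi-square and two-sided Fisher exact tests), a synthetic
    family-history generator with age-phase-dependent tumor spectra, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
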