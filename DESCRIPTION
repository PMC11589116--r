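Package: tripcheck
Title: Ploidy Verification and Chromosomal Aberration Analysis for
    Pressure-Induced Triploid Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for verifying ploidy and detecting chromosomal
    aberrations in Atlantic salmon produced with hydrostatic-pressure
    triploidization treatments. Implements microsatellite allele-dosage
    genotyping from electropherogram peak-height ratios (MAC-PR),
    individual-level ploidy and aneuploidy classification, exclusion-based
    family assignment for half-sibling diploid and triploid cohorts,
    typing of inheritance aberrations (missing parental alleles,
    uniparental disomy, double-paternal trisomies, repeat-slippage
    shifts), binomial regression of triploidy and aneuploidy incidence
    with a random-intercept logistic model fitted by adaptive
    Gauss-Hermite quadrature, and a forward simulator of half-sib,
    pressure-gradient breeding designs with full latent truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
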