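Package: pgxlifetime
Title: Lifetime Clinical Utility of Preemptive Pharmacogenomic Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the lifetime clinical utility of preemptive
    pharmacogenomic testing in a patient cohort. Annotates variant calls
    against a panel of clinically actionable pharmacogene variants, applies
    quality and read-depth exclusion rules, links carrier status to
    longitudinal prescription records to produce actionable drug-gene
    incidences, and computes age-indexed benefit-of-testing curves under
    fixed-cohort, living-population, and transient-population models. A
    seeded synthetic-cohort generator (genotypes under configurable linkage
    structure, lifespans, age-stamped prescriptions) exercises the full
    pipeline without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
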