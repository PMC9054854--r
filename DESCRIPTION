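Package: admixmeth
Title: Local-Ancestry-Aware EWAS and meQTL Mapping in Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing DNA methylation in two-way admixed cohorts
    (African/European). Computes distance-weighted local ancestry at CpG
    sites from per-haplotype ancestry calls, runs two-stage epigenome-wide
    association scans on self-reported race, global ancestry and local
    ancestry with control-probe and residual principal components, fits
    ancestry-decomposed cis-meQTL models with nested F tests for
    ancestry-specific allelic effects, clumps correlated meQTLs into loci,
    and performs positional and trait enrichment of significant CpG sets.
    Includes a simulator of admixed cohorts (ancestry tracts, phased
    genotypes, covariates, control probes, methylation) so every stage can
    be exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
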