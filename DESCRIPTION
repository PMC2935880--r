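Package: driftpower
Title: Power of Two-Phase Multiethnic Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic power calculations for two-phase case-control
    genome-wide association studies in which evidence is combined across
    population panels. Computes the non-centrality parameter of the 1-df
    allelic chi-square test under a multiplicative (log-additive) risk
    model, sums it over phases and panels, and converts it to asymptotic
    power at genome-wide significance. Includes genome-wide aggregation
    stratified by minor allele frequency, power-gain decompositions by
    cross-population allele-frequency difference, replication sample-size
    calculations for reported associations, a seeded Monte-Carlo oracle
    for validating the analytic formulas, and a Balding-Nichols simulator
    of multi-population allele-frequency tables with SNP-array
    ascertainment and finite-founder frequency estimation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
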