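Package: mitodrift
Title: Germline Transmission Genetics of mtDNA Heteroplasmy
Version: 0.1.0
Authors@R:
    person("Mitodrift", "Developers", email = "mitodrift@example.org",
           role = c("aut", "cre"))
Description: Analysis of mitochondrial DNA heteroplasmy transmission through
    the maternal germline. Provides logit-scale heteroplasmy shift statistics
    for mother-offspring and mother-oocyte comparisons, the Kimura pure-drift
    distribution of heteroplasmy (boundary masses, continuous density,
    sampling, drift-parameter estimation) and a simulation-based neutral-drift
    null test for purifying selection, mother-offspring transmission
    regression with a normality-gated testing policy, follicle-stage shift
    summaries, tissue-stability coefficients of variation, droplet digital PCR
    Poisson copy quantification, a conversion-rate off-target caller for
    base-editing pileups, and seeded synthetic-data generators (bottleneck
    pedigrees, follicle copy-number time courses, ddPCR partitioning,
    per-site base counts) that emulate the corresponding experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
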