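Package: chipdyn
Title: Longitudinal Clonal Hematopoiesis Dynamics from Targeted Panel Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying clonal hematopoiesis of indeterminate potential
    (CHIP) from serial targeted-panel sequencing. Reads Mutect2-style somatic
    variant calls against a 22-gene CHIP panel, applies depth/alt-read/VAF
    filters with cross-timepoint rescue of sub-threshold calls, estimates
    per-clone annual exponential growth rates from two-timepoint variant
    allele fractions, classifies clonal trajectories (stagnant, expansion,
    reduction) and two-clone architectures (sub-clone versus distinct clones),
    and computes cohort-level summaries: per-gene growth rates, driver-gene
    co-occurrence tests against a prevalence-controlled null, and covariate
    association regressions. Includes a ground-truthed synthetic cohort
    generator with binomial sequencing noise and limiting-dilution simulation
    so the full pipeline is testable without access-restricted biobank data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    vcfR,
    IRanges,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
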