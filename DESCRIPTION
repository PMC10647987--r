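Package: icebergExposome
Title: Iceberg Mixture Modeling of Chemometer-Based Exposome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for passive equilibrium sampling
    ("chemometer") studies of the internal chemical exposome of biota.
    Takes silicone (PDMS)-based concentrations of hydrophobic organic
    contaminants measured across animals and organs, applies EPA-style
    method detection limits, procedural-blank subtraction and
    lipid-uptake correction, converts between silicone, lipid and
    wet-weight concentration bases via equilibrium partition
    coefficients, computes organ-distribution statistics (detection
    frequencies, geometric summaries, ratio paired t-tests, effect
    threshold exceedance) and performs concentration-addition iceberg
    mixture modeling: bioanalytical equivalent concentrations (BEQ) and
    toxic units (TU) predicted from quantified chemicals are compared
    with bioassay-measured effects to obtain the fraction of observed
    mixture effect explained by the targeted analytes. Includes a
    seeded synthetic-study generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
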