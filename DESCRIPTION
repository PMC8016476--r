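Package: steadyomics
Title: Absolute-Quantitative Multi-Omics Analysis of Steady-State Yeast Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spike-in calibration of transcriptomic (FPKM) and
    proteomic (iBAQ) measurements to absolute units (mmol per gram dry
    weight), estimation of per-gene protein translation rates from paired
    mRNA and protein abundances, growth-rate and nitrogen-source scaling
    transforms, cluster-number voting across internal validity indices,
    GO-slim Fisher enrichment (set, sliding-window and top-abundance),
    amino-acid and codon-usage profiling along the protein-mRNA
    correlation ranking, and a growth-plus-nitrogen null model that
    separates perturbation-specific gene regulation from physiological
    confounding. Includes a chemostat-style synthetic multi-omics data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
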