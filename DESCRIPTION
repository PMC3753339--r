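Package: karyosim
Title: Agent-Based Simulation of Chromosome Mis-Segregation in Tumour Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based model of tissue homeostasis and cancer
    development driven by whole-chromosome mis-segregation. Cells carry copy
    numbers of three abstract gene classes (cell-division, apoptosis and
    chromosome-segregation regulators) arranged on chromosomes in configurable
    linkage patterns; per-cell death, division and mis-segregation
    probabilities are gene-dose dependent. Includes simulated interventions
    (surgery, chemotherapy and their combination), relapse bookkeeping,
    replicate cohorts with summary statistics and two-sample comparisons, and
    exporters and plots for trajectory, genotype-composition and gene-ratio
    series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
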