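Package: axotrace
Title: Phenotypic Profiling of Axonal Organelle Trafficking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for high-content phenotypic
    profiling of axonal organelle trafficking in compartmentalized neuron
    cultures. Provides a calibrated two-state (mobile/immobile) run-and-pause
    simulator of mitochondrial and lysosomal trajectories with genotype- and
    compartment-specific decline schedules, a spot detector and
    nearest-neighbour track linker for rendered time-lapse movies, per-track
    motility descriptors (the master parameters), 44-component Z-score
    phenotypic signatures with significance flagging, phenotypic-strength
    time courses and hierarchical clustering of signatures, plus fixed-cell
    quantification utilities: triangle-threshold foci segmentation,
    per-nucleus counting, co-occurrence classification, Pearson pixel
    colocalization, and one-way ANOVA with Bonferroni post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ape,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
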