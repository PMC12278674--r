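Package: redoxomics
Title: Multiplexed TMT Proteomics, Redox PTM Occupancy and Lipidomics
    Integration for Oleaginous Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multi-omics analysis of nitrogen-limited
    Rhodotorula toruloides cultures: rollup and normalization of multiplexed
    TMT reporter-ion data (global protein abundance, cysteine thiol-oxidation
    and phosphorylation site abundances), bridge-channel batch correction,
    channel-loading scaling of PTM sites against global peptide data,
    protein-level adjustment of site abundances, percent thiol-oxidation
    occupancy, probabilistic quotient normalization of lipidomics peak
    heights with subclass rollups, empirical-Bayes moderated differential
    statistics with a factorial nitrogen-by-time model, hypergeometric and
    rank-based set enrichment, and Pearson-correlation integration of
    oxidized cysteine sites with lipid class trajectories. A synthetic-data
    generator with known ground truth emulates the experimental design
    (two TMT-18 plexes with bridge, pooled total-thiol and empty channels)
    so the whole pipeline is testable without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
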