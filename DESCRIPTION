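Package: synflux
Title: Constraint-Based Flux Analysis and Omics Integration for
    Photoautotroph Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    models of photosynthetic microbes such as the cyanobacterium
    Synechocystis sp. PCC6803. Reads and writes models in the OptGene/BioOpt
    flat-text dialect, assembles stoichiometric matrices, and performs flux
    balance analysis (FBA), two-phase photon-uptake minimization, flux
    variability analysis (FVA) with blocked-reaction detection, and
    minimization-of-metabolic-adjustment (MOMA) mutant predictions.
    Includes genome-wide single-gene deletion screens with three-class
    essentiality calls, exhaustive and evolutionary knockout strain design
    for value-added compounds (succinate, hydrogen), Reporter-Metabolite
    integration of transcriptome p-values over the metabolic network, and a
    seeded synthetic phototroph generator for end-to-end testing of every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    quadprog,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
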