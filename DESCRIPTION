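Package: clonomod
Title: Gene-Module and Clonotype Analysis of Antigen-Reactive CD4+ T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for paired single-cell RNA-seq and
    TCR-alpha/beta repertoire analysis of antigen-reactive CD4+ T cells
    sampled longitudinally during oral immunotherapy. Discovers coexpressed
    gene modules by L1-penalized sparse PCA, calls module-expressing cells
    against a negative-control sorted population at a fixed false-positive
    rate, classifies T helper subtypes by module z-scores with within-class
    graph clustering and marker annotation, builds patient-scoped TCR-beta
    clonotypes with diversity, overlap and CDR3 distance statistics
    (BLOSUM62-derived mismatch penalties with gapped alignment), quantifies
    TCR convergence by likelihood ratios, tracks per-clonotype module
    suppression across treatment phases, and fits a baseline principal
    component signature of clinical outcome. Ships a synthetic cohort
    generator with planted ground truth so every stage is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
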