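Package: vspocket
Title: Binding-Pocket Comparison and Early-Recovery Metrics for
    Retrospective Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating and comparing protein binding pockets in
    retrospective structure-based virtual screens. Implements the normalized
    square-root area under the ROC curve (NSQ_AUC), an early-recovery
    statistic scaled between random (0) and perfect (100) retrieval;
    chemotype-stratified enrichment factors; best-of-repeats score handling
    with repeat-aware comparison statistics (ANOVA with Tukey HSD, Welch t);
    racemic ligand-library preparation from SDF with stereocenter
    bookkeeping, enantiomer deduplication and hierarchical chemotype
    clustering; and structural comparison of ligand/receptor co-complexes:
    group superposition, symmetry-aware ligand and pocket heavy-atom RMSD,
    distance-based pocket definition, seven-class interaction fingerprints
    and crystallographic model-quality flagging. A synthetic-data module
    generates docking-score tables, SDF libraries and miniature PDB
    complexes with known ground truth so the full pipeline can be exercised
    and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
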