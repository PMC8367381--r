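Package: wormlight
Title: Photoreceptor Cell-Type Transcriptomics, Opsin Spectral
    Sensitivity and Undulation Behavior Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-stage analysis toolkit for characterizing
    rhabdomeric-opsin-expressing sensory cell types in marine annelids.
    Provides cluster-based transcript quantification with
    length-normalized expression values, enrichment-signature set logic
    on differential-expression results, best-BLAST-hit homology mapping
    with permutation tests for cross-species gene-set overlap,
    action-spectrum estimation and Govardovskii visual-pigment template
    fitting of opsin spectral sensitivity from dose-response
    luminescence assays, and periodogram-based classification of
    undulation behavior from keypoint trajectories. Includes
    seed-deterministic synthetic-data generators with ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    IRanges,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
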