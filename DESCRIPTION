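Package: comparanet
Title: Comparative Analysis of Labeled Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Comparanet", "Developers", email = "maintainer@comparanet.dev",
           role = c("aut", "cre"))
Description: Tools for comparing two whole-brain structural connectomes that
    share a common parcellation ("assumed homologue" regions), as in
    macaque-human comparative connectomics. Provides labeled-connectome
    containers and file I/O, connectome construction transforms (symmetrize,
    binarize, subject averaging, density-matched thresholding, hemisphere
    splitting), cross-species similarity statistics (edge intersection ratio,
    homologue connectivity similarity, matching index, homologue matching
    index similarity and weighted variants), centrality and clustering
    metrics, binary and weighted rich-club analysis, degree-preserving and
    link-and-weight-reshuffle null ensembles with empirical z-scores and
    p-values, perturbation and edge-insertion robustness controls, and an
    end-to-end comparative pipeline with TSV reports. A synthetic-data module
    generates paired connectomes with planted edge overlap, preserved and
    rewired regions, and multi-subject weighted matrices so the whole
    pipeline can be exercised without any external data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    withr,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
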