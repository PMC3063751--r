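Package: fluctuogram
Title: Time-Resolved Elastic Network Models by Fluctuation Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms windowed segments of a coarse-grained protein
    trajectory into per-window elastic network models by iterative
    fluctuation matching, and follows the temporal variation of the
    resulting mechanical coupling network (the "fluctuogram").  Provides
    the two-site-per-residue Calpha-sidechain coarse graining, normal-mode
    prediction of bond-length variances, residue-level coupling metrics
    for two-state comparisons and window-to-window variation, selection of
    putative communication residues with hit-rate and coverage statistics
    against reference residue sets, a statistical coupling analysis arm
    for detecting co-evolving sequence sectors in multiple sequence
    alignments, and generators for Gaussian-sampled synthetic trajectories
    and planted-sector alignments used to validate every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
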