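Package: replicaseq
Title: Two-Experiment Microarray Replication Analysis of Alcohol-Exposed
    Mouse Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a two-experiment microarray
    replication pipeline for whole-embryo alcohol-exposure studies:
    MAS5-style detection-call ("present") filtering, per-probe Welch
    differential expression on log2 signals, directional cross-experiment
    intersection with an analytic null and overlap false discovery rate,
    on/off presence calling, an unweighted running-sum gene set enrichment
    engine with permutation p-values, leading-edge extraction and
    cross-experiment set-level replication FDR, average-linkage array
    clustering, and delta-delta-Ct qRT-PCR relative quantification. A
    synthetic-data generator emulates the study's paired-platform design
    (nested probe universes, small group sizes, planted effects) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
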