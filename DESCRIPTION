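Package: caploop
Title: Differential Enhancer-Promoter Interaction Analysis for Capture-C
Version: 0.1.0
Authors@R:
    person("SEM", "Genomics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies viewpoint-anchored chromosome-conformation (Capture-C)
    interaction profiles at restriction-fragment resolution and tests for
    differential enhancer-promoter contact between treatment conditions.
    Provides in-silico restriction digestion, per-viewpoint count
    normalization, windowed paired Wilcoxon signed-rank testing at binding
    peaks with Holm-Bonferroni correction, spike-in (ChIP-Rx) reference
    normalization of ChIP-seq signal, super-enhancer stitching and
    rank-cutoff calling with eRNA response windows, and a truth-tagged
    negative-binomial simulator so that every stage of the analysis can be
    validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
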