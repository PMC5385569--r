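Package: dihmm
Title: Hierarchical Hidden Markov Models for Chromatin State and Domain
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous annotation of chromatin states at nucleosome scale
    (200 bp bins) and domain scale (blocks of consecutive bins) from
    binarized multi-mark ChIP-seq tracks, using a two-level hierarchical
    hidden Markov model in which nucleosome-level transitions depend on the
    domain-level state and domain-level transitions are restricted to block
    boundaries. Provides Poisson-background binarization of read counts,
    k-centre initialization, scaled forward-backward inference, hierarchical
    Baum-Welch training over multiple cell types and chromosomes, Viterbi and
    posterior decoding, BED export of stitched state segments, a generative
    simulator, and downstream evaluation statistics (fold enrichment,
    TSS-centred profiles, expression by state, and a segmentation similarity
    score combining Pearson correlation with a conditional Gini index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
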