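Package: tillcall
Title: Bayesian Mutation Discovery for TILLING-by-Sequencing Pooled Amplicon Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse-genetic screens that detect EMS-induced point
    mutations by deep sequencing of multidimensionally pooled amplicons
    (TILLING by sequencing). Provides tridimensional pool design and
    deconvolution, a Bayesian rare-variant caller with a binomial
    sequencing-error model and a log10 posterior-odds confidence score,
    mutation effect prediction and BLOSUM62-based missense severity
    classification, Poisson mutation-load diagnostics for detecting genetic
    contamination, and a synthetic-data generator that emulates an EMS
    mutagenized M2 population sequenced as 64-plex tridimensional pools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
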