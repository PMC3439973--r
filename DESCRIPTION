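Package: svprob
Title: Probabilistic Structural Variant Calling from Paired-End Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative probabilistic caller for structural variants
    (deletions, inversions and generic breakends) from paired-end sequencing
    data. Discordant fragment alignments are clustered geometrically via
    convex breakend polygons in the two-dimensional breakend plane; candidate
    variants are scored with Poisson models of concordant read depth at the
    breakends (and across the deleted interval for deletions), with optional
    mapability scaling; ambiguously mapped fragments are resolved with a
    Metropolis-Hastings sampler over mapping matrices. Includes a fragment
    simulator for rearranged diploid genomes, call-set benchmarking with a
    double-uncertainty breakend metric, and BEDPE/VCF export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
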