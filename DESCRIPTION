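Package: preqcr
Title: Reference-Free Quality Assessment and Genome Characterization from
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-assembly quality assessment of whole-genome shotgun
    sequencing data without a reference genome. Builds an exact k-mer
    counting index over a read set and uses it to estimate the k-mer count
    spectrum and its zero-truncated Poisson mixture decomposition, genome
    size with sequencing-error correction, per-base error rates from
    read-read overlap consensus, the paired-end fragment-size distribution
    via greedy de Bruijn graph walks, the rate of de Bruijn graph branches
    attributable to sequencing errors, allelic variants and genomic
    repeats, and simulated contig N50 as a function of k. Includes a
    synthetic diploid genome and read simulator so every metric can be
    exercised and validated without external data, and writes a versioned
    JSON report with companion plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
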