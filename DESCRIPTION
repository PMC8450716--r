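Package: minitax
Title: Minimizer-Based Taxonomic k-mer Databases and Read Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds taxonomically merged 32-mer databases from reference
    sequences using MinHash minimizer selection (one minimum-FNV-1-hash
    k-mer per fixed-length window), classifies sequencing reads onto a
    taxonomy tree by exact k-mer matching with lowest-common-ancestor
    resolution of each spot, runs a two-phase sparse-screen/dense-quantify
    pipeline with per-kingdom read-count thresholds, and scrubs host reads
    from FASTQ files against a subtraction database.  Includes a synthetic
    taxonomy/genome/read simulator and strain-exclusion accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
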