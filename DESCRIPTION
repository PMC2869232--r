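Package: dlphylo
Title: Alignment-Free Phylogenetics from Denoised K-String Composition Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Whole-genome, alignment-free phylogeny reconstruction from
    K-string (k-mer) composition vectors. Observed K-string frequencies are
    denoised by subtracting the background predicted from (K-1)-string and
    single-letter frequencies under a dynamical-language model; genomes are
    compared by the uncentered (cosine) correlation of the resulting vectors.
    Provides the legacy pseudo-distance (1-C)/2 together with two proper
    distance metrics built on the correlation, the chord distance
    sqrt(2(1-C)) and the piecewise distance 1 - C/rho (rho >= 3), and builds
    neighbor-joining trees from the pairwise matrices. Includes a synthetic
    sequence-evolution module (Jukes-Cantor substitutions along a known tree)
    so the whole pipeline is testable offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
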