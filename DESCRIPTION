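Package: kspectra
Title: Genome Size and Repeat Structure from k-mer Abundance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the total size and per-copy-number repeat structure
    of microbial genomes directly from unassembled shotgun reads. Canonical
    k-mers (default k = 21) are counted across a read set and summarised as
    an abundance spectrum; the spectrum is modelled as a mixture of
    over-dispersed Poisson (negative binomial) components centred at integer
    multiples of the single-copy coverage peak, and the mixture coefficients
    are fitted by staged maximum likelihood. Includes exact copy-number
    tabulation for assembled genomes, a synthetic genome and shotgun-read
    simulator for validation, rank-order spectrum diagnostics, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
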