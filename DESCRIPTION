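Package: clonaltrace
Title: Reconstructing the Mutational History of a Clonal Cell Lineage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the mutational history of a clonally
    expanding somatic cell population from deep sequencing data.
    Implements paired-read consensus merging for sequencing-error
    suppression, chi-square detection of sub-clonal variants against a
    matched control genome with Bonferroni correction, a Poisson
    molecule-sampling model that converts sub-clonal variant counts into
    a per-cell per-generation mutation rate, mutant-allele-frequency
    clustering into division generations (Dirichlet-process and
    finite-mixture routes), cellular lineage-tree construction from
    variant sharing patterns, and 96-channel trinucleotide mutational
    spectra with non-negative matrix factorization signature extraction.
    A synthetic clonal-expansion generator provides labelled truth data
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    pracma,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
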