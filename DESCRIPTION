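Package: pentabase
Title: Group-Theoretic Edit Algebra for DNA/RNA Sequences over a Five-Letter Alphabet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cyclic-group edit calculus on nucleotide sequences
    augmented with an imaginary "empty" base E. The five letters C, A, T (or U),
    G, E carry an order-five cyclic group of shift operations, so substitutions,
    insertions and deletions all become group actions: sequences are sparse
    place-indexed vectors over an implicit background of E's, edits are
    componentwise operator vectors with exact inverses, and recombination is a
    segment swap realised by a pair of mutually inverse operators. On top of the
    algebra the package provides a central-dogma pipeline (complement,
    transcription, intron splicing, maturation, codon partition), verifiers for
    the category and functor laws the construction satisfies, a wallpaper-grid
    visualisation of the five-letter lattice, FASTA/JSON interchange, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
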