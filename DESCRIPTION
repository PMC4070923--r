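Package: mitoComp
Title: Comparative Analysis of Circular Insect Mitochondrial Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative mitogenome analysis built around circular
    1-based annotation arithmetic (gene overlaps and intergenic spacers),
    nucleotide composition and relative synonymous codon usage (RSCU),
    classification of codon sites by degeneracy fold (0-, 2- and 4-fold)
    under a chosen genetic code, class-conditional nucleotide substitution
    frequencies with Jukes-Cantor correction, Poisson-corrected amino acid
    distances, Pearson correlation batteries over per-gene statistics, and
    control-region motif scanning (poly-T stretches, TA(A)n stretches,
    purine-rich blocks, exact tandem repeats, spacer counterparts and
    stem-loop hairpins). Includes a synthetic-data simulator that evolves
    ortholog sets on a star phylogeny with independently controlled
    substitution rates per degeneracy class, so every pipeline stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
biocViews: Genetics, Annotation, SequenceMatching, Software
RoxygenNote: 7.3.3
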