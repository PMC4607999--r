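Package: mitoprofile
Title: Mitogenome Characterization and Distance Phylogenetics for Insect
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize annotated circular mitochondrial genomes
    the way insect mitogenome reports do: feature tables with sizes,
    intergenic spacers and overlaps; strand census; base composition with
    AT and GC skew; start and stop codon assignment under the invertebrate
    mitochondrial code, including incomplete (T and TA) stops; poly-T
    stretch detection in the control region; stem-loop (inverted repeat)
    detection in spacers; template-based tRNA cloverleaf folding with
    missing-arm classification; and comparative analysis of multiple
    mitogenomes via per-gene alignment, concatenated protein-coding-gene
    supermatrices, uncorrected p-distances, neighbor-joining trees with
    bootstrap support, and Robinson-Foulds topology comparison. A seeded
    synthetic-mitogenome generator with substitution-based evolution along
    a tree makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
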