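Package: znfarray
Title: Minisatellite Zinc-Finger Array Phylogenetics and Binding-Motif
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of tandem-repeat (minisatellite) alleles encoding
    C2H2 zinc-finger arrays, as found in exon 12 of the mouse meiotic
    regulator Prdm9. Decomposes nucleotide alleles into 84-bp repeat
    units, translates them into zinc fingers and extracts the
    DNA-contacting recognition-helix residues; computes weighted minimum
    edit distances between repeat-unit arrays (point mutation, whole-unit
    indel and tandem-duplication/slippage costs), with an optional mask
    of the hypervariable contact codons; builds BIONJ neighbor-joining
    trees from the distance matrices and roots them on an outgroup
    allele; assembles array-level DNA-binding position weight matrices
    by reverse-complement concatenation of per-finger specificities,
    compares motifs with a permutation null, scans genomes for putative
    binding sites at a p-value calibrated log-odds threshold and
    quantifies pairwise binding-site overlap; and simulates allele
    families with known evolutionary history plus genomes with planted
    motif instances, so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
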