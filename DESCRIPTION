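Package: mitocompare
Title: Comparative Statistics for Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of annotated circular mitochondrial
    genomes, motivated by the compact mitogenomes of sea anemones
    (Actiniaria): base composition and AT/GC skew, intergenic-region
    accounting and control-region-like G(A)nT motif scanning, codon usage
    and relative synonymous codon usage (RSCU) under the mold/coelenterate
    mitochondrial genetic code, amino-acid usage contrasts between depth
    groups, sliding-window nucleotide diversity (Pi) over gene alignments,
    circular signed gene-order breakpoint distances, and pairwise
    Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction. A seeded
    synthetic mitogenome generator with known ground truth (composition,
    skews, per-gene rates, omega) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
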