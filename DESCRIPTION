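Package: mitoprofiler
Title: Comparative Profiling of Anuran Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of annotated mitochondrial
    genomes of the kind found in high-altitude Nanorana frogs: validated
    annotation models with length, intergenic-spacer and overlap accounting;
    AT/GC strand-skew and base-composition profiles per gene, region and
    codon position; codon usage and relative synonymous codon usage (RSCU)
    under the vertebrate mitochondrial code with incomplete-stop-codon
    handling; control-region decomposition into tandem-repeat arrays and
    conserved motifs (TAS, CSB-1/2/3, OH); gene-order signatures and tandem
    tRNA duplication detection; and preparation of stop-codon-stripped
    13-gene supermatrices with alignment site statistics, p-distances and
    neighbor-joining sanity trees. A seeded synthetic mitogenome generator
    with recorded ground truth makes every stage testable without external
    sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
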