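Package: PolyploidTools
Title: Assembly Curation and Polyploid-Origin Analysis for Very Large Conifer Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of a hexaploid conifer
    genome project: k-mer histogram genome-size estimation with polyploid peak
    detection, telomere- and centromere-guided scaffold curation and splitting,
    staged filtering of predicted gene models (structural, functional-evidence,
    retroelement and processed-pseudogene rules), orthogroup copy-number
    classification, Kimura two-parameter and counting-based dN/dS estimators,
    a gene-tree monophyly test distinguishing autopolyploid from allopolyploid
    origin, and windowed nucleotide diversity and Weir-Cockerham Fst. Includes
    seeded synthetic-data generators that emulate each input so the whole
    pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    phangorn,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeAssembly, Annotation, Phylogenetics, PopulationGenetics
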