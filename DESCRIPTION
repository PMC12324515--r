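Package: hyperlocus
Title: Simulation and Detection of Hypermutable Gene-Family Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying self/non-self recognition loci that evolve
    inside localized structural-mutation hotspots, as observed for the
    paired allorecognition receptors of social amoebae. The package
    forward-simulates annotated genomes along a species tree with a
    rate-elevated locus (segmental duplication, intralocus gene
    conversion, inversion, gene loss, truncation, family transposition),
    curates gene-family homologs with a pseudogene length filter,
    extracts marker-bounded loci, detects head-to-head diverging gene
    pairs, aligns locus pairs into syntenic blocks and calls unalignable
    regions with a local-origin test, computes nucleotide diversity,
    Tajima's D and Nei-Gojobori dN/dS, and scans curated alignments for
    recombination breakpoints with a permutation significance filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    ape,
    phangorn,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
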