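Package: HaploGeo
Title: Haplotype-Based Phylogeography of Alpine Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for intraspecific phylogeography from single-locus
    sequence alignments (chloroplast DNA or nuclear ribosomal ITS).
    Collapses aligned sequences into haplotypes, tabulates them by
    population, and computes gene and nucleotide diversity, Pons-Petit
    GST/NST differentiation with a permutation test for phylogeographic
    structure, hierarchical AMOVA with permutation inference, a spatial
    AMOVA (SAMOVA) partition search by simulated annealing, Mantel tests
    of isolation by distance, minimum spanning haplotype networks,
    mismatch-distribution analysis under the sudden-expansion model with
    parametric bootstrap, Tajima's D and Fu's Fs neutrality tests, and
    expansion-time dating. Includes a coalescent-style simulator for
    generating test data with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vegan,
    igraph
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
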