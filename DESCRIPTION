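Package: contexttrees
Title: Cross-Species Genomic Context Comparison with Context Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares gene neighborhoods (genomic contexts) across annotated
    microbial genomes. Reads per-species GFF annotation and cross-species
    homology-cluster tables, groups genes into contexts (single genes,
    intergenic-distance operon predictions, gene or nucleotide windows,
    custom groupings), scores context-to-context dissimilarity with
    gene-content (Dice, Jaccard), spacing (moving distances) and length
    metrics, and agglomerates contexts into multidendrograms, hierarchical
    trees in which all clusters tied at the minimal distance merge
    simultaneously, so the result is independent of input order. Trees
    export to Newick, matrices to PHYLIP or TSV, and contexts render as
    SVG multi-genome browser panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    xml2,
    optparse
Config/testthat/edition: 3
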