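Package: crossnet
Title: Metabolic Cross-Feeding Annotation of Microbial Co-Occurrence
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates microbial co-occurrence networks with predicted
    metabolic interactions and phenotypic traits. Parses KEGG MODULE
    definition expressions and enumerates their alternatives (minimal KO
    sets realizing every step one way), detects pairwise pathway
    complementarity between genomes, derives seed sets of metabolic
    networks from strongly connected components of the compound graph
    (honoring reaction reversibility) and computes metabolic
    complementarity and competition indices, maps network taxa to genomes
    by exact or fuzzy (Levenshtein) name matching, assembles an annotated
    network with directed donor-to-beneficiary complementarity edges
    exportable as CX2 JSON, and tests network clusters for trait
    enrichment and depletion with Benjamini-Hochberg false discovery rate
    control. Ships deterministic seeded generators that produce every
    input type with planted ground truth, so the whole pipeline runs
    end-to-end without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
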