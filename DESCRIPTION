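Package: phyloshoot
Title: Phylogenetic Sequence Search Against Partitioned Gene-Tree Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds phylogenetically partitioned protein sequence databases
    from homolog groups (multiple sequence alignments and rooted gene trees),
    splitting oversized gene trees into outgroup-anchored subtrees linked by a
    supertree and selecting k-means representative sequences as a search
    profile. Novel query sequences are assigned to candidate gene trees by
    profile search, aligned into the pre-computed alignment, placed on the
    tree by an exhaustive parsimony edge scan, and reported with orthologs and
    paralogs inferred by the species-overlap method. Includes a
    duplication-loss gene-family simulator and an evaluation harness
    (leave-one-out cherry tests, mean average precision at k, ortholog
    precision/recall/F-score, normalized Robinson-Foulds distances).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
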