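Package: mirtarnet
Title: Integration of miRNA and mRNA Differential Expression into Target
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates differential-expression results from paired miRNA-Seq
    and mRNA-Seq experiments into miRNA-target regulatory networks. Provides
    Benjamini-Hochberg significance filtering, intersection of predicted
    miRNA targets with differentially expressed genes, an anti-correlation
    fold-change filter reflecting miRNA-mediated silencing, a binary
    miRNA-by-gene incidence matrix with a target-multiplicity histogram,
    shared-target (Jaccard) miRNA clustering with Newick export, assignment
    of genes to functional modules with derived sub-modules, and export of
    the tripartite miRNA-gene-module network in SIF and GraphML formats.
    A seeded synthetic-data generator produces differential-expression
    tables and prediction tables with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
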