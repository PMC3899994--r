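Package: AncestralGenomes
Title: Ancestral Bacterial Genome Reconstruction from Neighboring Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs ancestral bacterial genomes -- gene content,
    contiguous gene runs, and replicon (chromosome/plasmid) architecture --
    for every internal node of a rooted bifurcating species tree, using
    binary presence characters over orthologous gene families and
    neighboring gene pairs (NGPs). Ancestral states are inferred by Fitch
    maximum parsimony or by a two-state continuous-time Markov maximum
    likelihood model; called adjacencies are assembled into stranded gene
    runs through a weighted gene-end graph and minimum spanning forest;
    replicon architecture is derived from co-inheritance groups with an
    outgroup-guided group graph, a gene-run-driven replicon merge step,
    and core-gene chromosome restoration. Gene- and replicon-scale
    evolutionary events are inferred along each branch. Includes a genome
    evolution simulator (gene gain/loss/duplication, reversal,
    translocation, transposition, replicon gain/merge/split/loss) that
    provides ground truth for evaluation, plus precision/recall,
    coverage, operon-support and leave-one-out stability protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
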