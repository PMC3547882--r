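Package: linkmark
Title: Genome-Context Prediction of Protein Functional Linkages and
    Pathway-Stratified ROC Benchmarking
Version: 1.0.0
Authors@R:
    person("Linkmark", "Developers", email = "maintainers@linkmark.dev",
           role = c("aut", "cre"))
Description: Implements five genome-context scorers for protein-protein
    functional linkage in prokaryotes - Gene Neighbor (conserved chromosomal
    proximity), Gene Cluster (shared operon-like runs of co-directional
    genes), Phylogenetic Profiling (correlated ortholog bit-score profiles),
    genome-distance-corrected Mirrortree (coevolution of inter-species
    distance matrices after removal of the speciation signal), and Expression
    Similarity (co-expression across conditions) - together with a
    pathway-stratified gold-standard builder and threshold/ROC/AUC
    benchmarking. A synthetic-data module generates complete comparative
    genomics worlds (species tree, presence/absence profiles, gene orders,
    expression compendia, distance matrices, two-level pathway annotations)
    with controllable co-inheritance, operon, co-expression and co-evolution
    signal plus ground-truth linkage labels, so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    knitr,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
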