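Package: kgforge
Title: Query-Driven Construction and Analysis of Heterogeneous Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds small, query-specific biomedical knowledge graphs from
    flat-file collections of proteins, protein-protein interactions, ontology
    terms (diseases, pathways, phenotypes), drugs, compounds and bioactivity
    records. Node selection at every stage uses a degree-weighted
    hypergeometric overrepresentation score that favours terms specifically
    associated with the growing graph over promiscuous hub terms. Bioactive
    compounds are gathered through an iterative pChEMBL-cutoff pool search,
    clustered on fingerprint Tanimoto similarity, and added under a
    cluster-aware diversity rule; drug/compound-target edges carry
    evidence-priority labels (approved > experimental > predicted). Includes
    graph diversity and stability analyses (pairwise node identity,
    observed-versus-expected term frequency with Fisher's exact test), a
    synthetic datastore generator with planted hubs and planted compound
    scaffold clusters, concentric multi-layer layouts, and GraphML/JSON/TSV
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
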