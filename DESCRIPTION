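Package: ligscout
Title: Knowledge-Based Candidate Ligand Prediction for Protein Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts and ranks small molecules likely to bind a query
    protein using only its sequence. Homologous protein-ligand complexes
    are found by local sequence search against a structure library, the
    query is partitioned into predicted domains from homolog domain
    annotations, hit structures are superposed onto a per-domain
    reference by iterative outlier-trimmed rigid-body fitting, and each
    ligand is scored by its hydrogen bonds and nonbonded contacts
    weighted by the conservation of the contacted residues relative to
    the query. Candidates from compound-source tables are pooled with
    the structure-derived ligands, clustered by maximum-common-subgraph
    Tanimoto similarity with complete linkage, and ranked within and
    across clusters. Includes a synthetic-fixture generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    igraph,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
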