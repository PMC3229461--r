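Package: sbpathdb
Title: Integrating Kinetic Systems-Biology Models with Pathway Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses SBML Level 2 kinetic models into a relational entity
    model, extracts MIRIAM qualifier annotations from their RDF blocks,
    loads a KEGG-like pathway-side store, and builds explicit cross-source
    mapping tables (species to molecular entities, reactions to process
    entities, models to pathways) plus organism, Gene Ontology and EC-number
    annotation tables.  Descendant and ancestor queries over ontology DAGs
    are answered with a NodeCodes path-labeling scheme whose results are
    verified against an iterative traversal baseline.  All records are
    persisted in an embedded SQLite store behind a wrapper API with cached
    dimension tables, and coverage and growth reports summarise the
    integrated content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
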