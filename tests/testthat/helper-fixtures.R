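# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small SBML L2 document: 1 compartment, 2 species, 1 reaction with
# 2 reactants + 1 product, a kinetic law and annotations on model/species/
# reaction.  Element counts here are the reference for round-trip tests.
toy_sbml <- function(model_id = "toy", with_name = TRUE) {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
 <model id="%s"%s>
  <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/" xmlns:bqmodel="http://biomodels.net/model-qualifiers/">
   <rdf:Description>
    <bqbiol:is><rdf:Bag><rdf:li rdf:resource="urn:miriam:kegg.pathway:tbr00010"/></rdf:Bag></bqbiol:is>
    <bqbiol:is><rdf:Bag><rdf:li rdf:resource="urn:miriam:taxonomy:5691"/></rdf:Bag></bqbiol:is>
    <bqbiol:isVersionOf><rdf:Bag><rdf:li rdf:resource="urn:miriam:obo.go:GO%%3A0006096"/></rdf:Bag></bqbiol:isVersionOf>
    <bqmodel:isDescribedBy><rdf:Bag><rdf:li rdf:resource="urn:miriam:pubmed:11415442"/></rdf:Bag></bqmodel:isDescribedBy>
   </rdf:Description></rdf:RDF></annotation>
  <listOfCompartments><compartment id="c1" size="1"/></listOfCompartments>
  <listOfSpecies>
   <species id="S1" compartment="c1" initialConcentration="1">
    <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
     <rdf:Description><bqbiol:is><rdf:Bag>
      <rdf:li rdf:resource="urn:miriam:kegg.compound:C00074"/>
      <rdf:li rdf:resource="urn:miriam:obo.chebi:CHEBI%%3A18021"/>
     </rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>
   </species>
   <species id="S2" compartment="c1" initialAmount="2"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
     <rdf:Description>
      <bqbiol:is><rdf:Bag><rdf:li rdf:resource="urn:miriam:kegg.reaction:R00771"/></rdf:Bag></bqbiol:is>
      <bqbiol:isVersionOf><rdf:Bag><rdf:li rdf:resource="urn:miriam:ec-code:5.3.1.9"/></rdf:Bag></bqbiol:isVersionOf>
     </rdf:Description></rdf:RDF></annotation>
    <listOfReactants>
     <speciesReference species="S1" stoichiometry="2"/>
     <speciesReference species="S2"/>
    </listOfReactants>
    <listOfProducts><speciesReference species="S1"/></listOfProducts>
    <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k1</ci><ci>S1</ci></apply></math>
     <listOfParameters><parameter id="k1" value="0.5"/></listOfParameters></kineticLaw>
   </reaction>
  </listOfReactions>
 </model></sbml>', model_id, if (with_name) ' name="Toy"' else "")
}

# independent XML element walk (xml2 only, none of the package record
# model): counts elements by local name
xml_walk_counts <- function(doc_text) {
  doc <- xml2::read_xml(doc_text)
  count <- function(local) length(xml2::xml_find_all(
    doc, sprintf("//*[local-name()='%s']", local)))
  list(
    species = count("species"),
    reactions = count("reaction"),
    compartments = count("compartment"),
    reactants_products = length(xml2::xml_find_all(
      doc, "//*[local-name()='speciesReference']")),
    modifiers = length(xml2::xml_find_all(
      doc, "//*[local-name()='modifierSpeciesReference']")),
    kinetic_laws = count("kineticLaw"),
    function_definitions = count("functionDefinition"),
    events = count("event"),
    rules = length(xml2::xml_find_all(
      doc, paste0("//*[local-name()='assignmentRule' or ",
                  "local-name()='rateRule' or ",
                  "local-name()='algebraicRule']")))
  )
}

# brute-force count of distinct virtual-source -> v paths (root-path
# count); DFS enumeration, independent of the labeling code
brute_force_path_counts <- function(dag) {
  parents <- split(dag$edges$parent, dag$edges$child)
  memo <- new.env(parent = emptyenv())
  count_paths <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    ps <- parents[[v]]
    n <- if (is.null(ps) || !length(ps)) 1 else sum(vapply(ps, count_paths,
                                                           numeric(1)))
    memo[[v]] <- n
    n
  }
  vapply(dag$nodes, count_paths, numeric(1))
}

# reachability closure via igraph BFS distances — the independent
# transitive-closure oracle
closure_descendants <- function(dag) {
  g <- igraph::graph_from_data_frame(dag$edges[, c("parent", "child")],
                                     vertices = dag$nodes)
  d <- igraph::distances(g, mode = "out")
  lapply(stats::setNames(dag$nodes, dag$nodes), function(t)
    sort(setdiff(colnames(d)[is.finite(d[t, ])], t)))
}

# in-memory store loaded with the toy model; caller closes
toy_store <- function() {
  st <- store_open(":memory:")
  ds <- ensure_data_source(st, "test")
  b <- parse_sbml_document(toy_sbml(), ds, deterministic_ids = TRUE)
  persist_model_bundle(st, b)
  st
}

# full aligned fixture set (corpus + pathway source) in a temp dir
make_fixture_set <- function(config = list(), seed = 11) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  led <- generate_model_corpus(config, seed = seed,
                               dir = file.path(td, "sbml"))
  led <- generate_pathway_source(led, seed = seed,
                                 dir = file.path(td, "pathway"))
  list(dir = td, ledger = led)
}

# translate a ledger subject (model sbmlId, subject sbmlId, kind) to the
# deterministic internal id used at ingest
ledger_internal_id <- function(ds_id, model, kind, sbml_id) {
  paste(ds_id, model, kind, sbml_id, sep = ":")
}

# actual mapping rows of a store, normalised to ledger terms
actual_mapping_rows <- function(st, ds_id) {
  q <- sbpathdb:::st_query
  quals <- q(st, "SELECT id, name FROM AnnotationQualifier")
  sp <- q(st,
    "SELECT m.speciesId, m.molecularEntityId AS target, m.qualifierId
     FROM MapSpeciesMolecularEntities m")
  rx <- q(st,
    "SELECT m.reactionId, m.processId AS target, m.qualifierId
     FROM MapReactionsProcessEntities m")
  mp <- q(st,
    "SELECT m.modelId, m.pathwayId AS target, m.qualifierId
     FROM MapModelsPathways m")
  qname <- function(id) quals$name[match(id, quals$id)]
  rbind(
    if (nrow(sp)) data.frame(subjectId = sp$speciesId, target = sp$target,
                             qualifier = qname(sp$qualifierId),
                             table = "MapSpeciesMolecularEntities",
                             stringsAsFactors = FALSE),
    if (nrow(rx)) data.frame(subjectId = rx$reactionId, target = rx$target,
                             qualifier = qname(rx$qualifierId),
                             table = "MapReactionsProcessEntities",
                             stringsAsFactors = FALSE),
    if (nrow(mp)) data.frame(subjectId = mp$modelId, target = mp$target,
                             qualifier = qname(mp$qualifierId),
                             table = "MapModelsPathways",
                             stringsAsFactors = FALSE)
  )
}

# expected mapping rows straight off the fixture ledger
expected_mapping_rows <- function(ledger, ds_id) {
  e <- ledger$expected
  kind_tag <- c(species = "species", reaction = "reaction", model = "model")
  data.frame(
    subjectId = ledger_internal_id(ds_id, e$model, kind_tag[e$subjectKind],
                                   e$subject),
    target = e$target, qualifier = e$qualifier, table = e$table,
    stringsAsFactors = FALSE)
}

# ingest a fixture set into a fresh in-memory store and build mappings
ingest_fixture_set <- function(fx) {
  st <- store_open(":memory:")
  ds <- ensure_data_source(st, "fixtures")
  for (f in list.files(file.path(fx$dir, "sbml"), full.names = TRUE)) {
    b <- parse_sbml_document(f, ds, deterministic_ids = TRUE)
    persist_model_bundle(st, b)
  }
  ps <- load_pathway_source(file.path(fx$dir, "pathway"))
  persist_pathway_store(st, ps)
  build_entity_mappings(st)
  build_annotation_tables(st, quiet = TRUE)
  list(store = st, ds = ds, pstore = ps)
}
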