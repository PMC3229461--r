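test_that("mapping recovers the planted ground truth exactly", {
  fx <- make_fixture_set(list(models = 5), seed = 53)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))
  act <- actual_mapping_rows(st, env$ds)
  exp <- expected_mapping_rows(fx$ledger, env$ds)
  key <- function(df) sort(do.call(paste, c(df[c("subjectId", "target",
                                                 "qualifier", "table")],
                                            sep = "\r")))
  expect_identical(key(act), key(exp))   # precision = recall = 1
})

test_that("unmatched links produce no rows but are counted", {
  fx <- make_fixture_set(list(models = 4, unmatched_rate = 0.5), seed = 59)
  st <- store_open(":memory:")
  on.exit(store_close(st))
  ds <- ensure_data_source(st, "fixtures")
  for (f in list.files(file.path(fx$dir, "sbml"), full.names = TRUE)) {
    persist_model_bundle(st, parse_sbml_document(f, ds,
                                                 deterministic_ids = TRUE))
  }
  persist_pathway_store(st, load_pathway_source(file.path(fx$dir,
                                                          "pathway")))
  counts <- build_entity_mappings(st)
  led <- fx$ledger$links
  n_unmatched_mappable <- sum(!led$matched & led$namespace %in%
    c("kegg.compound", "obo.chebi", "kegg.reaction", "kegg.pathway"))
  expect_equal(counts$unmatched, n_unmatched_mappable)
  act <- actual_mapping_rows(st, ds)
  exp <- expected_mapping_rows(fx$ledger, ds)
  expect_equal(if (is.null(act)) 0L else nrow(act), nrow(exp))
})

test_that("qualifiers are conserved from link to mapping row", {
  fx <- make_fixture_set(list(models = 3), seed = 61)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))
  act <- actual_mapping_rows(st, env$ds)
  planted <- fx$ledger$links
  for (i in seq_len(nrow(act))) {
    subject_sbml <- sub(".*:", "", act$subjectId[i])
    hit <- planted[planted$subject == subject_sbml &
                   planted$qualifier == act$qualifier[i], , drop = FALSE]
    expect_gt(nrow(hit), 0L, label = paste("qualifier provenance",
                                           act$subjectId[i]))
  }
})

test_that("mapping never creates entities on either side", {
  fx <- make_fixture_set(list(models = 3), seed = 67)
  st <- store_open(":memory:")
  on.exit(store_close(st))
  ds <- ensure_data_source(st, "fixtures")
  for (f in list.files(file.path(fx$dir, "sbml"), full.names = TRUE)) {
    persist_model_bundle(st, parse_sbml_document(f, ds,
                                                 deterministic_ids = TRUE))
  }
  persist_pathway_store(st, load_pathway_source(file.path(fx$dir,
                                                          "pathway")))
  entity_tables <- c("Species", "Reaction", "Model", "molecular_entities",
                     "processes", "pathways", "go_terms", "ec_numbers")
  before <- vapply(entity_tables, function(t) store_count(st, t),
                   integer(1))
  build_entity_mappings(st)
  build_annotation_tables(st, quiet = TRUE)
  after <- vapply(entity_tables, function(t) store_count(st, t), integer(1))
  expect_identical(before, after)
})

test_that("annotation tables resolve organisms, GO terms and EC numbers", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  ds <- ensure_data_source(st, "test")
  b <- parse_sbml_document(toy_sbml(), ds, deterministic_ids = TRUE)
  persist_model_bundle(st, b)
  # pathway side with the GO term, the EC number and an organism group
  # holding taxon 5691
  td <- withr::local_tempdir()
  writeLines(c("id\tname\tncbi_taxonomy_ids", "G1\ttrypanosomes\t5691"),
             file.path(td, "organism_groups.tsv"))
  writeLines(c("go_id\tname\tparent_ids", "GO:0006096\tglycolysis\t"),
             file.path(td, "go_terms.tsv"))
  writeLines(c("ec_number\tname", "5.3.1.9\tGPI"),
             file.path(td, "ec_numbers.tsv"))
  persist_pathway_store(st, load_pathway_source(td))
  counts <- build_annotation_tables(st, quiet = TRUE)
  expect_equal(counts$model_organism, 1L)
  expect_equal(counts$sbase_go, 1L)
  expect_equal(counts$reaction_ec, 1L)
  mo <- sbpathdb:::st_query(st, "SELECT * FROM ModelOrganism")
  expect_equal(mo$NCBITaxonomyId, 5691L)
  expect_identical(mo$organismGroupId, "G1")
  ec <- sbpathdb:::st_query(st,
    "SELECT m.ecNumber, q.name AS qualifier FROM MapReactionECNumber m
     JOIN AnnotationQualifier q ON q.id = m.qualifierId")
  expect_identical(ec$ecNumber, "5.3.1.9")
  expect_identical(ec$qualifier, "isVersionOf")
})

test_that("GO and EC annotations outside the loaded tables are skipped", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  ds <- ensure_data_source(st, "test")
  persist_model_bundle(st, parse_sbml_document(toy_sbml(), ds,
                                               deterministic_ids = TRUE))
  # no pathway side at all: GO:0006096 and 5.3.1.9 are unknown
  counts <- build_annotation_tables(st, quiet = TRUE)
  expect_equal(counts$sbase_go, 0L)
  expect_equal(counts$reaction_ec, 0L)
  expect_gt(counts$skipped, 0L)
  expect_equal(nrow(store_orphan_check(st)), 0L)
})

test_that("mapping summary equals the ledger-derived counts", {
  fx <- make_fixture_set(list(models = 5), seed = 71)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))
  s <- summarize_mappings(st)
  led <- fx$ledger$links
  exp <- fx$ledger$expected
  cfg <- fx$ledger$config
  expect_equal(s$models_total, cfg$models)
  expect_equal(s$reactions_total, cfg$models * cfg$reactions_per_model)
  expect_equal(s$species_total, cfg$models * cfg$species_per_model)
  expect_equal(s$models_with_pathway_map,
               length(unique(exp$model[exp$table == "MapModelsPathways"])))
  expect_equal(s$species_mapped,
               length(unique(paste(exp$model, exp$subject)[
                 exp$table == "MapSpeciesMolecularEntities"])))
  expect_equal(s$reactions_mapped,
               length(unique(paste(exp$model, exp$subject)[
                 exp$table == "MapReactionsProcessEntities"])))
  expect_equal(s$distinct_pathways_hit,
               length(unique(exp$target[exp$table == "MapModelsPathways"])))
  expect_equal(s$models_with_go_annotation,
               length(unique(led$model[led$namespace == "obo.go"])))
})

test_that("an empty store summarises to all zeros", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  s <- summarize_mappings(st)
  expect_true(all(unlist(s) == 0L))
})
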