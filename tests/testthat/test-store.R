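test_that("persisting a bundle creates matching row counts per table", {
  st <- toy_store()
  on.exit(store_close(st))
  expect_equal(store_count(st, "Model"), 1L)
  expect_equal(store_count(st, "Species"), 2L)
  expect_equal(store_count(st, "Reaction"), 1L)
  expect_equal(store_count(st, "ReactionSpecies"), 3L)
  expect_equal(store_count(st, "KineticLaw"), 1L)
  expect_equal(store_count(st, "KineticLawParameter"), 1L)
  # links extracted and stored alongside
  expect_gt(store_count(st, "annotation_links"), 0L)
  expect_equal(nrow(store_orphan_check(st)), 0L)
})

test_that("re-ingesting the same document is idempotent", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  ds <- ensure_data_source(st, "test")
  b <- parse_sbml_document(toy_sbml(), ds, deterministic_ids = TRUE)
  persist_model_bundle(st, b)
  counts1 <- vapply(c("Sbase", "Model", "Species", "Reaction",
                      "ReactionSpecies", "annotation_links"),
                    function(t) store_count(st, t), integer(1))
  persist_model_bundle(st, b)
  counts2 <- vapply(names(counts1), function(t) store_count(st, t),
                    integer(1))
  expect_identical(counts1, counts2)
})

test_that("a bundle referencing a missing foreign key is rejected", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  ds <- ensure_data_source(st, "test")
  b <- parse_sbml_document(toy_sbml(), ds, deterministic_ids = TRUE)
  b$species$compartmentId <- "no-such-compartment"
  expect_error(persist_model_bundle(st, b), "FOREIGN KEY|constraint")
  # failed transaction rolled back completely
  expect_equal(store_count(st, "Model"), 0L)
  expect_equal(store_count(st, "Sbase"),
               length(sbml_base_units()))  # only the seeded base units
})

test_that("the data source name is a candidate key", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  id1 <- ensure_data_source(st, "biomodels", "http://example.org")
  id2 <- ensure_data_source(st, "biomodels")
  expect_identical(id1, id2)
  expect_equal(store_count(st, "DataSource"), 1L)
})

test_that("cascade delete removes every dependent row and nothing else", {
  fx <- make_fixture_set(list(models = 2, species_per_model = 4,
                              reactions_per_model = 3), seed = 21)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))
  models <- sbpathdb:::st_query(st, "SELECT id FROM Model ORDER BY sbmlId")
  expect_equal(nrow(models), 2L)
  pathway_rows <- store_count(st, "molecular_entities")
  n_map_before <- store_count(st, "MapSpeciesMolecularEntities")

  removed <- delete_model(st, models$id[1])
  expect_gt(removed, 0L)
  # the surviving model is intact
  expect_equal(store_count(st, "Model"), 1L)
  expect_gt(store_count(st, "Species"), 0L)
  # mapping rows for the deleted model's species are gone
  expect_lt(store_count(st, "MapSpeciesMolecularEntities"), n_map_before)
  # pathway side untouched
  expect_equal(store_count(st, "molecular_entities"), pathway_rows)
  # no orphan anywhere (full foreign-key sweep)
  expect_equal(nrow(store_orphan_check(st)), 0L)
  # no annotation link of the deleted model survives
  expect_equal(nrow(sbpathdb:::st_query(
    st, "SELECT * FROM annotation_links WHERE modelId = ?",
    list(models$id[1]))), 0L)

  expect_error(delete_model(st, "no-such-model"), "lookup error")
})

test_that("deleting the only model empties every model-side table", {
  st <- toy_store()
  on.exit(store_close(st))
  mid <- sbpathdb:::st_query(st, "SELECT id FROM Model")$id
  delete_model(st, mid)
  for (tab in c("Model", "Species", "Reaction", "ReactionSpecies",
                "KineticLaw", "KineticLawParameter", "annotation_links")) {
    expect_equal(store_count(st, tab), 0L, info = tab)
  }
  # Sbase retains only the seeded base units
  expect_equal(store_count(st, "Sbase"), length(sbml_base_units()))
})

test_that("dimension cache is resident, rebuilt on write, and read-free", {
  st <- store_open(":memory:")
  on.exit(store_close(st))
  roles <- dimension_table(st, "ReactionSpeciesRole")
  expect_setequal(roles$name, c("reactant", "product", "modifier"))
  # cache hits perform zero store reads
  r0 <- store_counters(st)$reads
  h0 <- store_counters(st)$cache_hits
  for (i in 1:5) dimension_table(st, "RuleType")
  expect_equal(store_counters(st)$reads, r0)
  expect_equal(store_counters(st)$cache_hits, h0 + 5L)
  # rebuild-on-write: a new RuleType row appears in the cache
  sbpathdb:::st_exec(st, "INSERT INTO RuleType (name) VALUES ('custom')")
  expect_true("custom" %in% dimension_table(st, "RuleType")$name)
})

test_that("query results are identical with the cache enabled or disabled", {
  fx <- make_fixture_set(list(models = 3), seed = 31)
  for (use_cache in c(TRUE, FALSE)) {
    st <- store_open(":memory:", use_cache = use_cache)
    ds <- ensure_data_source(st, "fixtures")
    for (f in list.files(file.path(fx$dir, "sbml"), full.names = TRUE)) {
      persist_model_bundle(st, parse_sbml_document(
        f, ds, deterministic_ids = TRUE))
    }
    persist_pathway_store(st, load_pathway_source(file.path(fx$dir,
                                                            "pathway")))
    build_entity_mappings(st)
    pw <- sbpathdb:::st_query(st, "SELECT id FROM pathways ORDER BY id")$id
    res <- lapply(pw, function(p)
      query_models_with_pathway_reactions(st, p))
    if (use_cache) cached_res <- res else
      expect_identical(res, cached_res)
    store_close(st)
  }
})

test_that("built-in queries answer the fixture cases", {
  fx <- make_fixture_set(list(models = 4), seed = 41)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))

  pw <- sbpathdb:::st_query(st,
    "SELECT DISTINCT pathwayId FROM MapModelsPathways")$pathwayId
  # query 3: role names resolved through the cached dimension
  rows <- query_models_with_pathway_reactions(st, pw[1])
  if (nrow(rows)) {
    expect_true(all(rows$roleName %in% c("reactant", "product", "modifier")))
  }
  expect_error(query_models_with_pathway_reactions(st, "PW-none"),
               "lookup error")

  # query 2: models via species -> molecular entity -> process participants
  met_models <- query_models_with_pathway_metabolites(st, pw[1])
  direct <- sbpathdb:::st_query(st,
    "SELECT DISTINCT s.modelId FROM MapSpeciesMolecularEntities ms
     JOIN Species s ON s.id = ms.speciesId
     JOIN process_participants pa
       ON pa.molecularEntityId = ms.molecularEntityId
     JOIN pathway_processes pp ON pp.processId = pa.processId
     WHERE pp.pathwayId = ?", list(pw[1]))$modelId
  expect_setequal(met_models, direct)

  # query 4: kinetic-law presence required; process outside pathway -> empty
  pr <- sbpathdb:::st_query(st,
    "SELECT DISTINCT processId FROM MapReactionsProcessEntities")$processId
  in_pw <- sbpathdb:::st_query(st,
    "SELECT processId FROM pathway_processes WHERE pathwayId = ?",
    list(pw[1]))$processId
  if (length(intersect(pr, in_pw))) {
    kin <- query_kinetic_models_for_process(st, pw[1],
                                            intersect(pr, in_pw)[1])
    expect_true(all(!is.na(kin$kineticLawId)))
  }
  outside <- setdiff(pr, in_pw)
  if (length(outside)) {
    expect_equal(nrow(query_kinetic_models_for_process(st, pw[1],
                                                       outside[1])), 0L)
  }
})

test_that("flux-expression query requires at least two distinct rate laws", {
  fx <- make_fixture_set(list(models = 4), seed = 43)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))
  procs <- sbpathdb:::st_query(st,
    "SELECT processId, COUNT(*) AS n FROM MapReactionsProcessEntities
     GROUP BY processId")
  for (i in seq_len(nrow(procs))) {
    rows <- query_flux_expressions_for_process(st, procs$processId[i])
    if (nrow(rows)) {
      expect_gte(length(unique(rows$mathml)), 2L)
    }
  }
  # single mapped reaction can never produce a group
  singles <- procs$processId[procs$n == 1L]
  for (p in singles) {
    expect_equal(nrow(query_flux_expressions_for_process(st, p)), 0L)
  }
  expect_error(query_flux_expressions_for_process(st, "PR-none"),
               "lookup error")
})

test_that("browsing by GO term includes the term and all descendants only", {
  fx <- make_fixture_set(list(models = 6, go_link_rate = 1.0), seed = 47)
  env <- ingest_fixture_set(fx)
  st <- env$store
  on.exit(store_close(st))
  go <- fx$ledger$go
  lab <- assign_nodecodes(sb_dag(
    data.frame(parent = go$parents$parentId, child = go$parents$goId),
    nodes = go$terms$goId))

  # iterative oracle: union of direct-annotation lookups over
  # descendants(t) + t
  oracle <- function(goId) {
    dag <- sb_dag(data.frame(parent = go$parents$parentId,
                             child = go$parents$goId),
                  nodes = go$terms$goId)
    terms <- c(goId, descendants_iterative(dag, goId))
    hits <- sbpathdb:::st_query(st, sprintf(
      "SELECT DISTINCT sbaseId FROM MapSbaseGO WHERE goId IN (%s)",
      paste(rep("?", length(terms)), collapse = ",")),
      as.list(terms))$sbaseId
    sort(sbpathdb:::.sbase_owner_models(st, hits))
  }
  for (t in go$terms$goId) {
    expect_identical(browse_models_by_go_term(st, t, lab), oracle(t),
                     info = t)
  }
  # root catches every annotated model; a model annotated to the term
  # itself is included
  root_models <- browse_models_by_go_term(st, "GO:0008150", lab)
  direct <- sbpathdb:::st_query(st,
    "SELECT DISTINCT modelId FROM annotation_links
     WHERE namespace = 'obo.go' AND externalId IN
       (SELECT goId FROM go_terms)")$modelId
  expect_setequal(root_models, direct)
  expect_error(browse_models_by_go_term(st, "GO:404", lab), "lookup error")
})
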