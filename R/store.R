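# Embedded relational store behind a single-point-of-contact wrapper.  All
# reads and writes flow through the internal st_query()/st_exec() helpers;
# callers never see SQL.  Twelve small dimension tables are mirrored in an
# in-memory cache that is rebuilt on any write to a cached table.

.dimension_tables <- c(
  "Attribute", "EntityName", "GraphNode", "MolecularEntityType", "NameId",
  "NameType", "PathwaysType", "ProcessEntityRole", "ReactionSpeciesRole",
  "RnaType", "RuleType", "UnitDefinition"
)

#' Open (and initialise) an sbpathdb store
#'
#' Creates or opens a single-file SQLite database holding the full schema:
#' model-side tables extending Sbase, pathway-side tables, the six
#' mapping/annotation tables, the qualifier dimension and the precomputed
#' NodeCodes table.  On first open the schema is created and seeded: the
#' participant-role and rule-type dimensions, the pre-filled annotation
#' qualifiers and the SBML built-in base units (unit definitions with an
#' absent model id) all exist before any document is ingested.
#'
#' @param path database file, or `":memory:"` for a transient store.
#' @param use_cache keep the dimension tables cached in memory (the cache is
#'   a pure optimisation: query results are identical either way).
#' @return an object of class `sb_store`.  Close with [store_close()].
#' @export
store_open <- function(path = ":memory:", use_cache = TRUE) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  st <- structure(
    list(con = con, path = path,
         cache = new.env(parent = emptyenv()),
         counters = new.env(parent = emptyenv()),
         use_cache = use_cache),
    class = "sb_store")
  st$counters$reads <- 0L
  st$counters$cache_hits <- 0L
  if (!DBI::dbExistsTable(con, "Sbase")) {
    .store_init_schema(st)
  }
  if (use_cache) load_dimension_cache(st)
  st
}

.store_init_schema <- function(store) {
  ddl <- readLines(system.file("sql", "schema.sql", package = "sbpathdb"),
                   warn = FALSE)
  ddl <- sub("--.*$", "", ddl)
  stmts <- strsplit(paste(ddl, collapse = "\n"), ";", fixed = TRUE)[[1]]
  for (s in stmts) {
    s <- trimws(s)
    if (nzchar(s)) DBI::dbExecute(store$con, s)
  }
  DBI::dbExecute(store$con, "INSERT INTO SchemaVersion VALUES (1)")
  for (r in c("reactant", "product", "modifier")) {
    st_exec(store, "INSERT INTO ReactionSpeciesRole (name) VALUES (?)",
            list(r))
  }
  for (r in c("substrate", "product", "cofactor")) {
    st_exec(store, "INSERT INTO ProcessEntityRole (name) VALUES (?)", list(r))
  }
  for (r in c("algebraic", "assignment", "rate")) {
    st_exec(store, "INSERT INTO RuleType (name) VALUES (?)", list(r))
  }
  for (r in c("compound", "glycan", "protein", "rna")) {
    st_exec(store, "INSERT INTO MolecularEntityType (name) VALUES (?)",
            list(r))
  }
  for (q in annotation_qualifiers()$prefilled) {
    st_exec(store, "INSERT INTO AnnotationQualifier (name) VALUES (?)",
            list(q))
  }
  for (u in sbml_base_units()) {
    uid <- paste0("base-unit:", u)
    st_exec(store, "INSERT INTO Sbase (id) VALUES (?)", list(uid))
    st_exec(store,
            "INSERT INTO UnitDefinition (id, modelId, sbmlId, name)
             VALUES (?, NULL, ?, ?)", list(uid, u, u))
  }
  invisible(store)
}

#' Close a store
#' @param store an `sb_store`.
#' @export
store_close <- function(store) {
  stopifnot(inherits(store, "sb_store"))
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.sb_store <- function(x, ...) {
  cat("<sb_store> ", x$path, "\n", sep = "")
  cat("  models:", store_count(x, "Model"),
      " species:", store_count(x, "Species"),
      " reactions:", store_count(x, "Reaction"), "\n")
  invisible(x)
}

# --- wrapper primitives (not exported): the single point of store contact --

st_query <- function(store, sql, params = NULL) {
  store$counters$reads <- store$counters$reads + 1L
  if (is.null(params)) DBI::dbGetQuery(store$con, sql)
  else DBI::dbGetQuery(store$con, sql, params = params)
}

st_exec <- function(store, sql, params = NULL) {
  n <- if (is.null(params)) DBI::dbExecute(store$con, sql)
  else DBI::dbExecute(store$con, sql, params = params)
  # rebuild-on-write contract for cached dimension tables
  touched <- .dimension_tables[vapply(
    .dimension_tables, function(t) grepl(paste0("\\b", t, "\\b"), sql),
    logical(1))]
  if (length(touched) && isTRUE(store$use_cache) &&
      grepl("^\\s*(INSERT|UPDATE|DELETE)", sql, ignore.case = TRUE)) {
    for (t in touched) .cache_one(store, t)
  }
  n
}

.cache_one <- function(store, tab) {
  store$counters$reads <- store$counters$reads + 1L
  store$cache[[tab]] <- DBI::dbGetQuery(
    store$con, paste0("SELECT * FROM ", DBI::dbQuoteIdentifier(store$con,
                                                               tab)))
  invisible()
}

#' Load (or rebuild) the dimension-table cache
#'
#' All twelve configured dimension tables become fully memory-resident;
#' subsequent dimension lookups are memory operations and perform zero
#' store reads.
#'
#' @param store an `sb_store`.
#' @return the cache environment, invisibly.
#' @export
load_dimension_cache <- function(store) {
  stopifnot(inherits(store, "sb_store"))
  for (tab in .dimension_tables) .cache_one(store, tab)
  invisible(store$cache)
}

#' Look up a dimension table
#'
#' Served from the in-memory cache when enabled (counted as a cache hit,
#' with no store read), from the store otherwise.
#'
#' @param store an `sb_store`.
#' @param name one of the twelve dimension table names.
#' @return the dimension table as a data frame.
#' @export
dimension_table <- function(store, name) {
  stopifnot(inherits(store, "sb_store"), name %in% .dimension_tables)
  if (isTRUE(store$use_cache) && !is.null(store$cache[[name]])) {
    store$counters$cache_hits <- store$counters$cache_hits + 1L
    return(store$cache[[name]])
  }
  st_query(store, paste0("SELECT * FROM ",
                         DBI::dbQuoteIdentifier(store$con, name)))
}

#' Read access counters (instrumentation)
#' @param store an `sb_store`.
#' @return list with `reads` (store reads issued) and `cache_hits`.
#' @export
store_counters <- function(store) {
  list(reads = store$counters$reads, cache_hits = store$counters$cache_hits)
}

#' Count rows of a table through the wrapper
#' @param store an `sb_store`.
#' @param table table name.
#' @return integer row count.
#' @export
store_count <- function(store, table) {
  as.integer(st_query(store, paste0(
    "SELECT COUNT(*) AS n FROM ",
    DBI::dbQuoteIdentifier(store$con, table)))$n)
}

.qualifier_id <- function(store, name) {
  q <- st_query(store, "SELECT id FROM AnnotationQualifier WHERE name = ?",
                list(name))
  if (nrow(q)) return(q$id[[1]])
  # members beyond the pre-filled list are inserted on first use
  st_exec(store, "INSERT INTO AnnotationQualifier (name) VALUES (?)",
          list(name))
  st_query(store, "SELECT id FROM AnnotationQualifier WHERE name = ?",
           list(name))$id[[1]]
}

.role_id <- function(store, name) {
  roles <- dimension_table(store, "ReactionSpeciesRole")
  id <- roles$id[roles$name == name]
  if (!length(id)) stop("unknown reaction-species role: ", name,
                        call. = FALSE)
  id[[1]]
}

#' Register a data source
#'
#' @param store an `sb_store`.
#' @param name data-source name (a candidate key: unique across the store).
#' @param url optional URL.
#' @return the data-source id (existing one if the name is already
#'   registered).
#' @export
ensure_data_source <- function(store, name, url = NA_character_) {
  ex <- st_query(store, "SELECT id FROM DataSource WHERE name = ?",
                 list(name))
  if (nrow(ex)) return(ex$id[[1]])
  id <- new_internal_id("datasource", name, deterministic = TRUE)
  st_exec(store, "INSERT INTO DataSource (id, name, url) VALUES (?, ?, ?)",
          list(id, name, url))
  id
}

.na2null <- function(df) {
  # RSQLite binds NA fine; helper retained for clarity of intent
  df
}

.insert_sbase_rows <- function(store, df) {
  if (!nrow(df)) return(invisible())
  for (i in seq_len(nrow(df))) {
    st_exec(store,
            "INSERT INTO Sbase (id, metaId, sboTerm, notes, annotation)
             VALUES (?, ?, ?, ?, ?)",
            list(df$id[i], df$metaId[i], df$sboTerm[i], df$notes[i],
                 df$annotation[i]))
  }
}

#' Persist a model bundle (with its extracted links) into the store
#'
#' Sbase rows are created first; entity rows then reference them, and all
#' foreign keys are satisfied on commit.  Re-ingesting a document with the
#' same (data source, SBML model id) atomically replaces the prior version.
#' The whole bundle is written in one transaction.
#'
#' @param store an `sb_store`.
#' @param bundle an `sbml_bundle` from [parse_sbml_document()].
#' @param links optional link data frame from [extract_bundle_links()]
#'   (extracted from the bundle when `NULL`).
#' @return the persisted model id, invisibly.
#' @export
persist_model_bundle <- function(store, bundle, links = NULL) {
  stopifnot(inherits(store, "sb_store"), inherits(bundle, "sbml_bundle"))
  if (is.null(links)) links <- extract_bundle_links(bundle, quiet = TRUE)
  normalize_unit_definitions(bundle)  # validates unit compositions
  m <- bundle$model
  DBI::dbExecute(store$con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(store$con, "ROLLBACK"))

  prior <- st_query(store,
    "SELECT id FROM Model WHERE dataSourceId = ? AND sbmlId = ?",
    list(m$dataSourceId, m$sbmlId))
  if (nrow(prior)) .delete_model_rows(store, prior$id[[1]])

  .insert_sbase_rows(store, m)
  st_exec(store,
    "INSERT INTO Model (id, sbmlId, name, sbmlLevel, sbmlVersion,
     dataSourceId, sbmlFile) VALUES (?, ?, ?, ?, ?, ?, ?)",
    list(m$id, m$sbmlId, m$name, m$sbmlLevel, m$sbmlVersion,
         m$dataSourceId, m$sbmlFile))

  ins <- function(df, sql, cols) {
    if (is.null(df) || !nrow(df)) return(invisible())
    .insert_sbase_rows(store, df)
    for (i in seq_len(nrow(df))) {
      st_exec(store, sql, unname(as.list(df[i, cols])))
    }
  }

  # user unit definitions before anything that references units
  ins(bundle$unit_definitions,
      "INSERT INTO UnitDefinition (id, modelId, sbmlId, name)
       VALUES (?, ?, ?, ?)",
      c("id", "modelId", "sbmlId", "name"))
  uc <- bundle$unit_compositions
  if (nrow(uc)) {
    for (i in seq_len(nrow(uc))) {
      st_exec(store,
        "INSERT INTO UnitComposition (unitDefinitionId, baseUnitId,
         baseUnitKind, exponent, scale, multiplier)
         VALUES (?, ?, ?, ?, ?, ?)",
        list(uc$unitDefinitionId[i], paste0("base-unit:", uc$baseUnitKind[i]),
             uc$baseUnitKind[i], uc$exponent[i], uc$scale[i],
             uc$multiplier[i]))
    }
  }
  ins(bundle$compartment_types,
      "INSERT INTO CompartmentType (id, modelId, sbmlId, name)
       VALUES (?, ?, ?, ?)", c("id", "modelId", "sbmlId", "name"))
  ins(bundle$species_types,
      "INSERT INTO SpeciesType (id, modelId, sbmlId, name)
       VALUES (?, ?, ?, ?)", c("id", "modelId", "sbmlId", "name"))
  ins(bundle$compartments,
      "INSERT INTO Compartment (id, modelId, sbmlId, name,
       compartmentTypeId, spatialDimensions, size, unitsId, outside,
       constant) VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?, ?)",
      c("id", "modelId", "sbmlId", "name", "compartmentTypeId",
        "spatialDimensions", "size", "unitsId", "outside", "constant"))
  ins(bundle$species,
      "INSERT INTO Species (id, modelId, sbmlId, name, speciesTypeId,
       compartmentId, initialAmount, initialConcentration,
       substanceUnitsId, hasOnlySubstanceUnits, boundaryCondition, charge,
       constant) VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?)",
      c("id", "modelId", "sbmlId", "name", "speciesTypeId", "compartmentId",
        "initialAmount", "initialConcentration", "substanceUnitsId",
        "hasOnlySubstanceUnits", "boundaryCondition", "charge", "constant"))
  ins(bundle$parameters,
      "INSERT INTO Parameter (id, modelId, sbmlId, name, value, unitsId,
       constant) VALUES (?, ?, ?, ?, ?, ?, ?)",
      c("id", "modelId", "sbmlId", "name", "value", "unitsId", "constant"))
  ins(bundle$function_definitions,
      "INSERT INTO FunctionDefinition (id, modelId, sbmlId, name, mathml)
       VALUES (?, ?, ?, ?, ?)",
      c("id", "modelId", "sbmlId", "name", "mathml"))

  # reactions first with NULL kineticLawId (circular reference), then laws,
  # then patch the reaction rows
  rx <- bundle$reactions
  if (nrow(rx)) {
    .insert_sbase_rows(store, rx)
    for (i in seq_len(nrow(rx))) {
      st_exec(store,
        "INSERT INTO Reaction (id, modelId, sbmlId, name, reversible, fast,
         kineticLawId) VALUES (?, ?, ?, ?, ?, ?, NULL)",
        list(rx$id[i], rx$modelId[i], rx$sbmlId[i], rx$name[i],
             rx$reversible[i], rx$fast[i]))
    }
  }
  ins(bundle$kinetic_laws,
      "INSERT INTO KineticLaw (id, reactionId, mathml) VALUES (?, ?, ?)",
      c("id", "reactionId", "mathml"))
  if (nrow(rx)) {
    for (i in seq_len(nrow(rx))) {
      if (!is.na(rx$kineticLawId[i])) {
        st_exec(store, "UPDATE Reaction SET kineticLawId = ? WHERE id = ?",
                list(rx$kineticLawId[i], rx$id[i]))
      }
    }
  }
  ins(bundle$kinetic_law_parameters,
      "INSERT INTO KineticLawParameter (id, kineticLawId, sbmlId, name,
       value, unitsId) VALUES (?, ?, ?, ?, ?, ?)",
      c("id", "kineticLawId", "sbmlId", "name", "value", "unitsId"))

  rs <- bundle$reaction_species
  if (nrow(rs)) {
    .insert_sbase_rows(store, rs)
    for (i in seq_len(nrow(rs))) {
      sm_id <- NA_character_
      if (!is.na(rs$stoichiometryMath[i])) {
        sm_id <- paste0(rs$id[i], ":stoichmath")
        st_exec(store, "INSERT INTO Sbase (id) VALUES (?)", list(sm_id))
        st_exec(store,
          "INSERT INTO StoichiometryMath (id, stoichiometry,
           stoichiometryMath) VALUES (?, ?, ?)",
          list(sm_id, rs$stoichiometry[i], rs$stoichiometryMath[i]))
      }
      st_exec(store,
        "INSERT INTO ReactionSpecies (id, reactionId, speciesId, roleId,
         stoichiometry, stoichiometryMathId, sbmlId, name)
         VALUES (?, ?, ?, ?, ?, ?, ?, ?)",
        list(rs$id[i], rs$reactionId[i], rs$speciesId[i],
             .role_id(store, rs$roleId[i]), rs$stoichiometry[i], sm_id,
             rs$sbmlId[i], rs$name[i]))
    }
  }

  rl <- bundle$rules
  if (nrow(rl)) {
    .insert_sbase_rows(store, rl)
    rt <- dimension_table(store, "RuleType")
    for (i in seq_len(nrow(rl))) {
      st_exec(store,
        "INSERT INTO Rule (id, modelId, ruleTypeId, variable, mathml)
         VALUES (?, ?, ?, ?, ?)",
        list(rl$id[i], rl$modelId[i], rt$id[rt$name == rl$ruleType[i]][[1]],
             rl$variable[i], rl$mathml[i]))
    }
  }
  ins(bundle$constraints,
      'INSERT INTO "Constraint" (id, modelId, mathml, message)
       VALUES (?, ?, ?, ?)', c("id", "modelId", "mathml", "message"))
  ins(bundle$initial_assignments,
      "INSERT INTO InitialAssignment (id, modelId, symbol, mathml)
       VALUES (?, ?, ?, ?)", c("id", "modelId", "symbol", "mathml"))
  ins(bundle$events,
      "INSERT INTO Event (id, modelId, sbmlId, name) VALUES (?, ?, ?, ?)",
      c("id", "modelId", "sbmlId", "name"))
  ins(bundle$event_triggers,
      "INSERT INTO EventTrigger (id, eventId, mathml) VALUES (?, ?, ?)",
      c("id", "eventId", "mathml"))
  ins(bundle$event_delays,
      "INSERT INTO EventDelay (id, eventId, mathml) VALUES (?, ?, ?)",
      c("id", "eventId", "mathml"))
  ins(bundle$event_assignments,
      "INSERT INTO EventAssignment (id, eventId, variable, mathml)
       VALUES (?, ?, ?, ?)", c("id", "eventId", "variable", "mathml"))

  # math-expression arguments with resolved function references
  expr_owners <- rbind(
    if (nrow(bundle$kinetic_laws))
      bundle$kinetic_laws[c("id", "mathml")],
    if (nrow(bundle$rules)) bundle$rules[c("id", "mathml")],
    if (nrow(bundle$event_triggers))
      bundle$event_triggers[c("id", "mathml")],
    if (nrow(bundle$initial_assignments))
      bundle$initial_assignments[c("id", "mathml")]
  )
  if (!is.null(expr_owners) && nrow(expr_owners)) {
    for (i in seq_len(nrow(expr_owners))) {
      args <- resolve_function_references(expr_owners$mathml[i], bundle)
      for (j in seq_len(nrow(args))) {
        st_exec(store,
          "INSERT INTO MathExpressionArgument (ownerId, symbol, kind,
           functionId) VALUES (?, ?, ?, ?)",
          list(expr_owners$id[i], args$symbol[j], args$kind[j],
               args$functionId[j]))
      }
    }
  }

  if (!is.null(links) && nrow(links)) {
    for (i in seq_len(nrow(links))) {
      st_exec(store,
        "INSERT OR IGNORE INTO annotation_links (sbaseId, subjectKind,
         modelId, qualifier, family, namespace, externalId, rawUrn)
         VALUES (?, ?, ?, ?, ?, ?, ?, ?)",
        list(links$sbaseId[i], links$subjectKind[i], links$modelId[i],
             links$qualifier[i], links$family[i], links$namespace[i],
             links$externalId[i], links$rawUrn[i]))
    }
  }

  DBI::dbExecute(store$con, "COMMIT")
  ok <- TRUE
  invisible(m$id)
}

# Collect the Sbase ids owned by a model and delete them; cascades wipe all
# dependent rows (entity, mapping and annotation tables alike).
.delete_model_rows <- function(store, model_id) {
  owned <- character()
  direct <- c("Compartment", "Species", "Reaction", "Parameter",
              "FunctionDefinition", "Rule", "\"Constraint\"",
              "InitialAssignment", "Event", "SpeciesType", "CompartmentType",
              "UnitDefinition")
  for (tab in direct) {
    owned <- c(owned, st_query(store, paste0(
      "SELECT id FROM ", tab, " WHERE modelId = ?"), list(model_id))$id)
  }
  owned <- c(owned, st_query(store,
    "SELECT rs.id FROM ReactionSpecies rs
     JOIN Reaction r ON rs.reactionId = r.id WHERE r.modelId = ?",
    list(model_id))$id)
  owned <- c(owned, st_query(store,
    "SELECT rs.stoichiometryMathId AS id FROM ReactionSpecies rs
     JOIN Reaction r ON rs.reactionId = r.id
     WHERE r.modelId = ? AND rs.stoichiometryMathId IS NOT NULL",
    list(model_id))$id)
  owned <- c(owned, st_query(store,
    "SELECT kl.id FROM KineticLaw kl
     JOIN Reaction r ON kl.reactionId = r.id WHERE r.modelId = ?",
    list(model_id))$id)
  owned <- c(owned, st_query(store,
    "SELECT klp.id FROM KineticLawParameter klp
     JOIN KineticLaw kl ON klp.kineticLawId = kl.id
     JOIN Reaction r ON kl.reactionId = r.id WHERE r.modelId = ?",
    list(model_id))$id)
  for (tab in c("EventTrigger", "EventDelay", "EventAssignment")) {
    owned <- c(owned, st_query(store, paste0(
      "SELECT t.id FROM ", tab, " t JOIN Event e ON t.eventId = e.id
       WHERE e.modelId = ?"), list(model_id))$id)
  }
  owned <- c(owned, model_id)
  for (id in unique(owned)) {
    st_exec(store, "DELETE FROM Sbase WHERE id = ?", list(id))
  }
  invisible(length(unique(owned)))
}

.model_side_tables <- c(
  "Sbase", "Model", "ModelLayout", "ModelMetadata", "Compartment", "Species",
  "Reaction", "ReactionSpecies", "StoichiometryMath", "KineticLaw",
  "KineticLawParameter", "Parameter", "FunctionDefinition", "Rule",
  "\"Constraint\"", "InitialAssignment", "Event", "EventTrigger",
  "EventDelay", "EventAssignment", "SpeciesType", "CompartmentType",
  "UnitComposition", "MathExpressionArgument", "annotation_links",
  "MapSpeciesMolecularEntities", "MapReactionsProcessEntities",
  "MapModelsPathways", "ModelOrganism", "MapSbaseGO", "MapReactionECNumber"
)

#' Delete a model and everything that depends on it
#'
#' Removes the model row and, by cascade, every dependent row: species,
#' reactions and participants, kinetic laws, events, rules, unit
#' definitions, extracted links, and all mapping/annotation rows pointing
#' at the model's records.  Pathway-side rows are untouched.
#'
#' @param store an `sb_store`.
#' @param model_id internal model id.
#' @return the number of rows removed across model-side tables.
#' @export
delete_model <- function(store, model_id) {
  stopifnot(inherits(store, "sb_store"))
  ex <- st_query(store, "SELECT id FROM Model WHERE id = ?", list(model_id))
  if (!nrow(ex)) stop("lookup error: unknown model id '", model_id, "'",
                      call. = FALSE)
  count_all <- function() sum(vapply(
    .model_side_tables,
    function(t) as.integer(
      st_query(store, paste0("SELECT COUNT(*) AS n FROM ", t))$n),
    integer(1)))
  before <- count_all()
  DBI::dbExecute(store$con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(store$con, "ROLLBACK"))
  .delete_model_rows(store, model_id)
  DBI::dbExecute(store$con, "COMMIT")
  ok <- TRUE
  before - count_all()
}

#' Sweep the whole store for orphaned foreign keys
#'
#' @param store an `sb_store`.
#' @return data frame of violations (zero rows when the store is clean).
#' @export
store_orphan_check <- function(store) {
  stopifnot(inherits(store, "sb_store"))
  st_query(store, "PRAGMA foreign_key_check")
}

#' Persist a pathway store into the relational store
#'
#' Loads molecular entities, processes (with EC numbers and participants),
#' pathways, organism groups, GO terms (with is-a edges) and external-id
#' rows into their tables.
#'
#' @param store an `sb_store`.
#' @param pstore a `pathway_store` from [load_pathway_source()].
#' @return invisible `NULL`.
#' @export
persist_pathway_store <- function(store, pstore) {
  stopifnot(inherits(store, "sb_store"), inherits(pstore, "pathway_store"))
  types <- dimension_table(store, "MolecularEntityType")
  DBI::dbExecute(store$con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(store$con, "ROLLBACK"))
  me <- pstore$molecular_entities
  for (i in seq_len(nrow(me))) {
    tid <- types$id[types$name == me$type[i]]
    st_exec(store,
      "INSERT INTO molecular_entities (id, name, typeId) VALUES (?, ?, ?)",
      list(me$id[i], me$name[i],
           if (length(tid)) tid[[1]] else NA_integer_))
  }
  for (i in seq_len(nrow(pstore$processes))) {
    st_exec(store, "INSERT INTO processes (id, name) VALUES (?, ?)",
            list(pstore$processes$id[i], pstore$processes$name[i]))
  }
  for (i in seq_len(nrow(pstore$ec_numbers))) {
    st_exec(store,
      "INSERT OR IGNORE INTO ec_numbers (ec_number, name) VALUES (?, ?)",
      list(pstore$ec_numbers$ec_number[i], pstore$ec_numbers$name[i]))
  }
  for (i in seq_len(nrow(pstore$process_ec))) {
    st_exec(store,
      "INSERT OR IGNORE INTO ec_numbers (ec_number) VALUES (?)",
      list(pstore$process_ec$ecNumber[i]))
    st_exec(store,
      "INSERT OR IGNORE INTO process_ec_numbers (processId, ecNumber)
       VALUES (?, ?)",
      list(pstore$process_ec$processId[i], pstore$process_ec$ecNumber[i]))
  }
  proles <- dimension_table(store, "ProcessEntityRole")
  pp <- pstore$process_participants
  for (i in seq_len(nrow(pp))) {
    rid <- proles$id[proles$name == pp$role[i]]
    if (!length(rid)) {
      st_exec(store, "INSERT INTO ProcessEntityRole (name) VALUES (?)",
              list(pp$role[i]))
      proles <- dimension_table(store, "ProcessEntityRole")
      rid <- proles$id[proles$name == pp$role[i]]
    }
    st_exec(store,
      "INSERT INTO process_participants (processId, molecularEntityId,
       roleId) VALUES (?, ?, ?)",
      list(pp$processId[i], pp$molecularEntityId[i], rid[[1]]))
  }
  for (i in seq_len(nrow(pstore$organism_groups))) {
    st_exec(store, "INSERT INTO organism_groups (id, name) VALUES (?, ?)",
            list(pstore$organism_groups$id[i],
                 pstore$organism_groups$name[i]))
  }
  gt <- pstore$organism_group_taxa
  for (i in seq_len(nrow(gt))) {
    st_exec(store,
      "INSERT OR IGNORE INTO organism_group_taxa (organismGroupId,
       ncbiTaxonomyId) VALUES (?, ?)",
      list(gt$organismGroupId[i], as.integer(gt$ncbiTaxonomyId[i])))
  }
  for (i in seq_len(nrow(pstore$pathways))) {
    st_exec(store,
      "INSERT INTO pathways (id, name, organismGroupId) VALUES (?, ?, ?)",
      list(pstore$pathways$id[i], pstore$pathways$name[i],
           pstore$pathways$organismGroupId[i]))
  }
  for (i in seq_len(nrow(pstore$pathway_processes))) {
    st_exec(store,
      "INSERT OR IGNORE INTO pathway_processes (pathwayId, processId)
       VALUES (?, ?)",
      list(pstore$pathway_processes$pathwayId[i],
           pstore$pathway_processes$processId[i]))
  }
  for (i in seq_len(nrow(pstore$go_terms))) {
    st_exec(store, "INSERT INTO go_terms (goId, name) VALUES (?, ?)",
            list(pstore$go_terms$goId[i], pstore$go_terms$name[i]))
  }
  for (i in seq_len(nrow(pstore$go_parents))) {
    st_exec(store,
      "INSERT OR IGNORE INTO go_term_parents (goId, parentId)
       VALUES (?, ?)",
      list(pstore$go_parents$goId[i], pstore$go_parents$parentId[i]))
  }
  x <- pstore$xrefs
  for (i in seq_len(nrow(x))) {
    st_exec(store,
      "INSERT OR IGNORE INTO entity_xrefs (kind, entityId, namespace,
       externalId) VALUES (?, ?, ?, ?)",
      list(x$kind[i], x$entityId[i], x$namespace[i], x$externalId[i]))
  }
  DBI::dbExecute(store$con, "COMMIT")
  ok <- TRUE
  invisible(NULL)
}

#' Persist a NodeCodes labeling of the GO graph
#'
#' Writes one (goId, nodeCode) row per code into the precomputed-codes
#' table; prior codes are replaced.
#'
#' @param store an `sb_store`.
#' @param lab a `nodecodes_labeling` over GO term ids.
#' @return number of code rows written, invisibly.
#' @export
persist_go_nodecodes <- function(store, lab) {
  stopifnot(inherits(store, "sb_store"),
            inherits(lab, "nodecodes_labeling"))
  DBI::dbExecute(store$con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(store$con, "ROLLBACK"))
  st_exec(store, "DELETE FROM GONodeCodes")
  for (i in seq_along(lab$all_codes)) {
    st_exec(store,
      "INSERT OR IGNORE INTO GONodeCodes (goId, nodeCode) VALUES (?, ?)",
      list(lab$all_nodes[i], lab$all_codes[i]))
  }
  DBI::dbExecute(store$con, "COMMIT")
  ok <- TRUE
  invisible(length(lab$all_codes))
}
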