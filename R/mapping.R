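# Cross-source mapping construction: turns extracted annotation links plus
# the pathway cross-reference index into the three mapping tables and three
# annotation tables.  Mapping never creates entities on either side — a
# link with no match produces no row and is merely counted.

#' Build the three entity mapping tables
#'
#' Species links in the `kegg.compound` (primarily) and `obo.chebi`
#' (secondarily) namespaces are matched against indexed molecular entities;
#' reaction links in `kegg.reaction` against process entities; model links
#' in `kegg.pathway` against pathways (copying the pathway's organism group
#' when present).  One-to-many fan-out is allowed in both directions;
#' duplicate rows collapse on the full (entity, target, qualifier) key;
#' the qualifier of every produced row equals the qualifier of the link
#' that produced it.  Reactome (and other unmapped-namespace) links are
#' retained as annotation links but produce no mapping rows.
#'
#' @param store an `sb_store` with models and the pathway side persisted.
#' @param links data frame of links (as stored by
#'   [persist_model_bundle()]); defaults to all links in the store.
#' @param index a `crossref_index`; defaults to one built from the store's
#'   `entity_xrefs` rows.
#' @return named list of counts: `species_molecular_entities`,
#'   `reactions_processes`, `models_pathways`, `unmatched`.
#' @export
build_entity_mappings <- function(store, links = NULL, index = NULL) {
  stopifnot(inherits(store, "sb_store"))
  if (is.null(links)) {
    links <- st_query(store, "SELECT * FROM annotation_links")
  }
  if (is.null(index)) {
    x <- st_query(store, "SELECT * FROM entity_xrefs")
    index <- structure(list(table = x,
                            key = paste(x$namespace, x$externalId,
                                        sep = "\r")),
                       class = "crossref_index")
  }
  counts <- c(species_molecular_entities = 0L, reactions_processes = 0L,
              models_pathways = 0L, unmatched = 0L)
  if (!nrow(links)) return(as.list(counts))

  add_unmatched <- function(k = 1L) counts["unmatched"] <<-
    counts[["unmatched"]] + k

  sp <- links[links$subjectKind == "species" &
              links$namespace %in% c("kegg.compound", "obo.chebi"), ,
              drop = FALSE]
  for (i in seq_len(nrow(sp))) {
    hits <- xref_lookup(index, sp$namespace[i], sp$externalId[i],
                        kind = "molecular_entity")
    if (!nrow(hits)) { add_unmatched(); next }
    qid <- .qualifier_id(store, sp$qualifier[i])
    for (ent in hits$entityId) {
      n <- st_exec(store,
        "INSERT OR IGNORE INTO MapSpeciesMolecularEntities
         (speciesId, molecularEntityId, qualifierId) VALUES (?, ?, ?)",
        list(sp$sbaseId[i], ent, qid))
      counts["species_molecular_entities"] <-
        counts[["species_molecular_entities"]] + n
    }
  }

  rx <- links[links$subjectKind == "reaction" &
              links$namespace == "kegg.reaction", , drop = FALSE]
  for (i in seq_len(nrow(rx))) {
    hits <- xref_lookup(index, rx$namespace[i], rx$externalId[i],
                        kind = "process")
    if (!nrow(hits)) { add_unmatched(); next }
    qid <- .qualifier_id(store, rx$qualifier[i])
    for (ent in hits$entityId) {
      n <- st_exec(store,
        "INSERT OR IGNORE INTO MapReactionsProcessEntities
         (reactionId, processId, qualifierId) VALUES (?, ?, ?)",
        list(rx$sbaseId[i], ent, qid))
      counts["reactions_processes"] <- counts[["reactions_processes"]] + n
    }
  }

  mp <- links[links$subjectKind == "model" &
              links$namespace == "kegg.pathway", , drop = FALSE]
  for (i in seq_len(nrow(mp))) {
    hits <- xref_lookup(index, mp$namespace[i], mp$externalId[i],
                        kind = "pathway")
    if (!nrow(hits)) { add_unmatched(); next }
    qid <- .qualifier_id(store, mp$qualifier[i])
    for (ent in hits$entityId) {
      og <- st_query(store,
        "SELECT organismGroupId FROM pathways WHERE id = ?",
        list(ent))$organismGroupId
      n <- st_exec(store,
        "INSERT OR IGNORE INTO MapModelsPathways
         (modelId, pathwayId, qualifierId, organismGroupId)
         VALUES (?, ?, ?, ?)",
        list(mp$sbaseId[i], ent, qid,
             if (length(og)) og[[1]] else NA_character_))
      counts["models_pathways"] <- counts[["models_pathways"]] + n
    }
  }
  as.list(counts)
}

#' Build the three annotation tables
#'
#' Taxonomy links on models become organism annotations (the organism group
#' is resolved through the pathway store when the taxon belongs to one);
#' GO links on any record become GO annotations, skipped with a message
#' when the GO id is not in the loaded term table (referential integrity is
#' kept, never broken); EC links on reactions become EC-number annotations
#' under the same skip rule.  Qualifiers are preserved on every row.
#'
#' @inheritParams build_entity_mappings
#' @param quiet suppress messages about skipped rows.
#' @return named list of counts: `model_organism`, `sbase_go`,
#'   `reaction_ec`, `skipped`.
#' @export
build_annotation_tables <- function(store, links = NULL, quiet = FALSE) {
  stopifnot(inherits(store, "sb_store"))
  if (is.null(links)) {
    links <- st_query(store, "SELECT * FROM annotation_links")
  }
  counts <- c(model_organism = 0L, sbase_go = 0L, reaction_ec = 0L,
              skipped = 0L)
  if (!nrow(links)) return(as.list(counts))

  tx <- links[links$subjectKind == "model" & links$namespace == "taxonomy", ,
              drop = FALSE]
  for (i in seq_len(nrow(tx))) {
    taxon <- suppressWarnings(as.integer(tx$externalId[i]))
    if (is.na(taxon)) { counts["skipped"] <- counts[["skipped"]] + 1L; next }
    og <- st_query(store,
      "SELECT organismGroupId FROM organism_group_taxa
       WHERE ncbiTaxonomyId = ?", list(taxon))$organismGroupId
    n <- st_exec(store,
      "INSERT OR IGNORE INTO ModelOrganism
       (modelId, organismGroupId, NCBITaxonomyId, qualifierId)
       VALUES (?, ?, ?, ?)",
      list(tx$sbaseId[i], if (length(og)) og[[1]] else NA_character_,
           taxon, .qualifier_id(store, tx$qualifier[i])))
    counts["model_organism"] <- counts[["model_organism"]] + n
  }

  go <- links[links$namespace == "obo.go", , drop = FALSE]
  for (i in seq_len(nrow(go))) {
    known <- nrow(st_query(store,
      "SELECT goId FROM go_terms WHERE goId = ?", list(go$externalId[i])))
    if (!known) {
      if (!quiet) message("skipping GO annotation to unknown term ",
                          go$externalId[i])
      counts["skipped"] <- counts[["skipped"]] + 1L
      next
    }
    n <- st_exec(store,
      "INSERT OR IGNORE INTO MapSbaseGO (sbaseId, goId, qualifierId)
       VALUES (?, ?, ?)",
      list(go$sbaseId[i], go$externalId[i],
           .qualifier_id(store, go$qualifier[i])))
    counts["sbase_go"] <- counts[["sbase_go"]] + n
  }

  ec <- links[links$subjectKind == "reaction" &
              links$namespace == "ec-code", , drop = FALSE]
  for (i in seq_len(nrow(ec))) {
    known <- nrow(st_query(store,
      "SELECT ec_number FROM ec_numbers WHERE ec_number = ?",
      list(ec$externalId[i])))
    if (!known) {
      if (!quiet) message("skipping EC annotation to unknown number ",
                          ec$externalId[i])
      counts["skipped"] <- counts[["skipped"]] + 1L
      next
    }
    n <- st_exec(store,
      "INSERT OR IGNORE INTO MapReactionECNumber
       (reactionId, ecNumber, qualifierId) VALUES (?, ?, ?)",
      list(ec$sbaseId[i], ec$externalId[i],
           .qualifier_id(store, ec$qualifier[i])))
    counts["reaction_ec"] <- counts[["reaction_ec"]] + n
  }
  as.list(counts)
}

#' Summarise the mapping results of a store
#'
#' Distinct-count summary of the integrated content: how many models carry
#' pathway references or GO annotations, how many reactions and species
#' are mapped, and how many pathway-side entities are hit.
#'
#' @param store an `sb_store`.
#' @return named list of counts.
#' @export
summarize_mappings <- function(store) {
  stopifnot(inherits(store, "sb_store"))
  one <- function(sql) as.integer(st_query(store, sql)[[1]])
  list(
    models_total = one("SELECT COUNT(*) FROM Model"),
    models_with_pathway_map = one(
      "SELECT COUNT(DISTINCT modelId) FROM MapModelsPathways"),
    models_with_go_annotation = one(
      "SELECT COUNT(DISTINCT modelId) FROM annotation_links
       WHERE namespace = 'obo.go'"),
    reactions_total = one("SELECT COUNT(*) FROM Reaction"),
    reactions_mapped = one(
      "SELECT COUNT(DISTINCT reactionId) FROM MapReactionsProcessEntities"),
    species_total = one("SELECT COUNT(*) FROM Species"),
    species_mapped = one(
      "SELECT COUNT(DISTINCT speciesId) FROM MapSpeciesMolecularEntities"),
    distinct_pathways_hit = one(
      "SELECT COUNT(DISTINCT pathwayId) FROM MapModelsPathways"),
    distinct_processes_hit = one(
      "SELECT COUNT(DISTINCT processId) FROM MapReactionsProcessEntities"),
    distinct_molecular_entities_hit = one(
      "SELECT COUNT(DISTINCT molecularEntityId)
       FROM MapSpeciesMolecularEntities")
  )
}

#' Export a mapping table as TSV
#'
#' @param store an `sb_store`.
#' @param table one of the mapping/annotation table names.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_mapping_tsv <- function(store, table, path) {
  stopifnot(table %in% c("MapSpeciesMolecularEntities",
                         "MapReactionsProcessEntities", "MapModelsPathways",
                         "ModelOrganism", "MapSbaseGO",
                         "MapReactionECNumber"))
  df <- st_query(store, paste0("SELECT * FROM ", table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
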