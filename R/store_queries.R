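# The four built-in queries plus GO-term browsing.  Query 3 resolves
# participant-role names through the cached ReactionSpeciesRole dimension
# table (an in-memory join); with the cache disabled the same join runs in
# the store, and results are identical either way.

.check_pathway <- function(store, pathway_id) {
  if (!nrow(st_query(store, "SELECT id FROM pathways WHERE id = ?",
                     list(pathway_id)))) {
    stop("lookup error: unknown pathway '", pathway_id, "'", call. = FALSE)
  }
}

.check_process <- function(store, process_id) {
  if (!nrow(st_query(store, "SELECT id FROM processes WHERE id = ?",
                     list(process_id)))) {
    stop("lookup error: unknown process '", process_id, "'", call. = FALSE)
  }
}

#' Find models that contain reactions of a given pathway
#'
#' One row per participant of each model reaction mapped to a process of
#' the pathway; the `speciesRole` column (the "Species Name (Reaction
#' Role)" view) joins participants to the role dimension, in memory when
#' the cache is enabled.
#'
#' @param store an `sb_store`.
#' @param pathway_id pathway id.
#' @return data frame (modelId, modelSbmlId, reactionId, reactionSbmlId,
#'   processId, speciesName, roleName).
#' @export
query_models_with_pathway_reactions <- function(store, pathway_id) {
  stopifnot(inherits(store, "sb_store"))
  .check_pathway(store, pathway_id)
  base <- st_query(store,
    "SELECT m.id AS modelId, m.sbmlId AS modelSbmlId,
            r.id AS reactionId, r.sbmlId AS reactionSbmlId,
            mp.processId AS processId,
            COALESCE(s.name, s.sbmlId) AS speciesName,
            rs.roleId AS roleId
     FROM pathway_processes pp
     JOIN MapReactionsProcessEntities mp ON mp.processId = pp.processId
     JOIN Reaction r ON r.id = mp.reactionId
     JOIN Model m ON m.id = r.modelId
     JOIN ReactionSpecies rs ON rs.reactionId = r.id
     JOIN Species s ON s.id = rs.speciesId
     WHERE pp.pathwayId = ?
     ORDER BY m.sbmlId, r.sbmlId, rs.id", list(pathway_id))
  roles <- dimension_table(store, "ReactionSpeciesRole")
  base$roleName <- roles$name[match(base$roleId, roles$id)]
  base$roleId <- NULL
  base
}

#' Find models that contain metabolites of a given pathway
#'
#' Models with at least one species mapped to a molecular entity that
#' participates in one of the pathway's processes.
#'
#' @param store an `sb_store`.
#' @param pathway_id pathway id.
#' @return character vector of model ids.
#' @export
query_models_with_pathway_metabolites <- function(store, pathway_id) {
  stopifnot(inherits(store, "sb_store"))
  .check_pathway(store, pathway_id)
  sort(st_query(store,
    "SELECT DISTINCT s.modelId AS modelId
     FROM pathway_processes pp
     JOIN process_participants pa ON pa.processId = pp.processId
     JOIN MapSpeciesMolecularEntities ms
       ON ms.molecularEntityId = pa.molecularEntityId
     JOIN Species s ON s.id = ms.speciesId
     WHERE pp.pathwayId = ?", list(pathway_id))$modelId)
}

#' Find models containing different expressions of metabolic flux for the
#' same process
#'
#' Among reactions mapped to the process, kinetic laws are grouped by
#' canonicalized MathML; rows are returned only when at least two distinct
#' expressions exist (one shared rate law is not "different expressions").
#'
#' @param store an `sb_store`.
#' @param process_id process id.
#' @return data frame (modelId, modelSbmlId, reactionId, reactionSbmlId,
#'   mathml), zero rows unless >= 2 distinct expressions.
#' @export
query_flux_expressions_for_process <- function(store, process_id) {
  stopifnot(inherits(store, "sb_store"))
  .check_process(store, process_id)
  rows <- st_query(store,
    "SELECT m.id AS modelId, m.sbmlId AS modelSbmlId,
            r.id AS reactionId, r.sbmlId AS reactionSbmlId,
            kl.mathml AS mathml
     FROM MapReactionsProcessEntities mp
     JOIN Reaction r ON r.id = mp.reactionId
     JOIN Model m ON m.id = r.modelId
     JOIN KineticLaw kl ON kl.reactionId = r.id
     WHERE mp.processId = ?
     ORDER BY m.sbmlId, r.sbmlId", list(process_id))
  if (!nrow(rows)) return(rows)
  rows$mathml <- vapply(rows$mathml, canonicalize_mathml, character(1),
                        USE.NAMES = FALSE)
  if (length(unique(rows$mathml[!is.na(rows$mathml)])) < 2L) {
    return(rows[0, , drop = FALSE])
  }
  rows
}

#' Find kinetic models for a given reaction (process) in a given pathway
#'
#' Reactions mapped to the process, restricted to processes of the pathway,
#' and carrying a kinetic law.  A process not belonging to the pathway
#' yields an empty result (not an error).
#'
#' @param store an `sb_store`.
#' @param pathway_id pathway id.
#' @param process_id process id.
#' @return data frame (modelId, modelSbmlId, reactionId, reactionSbmlId,
#'   kineticLawId, mathml).
#' @export
query_kinetic_models_for_process <- function(store, pathway_id, process_id) {
  stopifnot(inherits(store, "sb_store"))
  .check_pathway(store, pathway_id)
  .check_process(store, process_id)
  st_query(store,
    "SELECT m.id AS modelId, m.sbmlId AS modelSbmlId,
            r.id AS reactionId, r.sbmlId AS reactionSbmlId,
            kl.id AS kineticLawId, kl.mathml AS mathml
     FROM pathway_processes pp
     JOIN MapReactionsProcessEntities mp ON mp.processId = pp.processId
     JOIN Reaction r ON r.id = mp.reactionId
     JOIN Model m ON m.id = r.modelId
     JOIN KineticLaw kl ON kl.reactionId = r.id
     WHERE pp.pathwayId = ? AND mp.processId = ?
     ORDER BY m.sbmlId, r.sbmlId", list(pathway_id, process_id))
}

# map Sbase ids of GO-annotated records back to their owning model
.sbase_owner_models <- function(store, sbase_ids) {
  if (!length(sbase_ids)) return(character())
  ph <- paste(rep("?", length(sbase_ids)), collapse = ", ")
  unique(st_query(store, sprintf(
    "SELECT id AS modelId FROM Model WHERE id IN (%s)
     UNION SELECT modelId FROM Species WHERE id IN (%s)
     UNION SELECT modelId FROM Reaction WHERE id IN (%s)
     UNION SELECT modelId FROM Compartment WHERE id IN (%s)
     UNION SELECT modelId FROM Parameter WHERE id IN (%s)
     UNION SELECT modelId FROM Event WHERE id IN (%s)",
    ph, ph, ph, ph, ph, ph),
    as.list(rep(sbase_ids, 6)))$modelId)
}

#' Browse models by GO term
#'
#' Takes a GO term, obtains all of its descendants from the NodeCodes
#' labeling (no graph traversal), and returns every model whose records
#' carry a GO annotation to the term itself or any descendant.
#'
#' @param store an `sb_store` with the GO annotation table populated.
#' @param go_id GO term id (e.g. `"GO:0006096"`).
#' @param labeling a `nodecodes_labeling` over the store's GO graph.
#' @return sorted character vector of model ids.
#' @export
browse_models_by_go_term <- function(store, go_id, labeling) {
  stopifnot(inherits(store, "sb_store"),
            inherits(labeling, "nodecodes_labeling"))
  if (!nrow(st_query(store, "SELECT goId FROM go_terms WHERE goId = ?",
                     list(go_id)))) {
    stop("lookup error: unknown GO id '", go_id, "'", call. = FALSE)
  }
  terms <- c(go_id, descendants_labeled(labeling, go_id))
  ph <- paste(rep("?", length(terms)), collapse = ", ")
  hits <- st_query(store, sprintf(
    "SELECT DISTINCT sbaseId FROM MapSbaseGO WHERE goId IN (%s)", ph),
    as.list(terms))$sbaseId
  sort(.sbase_owner_models(store, hits))
}
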