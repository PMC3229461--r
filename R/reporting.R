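# Coverage and growth reporting over the integrated store.

#' External-link coverage report
#'
#' One row per model: whether the model element carries KEGG-pathway,
#' taxonomy and GO links, and how its reactions and species split into
#' with/without KEGG link (a reaction counts as "with KEGG" iff it carries
#' at least one `kegg.reaction` link; a species iff at least one
#' `kegg.compound` link).  The with/without columns always partition the
#' totals.
#'
#' @param store an `sb_store`.
#' @param model_ids models to report on (default: all).
#' @param bp_terms optional character vector of GO ids counted as
#'   biological-process terms; when supplied, the GO-link flag is
#'   restricted to them (without a loaded GO graph the subontology of an
#'   id is not derivable, so the default counts any GO link).
#' @return data frame with columns `modelId`, `modelName`,
#'   `hasKeggPathwayLink`, `hasTaxonomyLink`, `hasGoLink`, `nReactions`,
#'   `nReactionsWithKegg`, `nReactionsWithoutKegg`, `nSpecies`,
#'   `nSpeciesWithKegg`, `nSpeciesWithoutKegg`.
#' @export
external_link_report <- function(store, model_ids = NULL, bp_terms = NULL) {
  stopifnot(inherits(store, "sb_store"))
  models <- st_query(store,
    "SELECT id, sbmlId, name FROM Model ORDER BY sbmlId")
  if (!is.null(model_ids)) {
    missing <- setdiff(model_ids, models$id)
    if (length(missing)) {
      stop("lookup error: unknown model id '", missing[1], "'",
           call. = FALSE)
    }
    models <- models[models$id %in% model_ids, , drop = FALSE]
  }
  links <- st_query(store, "SELECT * FROM annotation_links")
  rows <- lapply(seq_len(nrow(models)), function(i) {
    mid <- models$id[i]
    ml <- links[links$modelId == mid, , drop = FALSE]
    model_level <- ml[ml$subjectKind == "model", , drop = FALSE]
    go_hit <- model_level$namespace == "obo.go"
    if (!is.null(bp_terms)) {
      go_hit <- go_hit & model_level$externalId %in% bp_terms
    }
    rx <- st_query(store, "SELECT id FROM Reaction WHERE modelId = ?",
                   list(mid))$id
    rx_with <- unique(ml$sbaseId[ml$subjectKind == "reaction" &
                                 ml$namespace == "kegg.reaction"])
    sp <- st_query(store, "SELECT id FROM Species WHERE modelId = ?",
                   list(mid))$id
    sp_with <- unique(ml$sbaseId[ml$subjectKind == "species" &
                                 ml$namespace == "kegg.compound"])
    data.frame(
      modelId = mid,
      modelName = models$sbmlId[i],
      hasKeggPathwayLink = any(model_level$namespace == "kegg.pathway"),
      hasTaxonomyLink = any(model_level$namespace == "taxonomy"),
      hasGoLink = any(go_hit),
      nReactions = length(rx),
      nReactionsWithKegg = sum(rx %in% rx_with),
      nReactionsWithoutKegg = sum(!(rx %in% rx_with)),
      nSpecies = length(sp),
      nSpeciesWithKegg = sum(sp %in% sp_with),
      nSpeciesWithoutKegg = sum(!(sp %in% sp_with)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(modelId = character(), modelName = character(),
                      hasKeggPathwayLink = logical(),
                      hasTaxonomyLink = logical(), hasGoLink = logical(),
                      nReactions = integer(), nReactionsWithKegg = integer(),
                      nReactionsWithoutKegg = integer(),
                      nSpecies = integer(), nSpeciesWithKegg = integer(),
                      nSpeciesWithoutKegg = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Growth statistics between two database snapshots
#'
#' For each item type present in both snapshots, the percentage increase is
#' computed exactly as `100 * (new - old) / old` and reported at full
#' double precision (at least eight significant decimals when printed).
#'
#' @param old_counts named numeric vector (or list) of counts in the older
#'   snapshot; every count must be positive.
#' @param new_counts named numeric vector (or list) of counts in the newer
#'   snapshot; must cover the same item types.
#' @return data frame (itemType, oldCount, newCount, pctIncrease).
#' @export
#' @examples
#' growth_stats(c(Models = 209), c(Models = 252))
growth_stats <- function(old_counts, new_counts) {
  old_counts <- unlist(old_counts)
  new_counts <- unlist(new_counts)
  if (is.null(names(old_counts)) || is.null(names(new_counts))) {
    stop("validation error: counts must be named by item type",
         call. = FALSE)
  }
  missing <- setdiff(names(old_counts), names(new_counts))
  if (length(missing)) {
    stop("validation error: item type(s) missing from new counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(old_counts <= 0)) {
    stop("validation error: old counts must be positive", call. = FALSE)
  }
  new_counts <- new_counts[names(old_counts)]
  data.frame(
    itemType = names(old_counts),
    oldCount = as.numeric(old_counts),
    newCount = as.numeric(new_counts),
    pctIncrease = 100 * (as.numeric(new_counts) - as.numeric(old_counts)) /
      as.numeric(old_counts),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a report as TSV or JSON
#'
#' @param report a data frame (coverage or growth report).
#' @param path output file; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
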