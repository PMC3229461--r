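# Pathway-side (KEGG-like) store: molecular entities, process entities and
# pathways with external-identifier indices, loaded from a TSV dialect, plus
# GO terms (TSV or minimal OBO) and the EC-number hierarchy.

.split_xrefs <- function(s) {
  # external ids are serialized "namespace:id" and semicolon-separated
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(namespace = character(), externalId = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  pos <- regexpr(":", parts, fixed = TRUE)
  bad <- pos < 1L
  if (any(bad)) {
    stop("malformed external id (expected 'namespace:id'): ",
         parts[bad][1], call. = FALSE)
  }
  data.frame(namespace = tolower(substr(parts, 1L, pos - 1L)),
             externalId = substr(parts, pos + 1L, nchar(parts)),
             stringsAsFactors = FALSE)
}

.read_tsv <- function(dir, file, required = FALSE) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    if (required) stop("missing pathway-source file: ", file, call. = FALSE)
    return(NULL)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character())
}

#' Load a pathway source from its TSV dialect
#'
#' The dialect is a directory of header-rowed TSV tables:
#' `molecular_entities.tsv` (id, name, type, external_ids),
#' `processes.tsv` (id, name, ec_numbers, external_ids),
#' `process_participants.tsv` (process_id, molecular_entity_id, role),
#' `pathways.tsv` (id, name, organism_group_id, external_ids),
#' `pathway_processes.tsv` (pathway_id, process_id),
#' `organism_groups.tsv` (id, name, ncbi_taxonomy_ids),
#' `go_terms.tsv` (go_id, name, parent_ids) and
#' `ec_numbers.tsv` (ec_number, name).  External ids are serialized
#' `namespace:id`, semicolon-separated; so are EC numbers, taxonomy ids and
#' GO parents.  Missing files load as empty tables; referential integrity
#' between the tables is enforced.
#'
#' @param dir directory containing the TSV files.
#' @param go_obo optional path to a minimal OBO file loaded instead of
#'   `go_terms.tsv` (see [read_minimal_obo()]).
#' @return an object of class `pathway_store`.
#' @export
load_pathway_source <- function(dir, go_obo = NULL) {
  me <- .read_tsv(dir, "molecular_entities.tsv")
  pr <- .read_tsv(dir, "processes.tsv")
  pp <- .read_tsv(dir, "process_participants.tsv")
  pw <- .read_tsv(dir, "pathways.tsv")
  pwp <- .read_tsv(dir, "pathway_processes.tsv")
  og <- .read_tsv(dir, "organism_groups.tsv")
  gt <- .read_tsv(dir, "go_terms.tsv")
  ec <- .read_tsv(dir, "ec_numbers.tsv")

  empty_entity <- data.frame(id = character(), name = character(),
                             stringsAsFactors = FALSE)
  xrefs <- list()
  take_xrefs <- function(df, kind) {
    if (is.null(df) || !nrow(df) || !("external_ids" %in% names(df))) {
      return(invisible())
    }
    for (i in seq_len(nrow(df))) {
      x <- .split_xrefs(df$external_ids[i])
      if (nrow(x)) {
        x$kind <- kind
        x$entityId <- df$id[i]
        if (anyDuplicated(x[c("namespace", "externalId")])) {
          stop("integrity error: duplicate external id on ", kind, " '",
               df$id[i], "'", call. = FALSE)
        }
        xrefs[[length(xrefs) + 1L]] <<- x
      }
    }
    invisible()
  }

  check_unique <- function(df, what) {
    if (!is.null(df) && nrow(df) && anyDuplicated(df$id)) {
      stop("integrity error: duplicate ", what, " id '",
           df$id[duplicated(df$id)][1], "'", call. = FALSE)
    }
  }

  molecular_entities <- if (is.null(me)) cbind(empty_entity,
    type = character()) else me[c("id", "name", "type")]
  check_unique(me, "molecular entity")
  take_xrefs(me, "molecular_entity")

  processes <- if (is.null(pr)) empty_entity else pr[c("id", "name")]
  check_unique(pr, "process")
  take_xrefs(pr, "process")
  process_ec <- data.frame(processId = character(), ecNumber = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(pr) && nrow(pr) && "ec_numbers" %in% names(pr)) {
    for (i in seq_len(nrow(pr))) {
      ecs <- strsplit(pr$ec_numbers[i], ";", fixed = TRUE)[[1]]
      ecs <- trimws(ecs[nzchar(trimws(ecs))])
      if (length(ecs)) {
        process_ec <- rbind(process_ec, data.frame(
          processId = pr$id[i], ecNumber = ecs, stringsAsFactors = FALSE))
      }
    }
  }

  participants <- if (is.null(pp)) data.frame(
    processId = character(), molecularEntityId = character(),
    role = character(), stringsAsFactors = FALSE) else
    stats::setNames(pp[c("process_id", "molecular_entity_id", "role")],
                    c("processId", "molecularEntityId", "role"))
  dangling <- setdiff(participants$processId, processes$id)
  if (length(dangling)) {
    stop("integrity error: participant references missing process ",
         dangling[1], call. = FALSE)
  }
  dangling <- setdiff(participants$molecularEntityId, molecular_entities$id)
  if (length(dangling)) {
    stop("integrity error: participant references missing molecular entity ",
         dangling[1], call. = FALSE)
  }

  organism_groups <- if (is.null(og)) empty_entity else og[c("id", "name")]
  check_unique(og, "organism group")
  group_taxa <- data.frame(organismGroupId = character(),
                           ncbiTaxonomyId = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(og) && nrow(og) && "ncbi_taxonomy_ids" %in% names(og)) {
    for (i in seq_len(nrow(og))) {
      taxa <- strsplit(og$ncbi_taxonomy_ids[i], ";", fixed = TRUE)[[1]]
      taxa <- trimws(taxa[nzchar(trimws(taxa))])
      if (length(taxa)) {
        group_taxa <- rbind(group_taxa, data.frame(
          organismGroupId = og$id[i], ncbiTaxonomyId = taxa,
          stringsAsFactors = FALSE))
      }
    }
  }

  pathways <- if (is.null(pw)) cbind(empty_entity,
    organismGroupId = character()) else stats::setNames(
      pw[c("id", "name", "organism_group_id")],
      c("id", "name", "organismGroupId"))
  check_unique(pw, "pathway")
  if (nrow(pathways)) {
    pathways$organismGroupId[!nzchar(pathways$organismGroupId)] <-
      NA_character_
    known <- is.na(pathways$organismGroupId) |
      pathways$organismGroupId %in% organism_groups$id
    if (!all(known)) {
      stop("integrity error: pathway references missing organism group ",
           pathways$organismGroupId[!known][1], call. = FALSE)
    }
  }
  take_xrefs(pw, "pathway")

  pathway_processes <- if (is.null(pwp)) data.frame(
    pathwayId = character(), processId = character(),
    stringsAsFactors = FALSE) else
    stats::setNames(pwp[c("pathway_id", "process_id")],
                    c("pathwayId", "processId"))
  dangling <- setdiff(pathway_processes$processId, processes$id)
  if (length(dangling)) {
    stop("integrity error: pathway references missing process ",
         dangling[1], call. = FALSE)
  }
  dangling <- setdiff(pathway_processes$pathwayId, pathways$id)
  if (length(dangling)) {
    stop("integrity error: pathway_processes references missing pathway ",
         dangling[1], call. = FALSE)
  }

  if (!is.null(go_obo)) {
    go <- read_minimal_obo(go_obo)
  } else if (!is.null(gt)) {
    parents <- list()
    for (i in seq_len(nrow(gt))) {
      ps <- strsplit(gt$parent_ids[i], ";", fixed = TRUE)[[1]]
      ps <- trimws(ps[nzchar(trimws(ps))])
      if (length(ps)) {
        parents[[length(parents) + 1L]] <- data.frame(
          goId = gt$go_id[i], parentId = ps, stringsAsFactors = FALSE)
      }
    }
    go <- list(
      terms = stats::setNames(gt[c("go_id", "name")], c("goId", "name")),
      parents = if (length(parents)) do.call(rbind, parents) else
        data.frame(goId = character(), parentId = character(),
                   stringsAsFactors = FALSE))
  } else {
    go <- list(terms = data.frame(goId = character(), name = character(),
                                  stringsAsFactors = FALSE),
               parents = data.frame(goId = character(),
                                    parentId = character(),
                                    stringsAsFactors = FALSE))
  }
  # acyclicity of the GO term graph is part of the store contract
  if (nrow(go$parents)) {
    sb_dag(data.frame(parent = go$parents$parentId,
                      child = go$parents$goId, stringsAsFactors = FALSE),
           nodes = go$terms$goId)
  }

  ec_numbers <- if (is.null(ec)) data.frame(
    ec_number = character(), name = character(), stringsAsFactors = FALSE)
    else ec[c("ec_number", "name")]

  xref_df <- if (length(xrefs)) do.call(rbind, xrefs) else data.frame(
    namespace = character(), externalId = character(), kind = character(),
    entityId = character(), stringsAsFactors = FALSE)
  rownames(xref_df) <- NULL

  structure(list(
    molecular_entities = molecular_entities, processes = processes,
    process_ec = process_ec, process_participants = participants,
    pathways = pathways, pathway_processes = pathway_processes,
    organism_groups = organism_groups, organism_group_taxa = group_taxa,
    go_terms = go$terms, go_parents = go$parents, ec_numbers = ec_numbers,
    xrefs = xref_df[c("kind", "entityId", "namespace", "externalId")]
  ), class = "pathway_store")
}

#' @export
print.pathway_store <- function(x, ...) {
  cat("<pathway_store>\n")
  cat("  molecular entities:", nrow(x$molecular_entities), "\n")
  cat("  processes:         ", nrow(x$processes), "\n")
  cat("  pathways:          ", nrow(x$pathways), "\n")
  cat("  organism groups:   ", nrow(x$organism_groups), "\n")
  cat("  GO terms:          ", nrow(x$go_terms), "\n")
  cat("  EC numbers:        ", nrow(x$ec_numbers), "\n")
  cat("  external ids:      ", nrow(x$xrefs), "\n")
  invisible(x)
}

#' Read a minimal OBO file (id, name, is_a only)
#'
#' @param path OBO 1.2 file; only `[Term]` stanzas with `id:`, `name:` and
#'   `is_a:` lines are interpreted.
#' @return list with `terms` (goId, name) and `parents` (goId, parentId).
#' @export
read_minimal_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); parents <- list()
  cur_id <- NA_character_; cur_name <- NA_character_
  in_term <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        goId = cur_id, name = cur_name, stringsAsFactors = FALSE)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE; cur_id <- NA_character_; cur_name <- NA_character_
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE
    } else if (in_term && startsWith(ln, "id:")) {
      cur_id <- trimws(substr(ln, 4L, nchar(ln)))
    } else if (in_term && startsWith(ln, "name:")) {
      cur_name <- trimws(substr(ln, 6L, nchar(ln)))
    } else if (in_term && startsWith(ln, "is_a:")) {
      target <- trimws(sub("!.*$", "", substr(ln, 6L, nchar(ln))))
      parents[[length(parents) + 1L]] <- data.frame(
        goId = cur_id, parentId = target, stringsAsFactors = FALSE)
    }
  }
  flush()
  list(
    terms = if (length(terms)) do.call(rbind, terms) else
      data.frame(goId = character(), name = character(),
                 stringsAsFactors = FALSE),
    parents = if (length(parents)) do.call(rbind, parents) else
      data.frame(goId = character(), parentId = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Build the cross-reference index of a pathway store
#'
#' Keyed by (namespace, external id); one key may resolve to several
#' entities and one entity may hold several keys.
#'
#' @param store a `pathway_store`.
#' @return object of class `crossref_index`.
#' @export
build_crossref_index <- function(store) {
  stopifnot(inherits(store, "pathway_store"))
  x <- store$xrefs
  structure(list(table = x,
                 key = paste(x$namespace, x$externalId, sep = "\r")),
            class = "crossref_index")
}

#' Look up entities by external identifier
#'
#' @param index a `crossref_index`.
#' @param namespace MIRIAM-style namespace (case-insensitive).
#' @param external_id external identifier (case-sensitive).
#' @param kind optional entity-kind filter (`"molecular_entity"`,
#'   `"process"`, `"pathway"`).
#' @return data frame of matching (kind, entityId) rows.
#' @export
xref_lookup <- function(index, namespace, external_id, kind = NULL) {
  stopifnot(inherits(index, "crossref_index"))
  hit <- index$key == paste(tolower(namespace), external_id, sep = "\r")
  out <- index$table[hit, c("kind", "entityId"), drop = FALSE]
  if (!is.null(kind)) out <- out[out$kind == kind, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.crossref_index <- function(x, ...) {
  cat("<crossref_index> ", nrow(x$table), " (namespace, id) entries over ",
      length(unique(x$key)), " distinct keys\n", sep = "")
  invisible(x)
}
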