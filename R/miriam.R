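# MIRIAM annotation extraction: qualifier-tagged URNs inside the RDF block
# of an SBML element's <annotation> subtree.

# The persisted qualifier dimension is pre-filled with exactly these names;
# other known qualifier local names are accepted and inserted on first use.
.prefilled_qualifiers <- c(
  "is", "isDescribedBy", "encodes", "hasPart", "hasVersion", "isEncodedBy",
  "isHomologTo", "isPartOf", "isVersionOf", "occursIn", "unknown"
)

.known_qualifiers <- c(
  .prefilled_qualifiers,
  "isDerivedFrom", "hasProperty", "hasTaxon", "isPropertyOf"
)

#' Pre-filled and accepted annotation qualifiers
#'
#' @return a list with elements `prefilled` (the names seeded into the
#'   qualifier dimension table) and `known` (all accepted local names; any
#'   other local name classifies as `"unknown"`).
#' @export
annotation_qualifiers <- function() {
  list(prefilled = .prefilled_qualifiers, known = .known_qualifiers)
}

#' Parse a MIRIAM URN into namespace and external identifier
#'
#' MIRIAM resources have the form `urn:miriam:<namespace>:<id>`, e.g.
#' `urn:miriam:kegg.compound:C00074`.  The identifier segment may carry
#' percent-escapes (`GO%3A0006096` for `GO:0006096`), which are decoded
#' exactly once.  Namespaces are normalised to lower case; identifiers keep
#' their case.
#'
#' @param urn a single URN string.
#' @return a list with `namespace` and `externalId`.
#' @export
#' @examples
#' parse_miriam_urn("urn:miriam:obo.go:GO%3A0006096")
parse_miriam_urn <- function(urn) {
  stopifnot(is.character(urn), length(urn) == 1)
  if (is.na(urn) || !startsWith(urn, "urn:miriam:")) {
    stop("malformed MIRIAM URN (must start with 'urn:miriam:'): ", urn,
         call. = FALSE)
  }
  rest <- substr(urn, nchar("urn:miriam:") + 1L, nchar(urn))
  # namespace is everything up to the last ":" separating it from the id;
  # the id itself never contains a raw ":" (it is percent-encoded there).
  pos <- regexpr(":[^:]*$", rest)
  if (pos < 1L || pos == nchar(rest)) {
    stop("malformed MIRIAM URN (missing id segment): ", urn, call. = FALSE)
  }
  ns <- substr(rest, 1L, pos - 1L)
  id <- substr(rest, pos + 1L, nchar(rest))
  if (!nzchar(ns) || !nzchar(id)) {
    stop("malformed MIRIAM URN (empty segment): ", urn, call. = FALSE)
  }
  list(namespace = tolower(ns), externalId = utils::URLdecode(id))
}

#' Classify a qualifier element name into qualifier and family
#'
#' Qualifier elements are prefixed `bqbiol:` (biology family) or `bqmodel:`
#' (model family); the local name is matched case-sensitively against the
#' accepted qualifier names, anything else mapping to `"unknown"` while
#' keeping the family of its prefix.
#'
#' @param element_name prefixed element name, e.g. `"bqbiol:isVersionOf"`.
#' @return list with `qualifier` and `family` (`"biology"` or `"model"`),
#'   or `NULL` when the prefix is not a qualifier prefix.
#' @export
classify_qualifier <- function(element_name) {
  stopifnot(is.character(element_name), length(element_name) == 1)
  parts <- strsplit(element_name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) return(NULL)
  family <- switch(parts[[1]], bqbiol = "biology", bqmodel = "model", NULL)
  if (is.null(family)) return(NULL)
  qualifier <- if (parts[[2]] %in% .known_qualifiers) parts[[2]] else "unknown"
  list(qualifier = qualifier, family = family)
}

#' Extract qualifier-tagged external links from an annotation block
#'
#' Walks the RDF inside an `<annotation>` subtree and returns one link per
#' `rdf:li` resource found inside a qualifier element's `rdf:Bag`.
#' Non-MIRIAM resources are skipped with a warning; unparseable annotation
#' text is skipped entirely (never fatal — real-world annotation blocks are
#' messy).  Duplicate (qualifier, family, namespace, id) tuples on the same
#' subject collapse to one link.
#'
#' @param annotation raw annotation XML text, or `NA`/`NULL` for none.
#' @param sbase_id internal id of the owning record.
#' @param subject_kind entity kind of the owner (`"model"`, `"species"`,
#'   `"reaction"`, `"compartment"`, ...).
#' @param quiet suppress warnings about skipped resources.
#' @return data frame with columns `sbaseId`, `subjectKind`, `qualifier`,
#'   `family`, `namespace`, `externalId`, `rawUrn` (zero rows when nothing
#'   was extracted).
#' @export
extract_annotation_links <- function(annotation, sbase_id,
                                     subject_kind = "sbase", quiet = FALSE) {
  empty <- data.frame(
    sbaseId = character(), subjectKind = character(), qualifier = character(),
    family = character(), namespace = character(), externalId = character(),
    rawUrn = character(), stringsAsFactors = FALSE
  )
  if (is.null(annotation) || length(annotation) == 0 || is.na(annotation) ||
      !nzchar(trimws(annotation))) {
    return(empty)
  }
  node <- tryCatch(
    xml2::read_xml(annotation, options = c("RECOVER", "NOERROR", "NOWARNING")),
    error = function(e) NULL
  )
  if (is.null(node)) {
    if (!quiet) warning("skipping unparseable annotation on ", sbase_id)
    return(empty)
  }
  # qualifier elements live under rdf:Description; match on prefixed names
  # so undeclared-but-conventional prefixes still classify.
  quals <- xml2::xml_find_all(
    node,
    ".//*[starts-with(name(), 'bqbiol:') or starts-with(name(), 'bqmodel:')]"
  )
  rows <- list()
  for (q in quals) {
    # name() yields the prefixed element name regardless of whether the
    # prefix was declared in the serialized fragment
    prefixed <- as.character(xml2::xml_find_first(q, "name(.)"))
    cls <- classify_qualifier(prefixed)
    if (is.null(cls)) next
    lis <- xml2::xml_find_all(q, ".//*[name()='rdf:li']")
    for (li in lis) {
      res <- xml2::xml_attr(li, "resource")
      # undeclared rdf: prefixes survive RECOVER parsing as literal names
      if (is.na(res)) res <- xml2::xml_attr(li, "rdf:resource")
      if (is.na(res)) next
      if (!startsWith(res, "urn:miriam:")) {
        if (!quiet) warning("skipping non-MIRIAM resource '", res, "' on ",
                            sbase_id)
        next
      }
      parsed <- tryCatch(parse_miriam_urn(res), error = function(e) NULL)
      if (is.null(parsed)) {
        if (!quiet) warning("skipping malformed URN '", res, "' on ", sbase_id)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sbaseId = sbase_id, subjectKind = subject_kind,
        qualifier = cls$qualifier, family = cls$family,
        namespace = parsed$namespace, externalId = parsed$externalId,
        rawUrn = res, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("sbaseId", "qualifier", "family", "namespace",
                        "externalId")]), , drop = FALSE]
}

#' Extract annotation links for every record of a model bundle
#'
#' @param bundle a model bundle from [parse_sbml_document()].
#' @param quiet suppress per-record warnings.
#' @return one data frame of links (see [extract_annotation_links()]) with
#'   an additional `modelId` column.
#' @export
extract_bundle_links <- function(bundle, quiet = FALSE) {
  stopifnot(inherits(bundle, "sbml_bundle"))
  pieces <- list(
    extract_annotation_links(bundle$model$annotation, bundle$model$id,
                             "model", quiet = quiet)
  )
  kind_of <- c(species = "species", reactions = "reaction",
               compartments = "compartment", parameters = "parameter",
               events = "event", function_definitions = "function")
  for (tab in names(kind_of)) {
    df <- bundle[[tab]]
    if (is.null(df) || !nrow(df)) next
    for (i in seq_len(nrow(df))) {
      pieces[[length(pieces) + 1L]] <- extract_annotation_links(
        df$annotation[i], df$id[i], kind_of[[tab]], quiet = quiet)
    }
  }
  out <- do.call(rbind, pieces)
  if (nrow(out)) out$modelId <- bundle$model$id else out$modelId <- character()
  rownames(out) <- NULL
  out
}
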