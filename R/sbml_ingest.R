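# SBML Level 2 ingest: one record per element of the kinds modelled in the
# relational schema, with SBML ids preserved in sbmlId and the raw
# <annotation> subtree stored verbatim on the owning record.

.sbase_cols <- c("id", "metaId", "sboTerm", "notes", "annotation")

.node_sbase <- function(node, internal_id) {
  ann <- xml2::xml_find_first(node, "./*[local-name()='annotation']")
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  data.frame(
    id = internal_id,
    metaId = xml2::xml_attr(node, "metaId"),
    sboTerm = xml2::xml_attr(node, "sboTerm"),
    notes = if (inherits(notes, "xml_missing")) NA_character_ else
      as.character(notes),
    annotation = if (inherits(ann, "xml_missing")) NA_character_ else
      as.character(ann),
    stringsAsFactors = FALSE
  )
}

.find1 <- function(node, local) {
  xml2::xml_find_first(node, sprintf("./*[local-name()='%s']", local))
}

.children_of_list <- function(model_node, list_name, child_name) {
  lst <- .find1(model_node, list_name)
  if (inherits(lst, "xml_missing")) return(list())
  as.list(xml2::xml_find_all(
    lst, sprintf("./*[local-name()='%s']", child_name)))
}

.math_text <- function(node) {
  m <- .find1(node, "math")
  if (inherits(m, "xml_missing")) NA_character_ else canonicalize_mathml(
    as.character(m))
}

#' Canonicalize MathML text
#'
#' Whitespace normalisation only (collapse runs, trim between tags); the
#' expression is stored, never evaluated, and no algebraic rewriting is
#' attempted.
#'
#' @param mathml MathML text (may be `NA`).
#' @return canonical text of the same expression.
#' @export
canonicalize_mathml <- function(mathml) {
  if (length(mathml) == 0 || is.na(mathml)) return(NA_character_)
  x <- gsub("\\s+", " ", mathml)
  x <- gsub("> <", "><", x, fixed = TRUE)
  trimws(x)
}

.df_or_empty <- function(rows, cols) {
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

#' Parse an SBML Level 2 document into a model bundle
#'
#' Produces one record per SBML element of the modelled kinds (model,
#' compartments, species, reactions and their participants, kinetic laws and
#' their parameters, global parameters, unit definitions, function
#' definitions, rules, constraints, initial assignments, events with
#' triggers/delays/assignments, species and compartment types).  Each record
#' carries the four Sbase fields (metaId, sboTerm, notes, raw annotation
#' text) plus its kind-specific columns; `sbmlId` always equals the source
#' element's `id` attribute.  Constructs outside these kinds remain in the
#' retained document text but are not materialised.
#'
#' SBML defaults are applied only where the SBML specification defines them
#' (`reversible = TRUE`, `constant = FALSE` for species, `constant = TRUE`
#' for parameters, stoichiometry 1 handled as absent-math default); all
#' other missing optional attributes stay absent (`NA`).
#'
#' @param document SBML XML text, or a path to an SBML file.
#' @param data_source_id id of the data source the document belongs to.
#' @param deterministic_ids derive internal ids from (data source, model id,
#'   element kind, SBML id) instead of generating opaque ones; used for
#'   reproducible stores and fixtures.
#' @return an object of class `sbml_bundle`: a list of data frames (`model`,
#'   `compartments`, `species`, `reactions`, `reaction_species`,
#'   `kinetic_laws`, `kinetic_law_parameters`, `parameters`,
#'   `unit_definitions`, `unit_compositions`, `function_definitions`,
#'   `rules`, `constraints`, `initial_assignments`, `events`,
#'   `event_triggers`, `event_delays`, `event_assignments`, `species_types`,
#'   `compartment_types`).
#' @export
parse_sbml_document <- function(document, data_source_id,
                                deterministic_ids = FALSE) {
  stopifnot(is.character(document), length(document) == 1)
  is_path <- !grepl("<", document, fixed = TRUE) && file.exists(document)
  raw_text <- if (is_path) paste(readLines(document, warn = FALSE),
                                 collapse = "\n") else document
  doc <- tryCatch(xml2::read_xml(raw_text),
                  error = function(e) {
                    stop("malformed XML: ", conditionMessage(e), call. = FALSE)
                  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    stop("not an SBML document (root element is '", xml2::xml_name(root),
         "')", call. = FALSE)
  }
  level <- suppressWarnings(as.integer(xml2::xml_attr(root, "level")))
  version <- suppressWarnings(as.integer(xml2::xml_attr(root, "version")))
  if (is.na(level) || level != 2L) {
    stop("unsupported SBML level: ", xml2::xml_attr(root, "level"),
         " (only Level 2 is accepted)", call. = FALSE)
  }
  model_node <- .find1(root, "model")
  if (inherits(model_node, "xml_missing")) {
    stop("SBML document has no <model> element", call. = FALSE)
  }
  model_sbml_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_sbml_id)) model_sbml_id <- "unnamed_model"

  mk_id <- function(kind, sbml_id) {
    new_internal_id(data_source_id, model_sbml_id, kind, sbml_id,
                    deterministic = deterministic_ids)
  }
  seen_ids <- new.env(parent = emptyenv())
  note_sbml_id <- function(sbml_id, kind) {
    if (is.na(sbml_id)) return(invisible())
    key <- sbml_id
    if (!is.null(seen_ids[[key]])) {
      stop("integrity error: duplicate sbmlId '", sbml_id, "' (", kind,
           " vs ", seen_ids[[key]], ") within model '", model_sbml_id, "'",
           call. = FALSE)
    }
    seen_ids[[key]] <- kind
    invisible()
  }

  model_id <- mk_id("model", model_sbml_id)
  model <- cbind(
    .node_sbase(model_node, model_id),
    data.frame(sbmlId = model_sbml_id,
               name = xml2::xml_attr(model_node, "name"),
               sbmlLevel = level, sbmlVersion = version,
               dataSourceId = data_source_id,
               sbmlFile = raw_text, stringsAsFactors = FALSE)
  )
  note_sbml_id(model_sbml_id, "model")

  simple_entity <- function(list_name, child_name, kind) {
    rows <- lapply(.children_of_list(model_node, list_name, child_name),
                   function(nd) {
      sid <- xml2::xml_attr(nd, "id")
      note_sbml_id(sid, kind)
      cbind(.node_sbase(nd, mk_id(kind, sid)),
            data.frame(modelId = model_id, sbmlId = sid,
                       name = xml2::xml_attr(nd, "name"),
                       stringsAsFactors = FALSE),
            .entity_extra(nd, kind))
    })
    rows
  }

  .entity_extra <- function(nd, kind) {
    switch(kind,
      compartment = data.frame(
        compartmentTypeSbmlId = xml2::xml_attr(nd, "compartmentType"),
        spatialDimensions =
          suppressWarnings(as.integer(
            xml2::xml_attr(nd, "spatialDimensions"))),
        size = suppressWarnings(as.numeric(xml2::xml_attr(nd, "size"))),
        unitsSbmlId = xml2::xml_attr(nd, "units"),
        outside = xml2::xml_attr(nd, "outside"),
        constant = as_flag(xml2::xml_attr(nd, "constant"), TRUE),
        stringsAsFactors = FALSE),
      species = {
        amt <- suppressWarnings(as.numeric(
          xml2::xml_attr(nd, "initialAmount")))
        conc <- suppressWarnings(as.numeric(
          xml2::xml_attr(nd, "initialConcentration")))
        if (!is.na(amt) && !is.na(conc)) {
          stop("integrity error: species '", xml2::xml_attr(nd, "id"),
               "' sets both initialAmount and initialConcentration",
               call. = FALSE)
        }
        data.frame(
          speciesTypeSbmlId = xml2::xml_attr(nd, "speciesType"),
          compartmentSbmlId = xml2::xml_attr(nd, "compartment"),
          initialAmount = amt, initialConcentration = conc,
          substanceUnitsSbmlId = xml2::xml_attr(nd, "substanceUnits"),
          hasOnlySubstanceUnits =
            as_flag(xml2::xml_attr(nd, "hasOnlySubstanceUnits"), FALSE),
          boundaryCondition =
            as_flag(xml2::xml_attr(nd, "boundaryCondition"), FALSE),
          charge = suppressWarnings(as.integer(xml2::xml_attr(nd, "charge"))),
          constant = as_flag(xml2::xml_attr(nd, "constant"), FALSE),
          stringsAsFactors = FALSE)
      },
      parameter = data.frame(
        value = suppressWarnings(as.numeric(xml2::xml_attr(nd, "value"))),
        unitsSbmlId = xml2::xml_attr(nd, "units"),
        constant = as_flag(xml2::xml_attr(nd, "constant"), TRUE),
        stringsAsFactors = FALSE),
      functiondef = data.frame(mathml = .math_text(nd),
                               stringsAsFactors = FALSE),
      data.frame(row.names = 1L)[, FALSE]
    )
  }

  compartments <- .df_or_empty(
    simple_entity("listOfCompartments", "compartment", "compartment"),
    c(.sbase_cols, "modelId", "sbmlId", "name"))
  species <- .df_or_empty(
    simple_entity("listOfSpecies", "species", "species"),
    c(.sbase_cols, "modelId", "sbmlId", "name"))
  parameters <- .df_or_empty(
    simple_entity("listOfParameters", "parameter", "parameter"),
    c(.sbase_cols, "modelId", "sbmlId", "name"))
  function_definitions <- .df_or_empty(
    simple_entity("listOfFunctionDefinitions", "functionDefinition",
                  "functiondef"),
    c(.sbase_cols, "modelId", "sbmlId", "name", "mathml"))
  species_types <- .df_or_empty(
    simple_entity("listOfSpeciesTypes", "speciesType", "speciestype"),
    c(.sbase_cols, "modelId", "sbmlId", "name"))
  compartment_types <- .df_or_empty(
    simple_entity("listOfCompartmentTypes", "compartmentType",
                  "compartmenttype"),
    c(.sbase_cols, "modelId", "sbmlId", "name"))

  # unit definitions + compositions
  ud_rows <- list(); uc_rows <- list()
  for (nd in .children_of_list(model_node, "listOfUnitDefinitions",
                               "unitDefinition")) {
    sid <- xml2::xml_attr(nd, "id")
    note_sbml_id(sid, "unitdef")
    uid <- mk_id("unitdef", sid)
    ud_rows[[length(ud_rows) + 1L]] <- cbind(
      .node_sbase(nd, uid),
      data.frame(modelId = model_id, sbmlId = sid,
                 name = xml2::xml_attr(nd, "name"), stringsAsFactors = FALSE))
    lou <- .find1(nd, "listOfUnits")
    if (!inherits(lou, "xml_missing")) {
      for (u in xml2::xml_find_all(lou, "./*[local-name()='unit']")) {
        uc_rows[[length(uc_rows) + 1L]] <- data.frame(
          unitDefinitionId = uid,
          baseUnitKind = xml2::xml_attr(u, "kind"),
          exponent = suppressWarnings(
            as.integer(xml2::xml_attr(u, "exponent"))) %||% 1L,
          scale = suppressWarnings(
            as.integer(xml2::xml_attr(u, "scale"))) %||% 0L,
          multiplier = suppressWarnings(
            as.numeric(xml2::xml_attr(u, "multiplier"))) %||% 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  unit_definitions <- .df_or_empty(
    ud_rows, c(.sbase_cols, "modelId", "sbmlId", "name"))
  unit_compositions <- .df_or_empty(
    uc_rows, c("unitDefinitionId", "baseUnitKind", "exponent", "scale",
               "multiplier"))

  # reactions, participants, kinetic laws
  rx_rows <- list(); rs_rows <- list(); kl_rows <- list(); klp_rows <- list()
  for (nd in .children_of_list(model_node, "listOfReactions", "reaction")) {
    sid <- xml2::xml_attr(nd, "id")
    note_sbml_id(sid, "reaction")
    rid <- mk_id("reaction", sid)
    kl_node <- .find1(nd, "kineticLaw")
    kl_id <- NA_character_
    if (!inherits(kl_node, "xml_missing")) {
      kl_id <- mk_id("kineticlaw", sid)
      kl_rows[[length(kl_rows) + 1L]] <- cbind(
        .node_sbase(kl_node, kl_id),
        data.frame(reactionId = rid, mathml = .math_text(kl_node),
                   stringsAsFactors = FALSE))
      lop <- .find1(kl_node, "listOfParameters")
      if (!inherits(lop, "xml_missing")) {
        for (p in xml2::xml_find_all(lop, "./*[local-name()='parameter']")) {
          psid <- xml2::xml_attr(p, "id")
          klp_rows[[length(klp_rows) + 1L]] <- cbind(
            .node_sbase(p, mk_id("klparam", paste(sid, psid, sep = "."))),
            data.frame(kineticLawId = kl_id, sbmlId = psid,
                       name = xml2::xml_attr(p, "name"),
                       value = suppressWarnings(
                         as.numeric(xml2::xml_attr(p, "value"))),
                       unitsSbmlId = xml2::xml_attr(p, "units"),
                       stringsAsFactors = FALSE))
        }
      }
    }
    rx_rows[[length(rx_rows) + 1L]] <- cbind(
      .node_sbase(nd, rid),
      data.frame(modelId = model_id, sbmlId = sid,
                 name = xml2::xml_attr(nd, "name"),
                 reversible = as_flag(xml2::xml_attr(nd, "reversible"), TRUE),
                 fast = as_flag(xml2::xml_attr(nd, "fast"), FALSE),
                 kineticLawId = kl_id, stringsAsFactors = FALSE))
    for (role in c("reactant", "product", "modifier")) {
      list_name <- switch(role, reactant = "listOfReactants",
                          product = "listOfProducts",
                          modifier = "listOfModifiers")
      child <- if (role == "modifier") "modifierSpeciesReference" else
        "speciesReference"
      k <- 0L
      for (sr in .children_of_list(nd, list_name, child)) {
        k <- k + 1L
        sm_node <- .find1(sr, "stoichiometryMath")
        sm_text <- if (inherits(sm_node, "xml_missing")) NA_character_ else
          .math_text(sm_node)
        stoich <- suppressWarnings(
          as.numeric(xml2::xml_attr(sr, "stoichiometry")))
        # SBML default stoichiometry is 1 for reactants/products when no
        # stoichiometryMath is given
        if (role != "modifier" && is.na(stoich) && is.na(sm_text)) stoich <- 1
        rs_rows[[length(rs_rows) + 1L]] <- cbind(
          .node_sbase(sr, mk_id("rxnspecies",
                                paste(sid, role, k, sep = "."))),
          data.frame(reactionId = rid,
                     speciesSbmlId = xml2::xml_attr(sr, "species"),
                     roleId = role,
                     stoichiometry = if (role == "modifier") NA_real_ else
                       stoich,
                     stoichiometryMath = if (role == "modifier")
                       NA_character_ else sm_text,
                     sbmlId = xml2::xml_attr(sr, "id"),
                     name = xml2::xml_attr(sr, "name"),
                     stringsAsFactors = FALSE))
      }
    }
  }
  reactions <- .df_or_empty(
    rx_rows, c(.sbase_cols, "modelId", "sbmlId", "name", "reversible",
               "fast", "kineticLawId"))
  reaction_species <- .df_or_empty(
    rs_rows, c(.sbase_cols, "reactionId", "speciesSbmlId", "roleId",
               "stoichiometry", "stoichiometryMath", "sbmlId", "name"))
  kinetic_laws <- .df_or_empty(
    kl_rows, c(.sbase_cols, "reactionId", "mathml"))
  kinetic_law_parameters <- .df_or_empty(
    klp_rows, c(.sbase_cols, "kineticLawId", "sbmlId", "name", "value",
                "unitsSbmlId"))

  # rules (three SBML L2 kinds), constraints, initial assignments
  rule_rows <- list()
  lor <- .find1(model_node, "listOfRules")
  if (!inherits(lor, "xml_missing")) {
    k <- 0L
    for (nd in xml2::xml_children(lor)) {
      k <- k + 1L
      kind <- switch(xml2::xml_name(nd),
                     algebraicRule = "algebraic",
                     assignmentRule = "assignment",
                     rateRule = "rate", NA_character_)
      if (is.na(kind)) next
      rule_rows[[length(rule_rows) + 1L]] <- cbind(
        .node_sbase(nd, mk_id("rule", k)),
        data.frame(modelId = model_id, ruleType = kind,
                   variable = xml2::xml_attr(nd, "variable"),
                   mathml = .math_text(nd), stringsAsFactors = FALSE))
    }
  }
  rules <- .df_or_empty(
    rule_rows, c(.sbase_cols, "modelId", "ruleType", "variable", "mathml"))

  con_rows <- list()
  k <- 0L
  for (nd in .children_of_list(model_node, "listOfConstraints",
                               "constraint")) {
    k <- k + 1L
    msg <- .find1(nd, "message")
    con_rows[[length(con_rows) + 1L]] <- cbind(
      .node_sbase(nd, mk_id("constraint", k)),
      data.frame(modelId = model_id, mathml = .math_text(nd),
                 message = if (inherits(msg, "xml_missing")) NA_character_
                 else as.character(msg), stringsAsFactors = FALSE))
  }
  constraints <- .df_or_empty(
    con_rows, c(.sbase_cols, "modelId", "mathml", "message"))

  ia_rows <- list()
  k <- 0L
  for (nd in .children_of_list(model_node, "listOfInitialAssignments",
                               "initialAssignment")) {
    k <- k + 1L
    ia_rows[[length(ia_rows) + 1L]] <- cbind(
      .node_sbase(nd, mk_id("initassign", k)),
      data.frame(modelId = model_id, symbol = xml2::xml_attr(nd, "symbol"),
                 mathml = .math_text(nd), stringsAsFactors = FALSE))
  }
  initial_assignments <- .df_or_empty(
    ia_rows, c(.sbase_cols, "modelId", "symbol", "mathml"))

  # events
  ev_rows <- list(); tr_rows <- list(); dl_rows <- list(); ea_rows <- list()
  k <- 0L
  for (nd in .children_of_list(model_node, "listOfEvents", "event")) {
    k <- k + 1L
    sid <- xml2::xml_attr(nd, "id")
    note_sbml_id(sid, "event")
    eid <- mk_id("event", if (is.na(sid)) k else sid)
    ev_rows[[length(ev_rows) + 1L]] <- cbind(
      .node_sbase(nd, eid),
      data.frame(modelId = model_id, sbmlId = sid,
                 name = xml2::xml_attr(nd, "name"), stringsAsFactors = FALSE))
    trg <- .find1(nd, "trigger")
    if (!inherits(trg, "xml_missing")) {
      tr_rows[[length(tr_rows) + 1L]] <- cbind(
        .node_sbase(trg, mk_id("eventtrigger", k)),
        data.frame(eventId = eid, mathml = .math_text(trg),
                   stringsAsFactors = FALSE))
    }
    dly <- .find1(nd, "delay")
    if (!inherits(dly, "xml_missing")) {
      dl_rows[[length(dl_rows) + 1L]] <- cbind(
        .node_sbase(dly, mk_id("eventdelay", k)),
        data.frame(eventId = eid, mathml = .math_text(dly),
                   stringsAsFactors = FALSE))
    }
    j <- 0L
    for (ea in .children_of_list(nd, "listOfEventAssignments",
                                 "eventAssignment")) {
      j <- j + 1L
      ea_rows[[length(ea_rows) + 1L]] <- cbind(
        .node_sbase(ea, mk_id("eventassign", paste(k, j, sep = "."))),
        data.frame(eventId = eid, variable = xml2::xml_attr(ea, "variable"),
                   mathml = .math_text(ea), stringsAsFactors = FALSE))
    }
  }
  events <- .df_or_empty(ev_rows, c(.sbase_cols, "modelId", "sbmlId", "name"))
  event_triggers <- .df_or_empty(tr_rows, c(.sbase_cols, "eventId", "mathml"))
  event_delays <- .df_or_empty(dl_rows, c(.sbase_cols, "eventId", "mathml"))
  event_assignments <- .df_or_empty(
    ea_rows, c(.sbase_cols, "eventId", "variable", "mathml"))

  # resolve intra-model sbmlId references to internal ids
  lookup <- function(df, sbml_ids) {
    if (!length(sbml_ids)) return(character())
    df$id[match(sbml_ids, df$sbmlId)]
  }
  if (nrow(species)) {
    species$compartmentId <- lookup(compartments, species$compartmentSbmlId)
    bad <- !is.na(species$compartmentSbmlId) & is.na(species$compartmentId)
    if (any(bad)) {
      stop("integrity error: species reference unknown compartment(s): ",
           paste(unique(species$compartmentSbmlId[bad]), collapse = ", "),
           call. = FALSE)
    }
    species$speciesTypeId <- lookup(species_types, species$speciesTypeSbmlId)
    species$substanceUnitsId <- lookup(unit_definitions,
                                       species$substanceUnitsSbmlId)
  }
  if (nrow(compartments)) {
    compartments$compartmentTypeId <- lookup(compartment_types,
                                             compartments$compartmentTypeSbmlId)
    compartments$unitsId <- lookup(unit_definitions,
                                   compartments$unitsSbmlId)
  }
  if (nrow(parameters)) {
    parameters$unitsId <- lookup(unit_definitions, parameters$unitsSbmlId)
  }
  if (nrow(kinetic_law_parameters)) {
    kinetic_law_parameters$unitsId <- lookup(
      unit_definitions, kinetic_law_parameters$unitsSbmlId)
  }
  if (nrow(reaction_species)) {
    reaction_species$speciesId <- lookup(species,
                                         reaction_species$speciesSbmlId)
    bad <- is.na(reaction_species$speciesId)
    if (any(bad)) {
      stop("integrity error: reaction participants reference unknown ",
           "species: ",
           paste(unique(reaction_species$speciesSbmlId[bad]), collapse = ", "),
           call. = FALSE)
    }
  }

  structure(list(
    model = model, compartments = compartments, species = species,
    reactions = reactions, reaction_species = reaction_species,
    kinetic_laws = kinetic_laws,
    kinetic_law_parameters = kinetic_law_parameters,
    parameters = parameters, unit_definitions = unit_definitions,
    unit_compositions = unit_compositions,
    function_definitions = function_definitions, rules = rules,
    constraints = constraints, initial_assignments = initial_assignments,
    events = events, event_triggers = event_triggers,
    event_delays = event_delays, event_assignments = event_assignments,
    species_types = species_types, compartment_types = compartment_types
  ), class = "sbml_bundle")
}

#' @export
print.sbml_bundle <- function(x, ...) {
  cat("<sbml_bundle> model '", x$model$sbmlId, "' (SBML L",
      x$model$sbmlLevel, "V", x$model$sbmlVersion, ")\n", sep = "")
  for (tab in setdiff(names(x), "model")) {
    n <- nrow(x[[tab]])
    if (n > 0) cat(sprintf("  %-24s %d\n", tab, n))
  }
  invisible(x)
}

#' Parse every SBML file in a directory
#'
#' @param dir directory containing `.xml`/`.sbml` files, one model each.
#' @inheritParams parse_sbml_document
#' @param on_error `"stop"` or `"skip"` (skipped files are reported via
#'   warning).
#' @return list of `sbml_bundle` objects, named by file.
#' @export
parse_sbml_directory <- function(dir, data_source_id,
                                 deterministic_ids = FALSE,
                                 on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  files <- sort(list.files(dir, pattern = "\\.(xml|sbml)$",
                           full.names = TRUE))
  out <- list()
  for (f in files) {
    b <- tryCatch(
      parse_sbml_document(f, data_source_id,
                          deterministic_ids = deterministic_ids),
      error = function(e) {
        if (on_error == "stop") stop(conditionMessage(e), call. = FALSE)
        warning("skipping ", basename(f), ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(b)) out[[basename(f)]] <- b
  }
  out
}

#' Classify the identifiers of a mathematical expression
#'
#' MathML expressions (kinetic laws, rules, event elements, ...) may
#' reference species, global parameters, compartments and pre-defined
#' functions of the same model by their SBML id.  This resolves every
#' `<ci>` identifier against the bundle: identifiers naming a function
#' definition become arguments of kind `"function"` carrying the internal
#' `functionId`; the rest are classified `species` / `parameter` /
#' `compartment`, and anything unresolved is flagged (never fatal).
#'
#' @param mathml MathML text.
#' @param bundle the owning `sbml_bundle`.
#' @return data frame with columns `symbol`, `kind`
#'   (`species|parameter|compartment|function|unresolved`) and `functionId`
#'   (`NA` except for functions); one row per distinct identifier.
#' @export
resolve_function_references <- function(mathml, bundle) {
  stopifnot(inherits(bundle, "sbml_bundle"))
  empty <- data.frame(symbol = character(), kind = character(),
                      functionId = character(), stringsAsFactors = FALSE)
  if (length(mathml) == 0 || is.na(mathml)) return(empty)
  node <- tryCatch(xml2::read_xml(mathml), error = function(e) NULL)
  if (is.null(node)) return(empty)
  cis <- xml2::xml_find_all(node, ".//*[local-name()='ci']")
  syms <- unique(trimws(xml2::xml_text(cis)))
  syms <- syms[nzchar(syms)]
  if (!length(syms)) return(empty)
  fmatch <- match(syms, bundle$function_definitions$sbmlId)
  kind <- ifelse(!is.na(fmatch), "function",
          ifelse(syms %in% bundle$species$sbmlId, "species",
          ifelse(syms %in% bundle$parameters$sbmlId |
                 syms %in% bundle$kinetic_law_parameters$sbmlId, "parameter",
          ifelse(syms %in% bundle$compartments$sbmlId, "compartment",
                 "unresolved"))))
  data.frame(symbol = syms, kind = kind,
             functionId = ifelse(!is.na(fmatch),
                                 bundle$function_definitions$id[fmatch],
                                 NA_character_),
             stringsAsFactors = FALSE)
}

# SBML Level 2 built-in base unit kinds; seeded as UnitDefinition rows with
# an absent modelId before any document is ingested.
.sbml_base_units <- c(
  "ampere", "becquerel", "candela", "celsius", "coulomb", "dimensionless",
  "farad", "gram", "gray", "henry", "hertz", "item", "joule", "katal",
  "kelvin", "kilogram", "litre", "lumen", "lux", "metre", "mole", "newton",
  "ohm", "pascal", "radian", "second", "siemens", "sievert", "steradian",
  "tesla", "volt", "watt", "weber"
)

#' Built-in SBML base unit kinds
#' @return character vector of base unit names.
#' @export
sbml_base_units <- function() .sbml_base_units

#' Validate and partition a bundle's unit definitions
#'
#' User-specified unit definitions carry the model id and must be composed
#' exclusively of built-in base units — a unit built on another user unit is
#' rejected, mirroring the SBML rule that user units cannot be defined in
#' terms of each other.
#'
#' @param bundle an `sbml_bundle`.
#' @return list with `user` (the bundle's unit definition records) and
#'   `compositions` (validated composition rows).
#' @export
normalize_unit_definitions <- function(bundle) {
  stopifnot(inherits(bundle, "sbml_bundle"))
  comp <- bundle$unit_compositions
  if (nrow(comp)) {
    bad <- !(comp$baseUnitKind %in% .sbml_base_units)
    if (any(bad)) {
      stop("validation error: unit composition references non-base unit(s): ",
           paste(unique(comp$baseUnitKind[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  list(user = bundle$unit_definitions, compositions = comp)
}
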