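# Synthetic fixture generation: SBML corpora with planted MIRIAM links, an
# aligned pathway source, and random DAGs — all deterministic per seed and
# accompanied by a machine-readable ground-truth ledger from which every
# downstream count (mapping precision/recall, coverage partitions, path
# counts) is decidable.

.with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("validation error: a seed is required for fixture generation",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default fixture configuration
#'
#' Corpus shape and annotation coverage used by the generator unless
#' overridden: 10 models of 8 species and 6 reactions each, KEGG compound
#' and reaction coverage 0.5 (per-model planted-link counts are
#' `floor(coverage * entities)`), ChEBI coverage 0.25, EC coverage 0.25,
#' model-level KEGG-pathway links on 80% of models, GO links on 90%,
#' taxonomy links on all, and a 10% unmatched-link fraction referencing
#' identifiers absent from the pathway source.
#'
#' @return named list of configuration values.
#' @export
fixture_config <- function() {
  list(
    models = 10L, species_per_model = 8L, reactions_per_model = 6L,
    kegg_compound_coverage = 0.5, chebi_coverage = 0.25,
    kegg_reaction_coverage = 0.5, ec_coverage = 0.25,
    pathway_link_rate = 0.8, go_link_rate = 0.9, taxonomy_link_rate = 1.0,
    unmatched_rate = 0.1,
    qualifier_mix = c("is", "isVersionOf", "isHomologTo")
  )
}

.check_config <- function(config) {
  fracs <- c("kegg_compound_coverage", "chebi_coverage",
             "kegg_reaction_coverage", "ec_coverage", "pathway_link_rate",
             "go_link_rate", "taxonomy_link_rate", "unmatched_rate")
  for (f in fracs) {
    v <- config[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("validation error: ", f, " must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  for (f in c("models", "species_per_model", "reactions_per_model")) {
    if (!is.numeric(config[[f]]) || config[[f]] < 0) {
      stop("validation error: ", f, " must be a non-negative count",
           call. = FALSE)
    }
  }
  invisible(config)
}

# fixed GO hierarchy used for planted GO links (ids inside go pool are
# loadable; the unmatched pool uses ids outside it)
.fixture_go <- function() {
  terms <- data.frame(
    goId = c("GO:0008150", "GO:0008152", "GO:0006096", "GO:0006099",
             "GO:0046323", "GO:0005975", "GO:0006006"),
    name = c("biological_process", "metabolic process", "glycolysis",
             "TCA cycle", "glucose import", "carbohydrate metabolism",
             "glucose metabolism"),
    stringsAsFactors = FALSE)
  parents <- data.frame(
    goId = c("GO:0008152", "GO:0005975", "GO:0006006", "GO:0006096",
             "GO:0006099", "GO:0046323"),
    parentId = c("GO:0008150", "GO:0008152", "GO:0005975", "GO:0006006",
                 "GO:0008152", "GO:0008150"),
    stringsAsFactors = FALSE)
  list(terms = terms, parents = parents)
}

.rdf_annotation <- function(links) {
  # links: data frame (qualifier, family, urn)
  if (!nrow(links)) return("")
  quals <- character()
  for (i in seq_len(nrow(links))) {
    pre <- if (links$family[i] == "model") "bqmodel" else "bqbiol"
    quals <- c(quals, sprintf(
      "<%s:%s><rdf:Bag><rdf:li rdf:resource=\"%s\"/></rdf:Bag></%s:%s>",
      pre, links$qualifier[i], links$urn[i], pre, links$qualifier[i]))
  }
  paste0(
    "<annotation><rdf:RDF",
    " xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\"",
    " xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\">",
    "<rdf:Description>", paste(quals, collapse = ""),
    "</rdf:Description></rdf:RDF></annotation>")
}

.urn_encode_id <- function(id) gsub(":", "%3A", id, fixed = TRUE)

#' Generate a synthetic SBML corpus with planted annotation links
#'
#' Writes one SBML Level 2 file per model into `dir` and returns the
#' ground-truth ledger.  Planted links follow the MIRIAM URN grammar
#' (`urn:miriam:kegg.compound:C00031`, colons in GO/ChEBI ids
#' percent-encoded).  Per-model planted-link counts are
#' `floor(coverage * entities)` (the documented rounding rule), assigned to
#' the first entities in id order; a `floor(unmatched_rate * n)` tail of
#' each link category references identifiers from a disjoint pool that the
#' aligned pathway source will not contain, exercising unmatched-link
#' handling.  Qualifiers rotate deterministically through `qualifier_mix`
#' under the seed.
#'
#' @param config configuration list (see [fixture_config()]); partial
#'   overrides are merged over the defaults.
#' @param seed integer seed (mandatory).
#' @param dir output directory for the SBML files (created if needed).
#' @return the fixture ledger: a list with `config`, `models` (per-model
#'   expected counts), `links` (planted links with their `matched` flag)
#'   and `go` (the GO graph used).
#' @export
generate_model_corpus <- function(config = list(), seed, dir) {
  config <- utils::modifyList(fixture_config(), config)
  .check_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  go <- .fixture_go()

  .with_seed(seed, {
    n_models <- as.integer(config$models)
    nsp <- as.integer(config$species_per_model)
    nrx <- as.integer(config$reactions_per_model)
    qmix <- config$qualifier_mix

    # matched/unmatched external-id pools (disjoint)
    pool <- list(
      kegg.compound = sprintf("C%05d", 1:60),
      obo.chebi = sprintf("CHEBI:%d", 15000 + 1:40),
      kegg.reaction = sprintf("R%05d", 1:60),
      kegg.pathway = sprintf("hsa%05d", c(10, 20, 30, 40, 51, 62)),
      taxonomy = c("9606", "10090", "4932", "562", "5691"),
      "obo.go" = go$terms$goId,
      "ec-code" = c("5.3.1.9", "2.7.1.1", "1.1.1.1", "4.1.2.13")
    )
    unmatched_pool <- list(
      kegg.compound = sprintf("C9%04d", 1:20),
      obo.chebi = sprintf("CHEBI:%d", 99000 + 1:20),
      kegg.reaction = sprintf("R9%04d", 1:20),
      kegg.pathway = sprintf("zzz%05d", 1:5),
      "obo.go" = sprintf("GO:99%05d", 1:10),
      "ec-code" = c("9.9.9.9", "8.8.8.8")
    )

    ledger_links <- list()
    model_rows <- list()
    qi <- 0L
    next_qual <- function() {
      qi <<- qi + 1L
      qmix[((qi - 1L) %% length(qmix)) + 1L]
    }

    plant <- function(model_sbml_id, subject_sbml_id, kind, namespace,
                      external_id, matched, family = "biology",
                      qualifier = NULL) {
      if (is.null(qualifier)) qualifier <- next_qual()
      ledger_links[[length(ledger_links) + 1L]] <<- data.frame(
        model = model_sbml_id, subject = subject_sbml_id,
        subjectKind = kind, qualifier = qualifier, family = family,
        namespace = namespace, externalId = external_id,
        matched = matched, stringsAsFactors = FALSE)
      data.frame(qualifier = qualifier, family = family,
                 urn = paste0("urn:miriam:", namespace, ":",
                              .urn_encode_id(external_id)),
                 stringsAsFactors = FALSE)
    }

    n_with_pathway <- floor(config$pathway_link_rate * n_models)
    n_with_go <- floor(config$go_link_rate * n_models)
    n_with_tax <- floor(config$taxonomy_link_rate * n_models)
    n_sp_links <- floor(config$kegg_compound_coverage * nsp)
    n_chebi <- floor(config$chebi_coverage * nsp)
    n_rx_links <- floor(config$kegg_reaction_coverage * nrx)
    n_ec <- floor(config$ec_coverage * nrx)

    unmatched_tail <- function(n) {
      # the last floor(rate * n) planted links of a category are unmatched
      k <- floor(config$unmatched_rate * n)
      if (k == 0) rep(TRUE, n) else c(rep(TRUE, n - k), rep(FALSE, k))
    }

    pick <- function(ns, n, matched_flags) {
      src <- ifelse(matched_flags,
                    sample(pool[[ns]], n, replace = TRUE), NA)
      un <- !matched_flags
      if (any(un)) src[un] <- sample(unmatched_pool[[ns]], sum(un),
                                     replace = TRUE)
      src
    }

    for (mi in seq_len(n_models)) {
      msid <- sprintf("model%03d", mi)
      sp_ids <- sprintf("S%d_%d", mi, seq_len(nsp))
      rx_ids <- sprintf("R%d_%d", mi, seq_len(nrx))

      # model-level links
      model_link_rows <- list()
      if (mi <= n_with_pathway) {
        flag <- unmatched_tail(n_with_pathway)[mi]
        model_link_rows[[length(model_link_rows) + 1L]] <- plant(
          msid, msid, "model", "kegg.pathway",
          pick("kegg.pathway", 1L, flag), flag, qualifier = "is")
      }
      if (mi <= n_with_go) {
        flag <- unmatched_tail(n_with_go)[mi]
        model_link_rows[[length(model_link_rows) + 1L]] <- plant(
          msid, msid, "model", "obo.go", pick("obo.go", 1L, flag), flag,
          qualifier = "isVersionOf")
      }
      if (mi <= n_with_tax) {
        model_link_rows[[length(model_link_rows) + 1L]] <- plant(
          msid, msid, "model", "taxonomy",
          sample(pool$taxonomy, 1L), TRUE, qualifier = "is")
      }
      model_ann <- if (length(model_link_rows))
        .rdf_annotation(do.call(rbind, model_link_rows)) else ""

      # species links: first n_sp_links species get kegg.compound, first
      # n_chebi get obo.chebi
      sp_ann <- character(nsp)
      sp_flags <- unmatched_tail(n_sp_links)
      sp_ext <- pick("kegg.compound", n_sp_links, sp_flags)
      ch_flags <- unmatched_tail(n_chebi)
      ch_ext <- pick("obo.chebi", n_chebi, ch_flags)
      for (si in seq_len(nsp)) {
        rows <- list()
        if (si <= n_sp_links) {
          rows[[length(rows) + 1L]] <- plant(
            msid, sp_ids[si], "species", "kegg.compound", sp_ext[si],
            sp_flags[si])
        }
        if (si <= n_chebi) {
          rows[[length(rows) + 1L]] <- plant(
            msid, sp_ids[si], "species", "obo.chebi", ch_ext[si],
            ch_flags[si])
        }
        sp_ann[si] <- if (length(rows)) .rdf_annotation(do.call(rbind, rows))
          else ""
      }

      rx_ann <- character(nrx)
      rx_flags <- unmatched_tail(n_rx_links)
      rx_ext <- pick("kegg.reaction", n_rx_links, rx_flags)
      ec_flags <- unmatched_tail(n_ec)
      ec_ext <- pick("ec-code", n_ec, ec_flags)
      for (ri in seq_len(nrx)) {
        rows <- list()
        if (ri <= n_rx_links) {
          rows[[length(rows) + 1L]] <- plant(
            msid, rx_ids[ri], "reaction", "kegg.reaction", rx_ext[ri],
            rx_flags[ri])
        }
        if (ri <= n_ec) {
          rows[[length(rows) + 1L]] <- plant(
            msid, rx_ids[ri], "reaction", "ec-code", ec_ext[ri],
            ec_flags[ri], qualifier = "isVersionOf")
        }
        rx_ann[ri] <- if (length(rows)) .rdf_annotation(do.call(rbind, rows))
          else ""
      }

      # assemble the document
      sp_xml <- vapply(seq_len(nsp), function(si) sprintf(
        "  <species id=\"%s\" compartment=\"cell\" initialConcentration=\"%.1f\">%s</species>",
        sp_ids[si], si / 10, sp_ann[si]), character(1))
      rx_xml <- vapply(seq_len(nrx), function(ri) {
        a <- sp_ids[((ri - 1L) %% nsp) + 1L]
        b <- sp_ids[(ri %% nsp) + 1L]
        sprintf(paste0(
          "  <reaction id=\"%s\" reversible=\"false\">%s",
          "<listOfReactants><speciesReference species=\"%s\"/>",
          "</listOfReactants><listOfProducts>",
          "<speciesReference species=\"%s\"/></listOfProducts>",
          "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
          "<apply><times/><ci>k%d</ci><ci>%s</ci></apply></math>",
          "<listOfParameters><parameter id=\"k%d\" value=\"%.2f\"/>",
          "</listOfParameters></kineticLaw></reaction>"),
          rx_ids[ri], rx_ann[ri], a, b, ri, a, ri, ri / 10)
      }, character(1))
      doc <- paste0(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
        "<sbml xmlns=\"http://www.sbml.org/sbml/level2\" level=\"2\" ",
        "version=\"4\">\n",
        sprintf("<model id=\"%s\" name=\"Synthetic model %d\">%s\n",
                msid, mi, model_ann),
        "<listOfCompartments><compartment id=\"cell\" size=\"1\"/>",
        "</listOfCompartments>\n",
        "<listOfSpecies>\n", paste(sp_xml, collapse = "\n"),
        "\n</listOfSpecies>\n",
        "<listOfReactions>\n", paste(rx_xml, collapse = "\n"),
        "\n</listOfReactions>\n</model></sbml>\n")
      writeLines(doc, file.path(dir, paste0(msid, ".xml")))
      model_rows[[mi]] <- data.frame(
        model = msid, species = nsp, reactions = nrx,
        participants = 2L * nrx, stringsAsFactors = FALSE)
    }

    links <- if (length(ledger_links)) do.call(rbind, ledger_links) else
      data.frame(model = character(), subject = character(),
                 subjectKind = character(), qualifier = character(),
                 family = character(), namespace = character(),
                 externalId = character(), matched = logical(),
                 stringsAsFactors = FALSE)
    rownames(links) <- NULL
    list(config = config, models = do.call(rbind, model_rows),
         links = links, go = go)
  })
}

#' Generate the pathway source aligned with a corpus ledger
#'
#' Creates one pathway-side entity per distinct matched external id of the
#' corresponding category (molecular entities for `kegg.compound` and
#' `obo.chebi` ids, processes for `kegg.reaction`, pathways for
#' `kegg.pathway`), so the expected mapping rows are exactly the matched
#' planted links.  Organism groups aggregate the taxonomy pool; processes
#' are attached to pathways and given participants deterministically under
#' the seed; GO terms and EC numbers cover the matched pools.
#'
#' @param ledger ledger returned by [generate_model_corpus()].
#' @param seed integer seed (mandatory).
#' @param dir output directory for the TSV files.
#' @return the ledger, augmented with `expected` — a data frame of expected
#'   mapping rows (model, subject sbml id, kind, target entity id,
#'   qualifier, table).
#' @export
generate_pathway_source <- function(ledger, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  links <- ledger$links
  .with_seed(seed, {
    matched <- links[links$matched, , drop = FALSE]

    me_ids <- unique(matched$externalId[
      matched$namespace %in% c("kegg.compound", "obo.chebi")])
    me_ns <- matched$namespace[match(me_ids, matched$externalId)]
    me <- data.frame(
      id = sprintf("ME%03d", seq_along(me_ids)),
      name = if (length(me_ids)) paste("compound", me_ids) else character(),
      type = rep("compound", length(me_ids)),
      external_ids = paste0(me_ns, ":", me_ids, recycle0 = TRUE),
      stringsAsFactors = FALSE)

    pr_ids <- unique(matched$externalId[matched$namespace == "kegg.reaction"])
    ec_pool <- unique(matched$externalId[matched$namespace == "ec-code"])
    pr <- data.frame(
      id = sprintf("PR%03d", seq_along(pr_ids)),
      name = if (length(pr_ids)) paste("process", pr_ids) else character(),
      ec_numbers = if (length(ec_pool))
        sample(ec_pool, length(pr_ids), replace = TRUE) else
        rep("", length(pr_ids)),
      external_ids = paste0("kegg.reaction:", pr_ids, recycle0 = TRUE),
      stringsAsFactors = FALSE)

    # every process gets 1-2 molecular-entity participants
    pp_rows <- list()
    if (nrow(pr) && nrow(me)) {
      for (i in seq_len(nrow(pr))) {
        k <- sample(1:2, 1)
        ents <- sample(me$id, min(k, nrow(me)))
        pp_rows[[i]] <- data.frame(
          process_id = pr$id[i], molecular_entity_id = ents,
          role = sample(c("substrate", "product"), length(ents),
                        replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    pp <- if (length(pp_rows)) do.call(rbind, pp_rows) else
      data.frame(process_id = character(), molecular_entity_id = character(),
                 role = character(), stringsAsFactors = FALSE)

    og <- data.frame(
      id = c("OG1", "OG2"),
      name = c("vertebrates", "microbes"),
      ncbi_taxonomy_ids = c("9606;10090", "4932;562;5691"),
      stringsAsFactors = FALSE)

    pw_ids <- unique(matched$externalId[matched$namespace == "kegg.pathway"])
    pw <- data.frame(
      id = sprintf("PW%03d", seq_along(pw_ids)),
      name = if (length(pw_ids)) paste("pathway", pw_ids) else character(),
      organism_group_id = if (length(pw_ids))
        sample(og$id, length(pw_ids), replace = TRUE) else character(),
      external_ids = if (length(pw_ids))
        paste0("kegg.pathway:", pw_ids) else character(),
      stringsAsFactors = FALSE)

    pwp <- if (nrow(pw) && nrow(pr)) {
      do.call(rbind, lapply(seq_len(nrow(pw)), function(i) data.frame(
        pathway_id = pw$id[i],
        process_id = sample(pr$id, min(2L, nrow(pr))),
        stringsAsFactors = FALSE)))
    } else data.frame(pathway_id = character(), process_id = character(),
                      stringsAsFactors = FALSE)

    gt <- data.frame(
      go_id = ledger$go$terms$goId,
      name = ledger$go$terms$name,
      parent_ids = vapply(ledger$go$terms$goId, function(g) paste(
        ledger$go$parents$parentId[ledger$go$parents$goId == g],
        collapse = ";"), character(1)),
      stringsAsFactors = FALSE)

    ec <- data.frame(ec_number = ec_pool,
                     name = if (length(ec_pool)) paste("enzyme", ec_pool)
                       else character(),
                     stringsAsFactors = FALSE)

    wt <- function(df, file) utils::write.table(
      df, file.path(dir, file), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(me, "molecular_entities.tsv")
    wt(pr, "processes.tsv")
    wt(pp, "process_participants.tsv")
    wt(pw, "pathways.tsv")
    wt(pwp, "pathway_processes.tsv")
    wt(og, "organism_groups.tsv")
    wt(gt, "go_terms.tsv")
    wt(ec, "ec_numbers.tsv")

    # expected mapping rows = matched planted links resolved to entity ids
    expected <- list()
    add_expected <- function(rows, target_ids, table) {
      if (!nrow(rows)) return(invisible())
      expected[[length(expected) + 1L]] <<- data.frame(
        model = rows$model, subject = rows$subject,
        subjectKind = rows$subjectKind, target = target_ids,
        qualifier = rows$qualifier, table = table, stringsAsFactors = FALSE)
    }
    msp <- matched[matched$namespace %in% c("kegg.compound", "obo.chebi") &
                   matched$subjectKind == "species", , drop = FALSE]
    add_expected(msp, me$id[match(msp$externalId, me_ids)],
                 "MapSpeciesMolecularEntities")
    mrx <- matched[matched$namespace == "kegg.reaction" &
                   matched$subjectKind == "reaction", , drop = FALSE]
    add_expected(mrx, pr$id[match(mrx$externalId, pr_ids)],
                 "MapReactionsProcessEntities")
    mpw <- matched[matched$namespace == "kegg.pathway" &
                   matched$subjectKind == "model", , drop = FALSE]
    add_expected(mpw, pw$id[match(mpw$externalId, pw_ids)],
                 "MapModelsPathways")
    expected <- if (length(expected)) do.call(rbind, expected) else
      data.frame(model = character(), subject = character(),
                 subjectKind = character(), target = character(),
                 qualifier = character(), table = character(),
                 stringsAsFactors = FALSE)
    # duplicate planted links (same subject, target, qualifier) collapse in
    # the store; collapse them in the expectation too
    expected <- expected[!duplicated(expected), , drop = FALSE]
    rownames(expected) <- NULL
    ledger$expected <- expected
    ledger$pathway_entities <- list(molecular_entities = me, processes = pr,
                                    pathways = pw)
    ledger
  })
}

#' Write a fixture ledger as JSON
#' @param ledger fixture ledger.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Generate an Erdos-Renyi-style random DAG
#'
#' Nodes are ranked; each pair (i < j) is an edge with probability
#' `edge_prob`, so the graph is acyclic by construction.
#'
#' @param n number of nodes.
#' @param edge_prob edge probability between ranked pairs.
#' @param seed integer seed (mandatory).
#' @return an [sb_dag()].
#' @export
generate_random_dag <- function(n, edge_prob, seed) {
  stopifnot(n >= 0, edge_prob >= 0, edge_prob <= 1)
  .with_seed(seed, {
    nodes <- if (n > 0) sprintf("n%05d", seq_len(n)) else character()
    if (n < 2) return(sb_dag(NULL, nodes = nodes))
    from <- sequence(seq_len(n - 1L))
    to <- rep(2:n, times = seq_len(n - 1L))
    keep <- stats::runif(length(from)) < edge_prob
    sb_dag(data.frame(parent = nodes[from[keep]], child = nodes[to[keep]],
                      stringsAsFactors = FALSE), nodes = nodes)
  })
}

#' Generate an ontology-like sparse DAG
#'
#' A random recursive tree (every node gets one parent uniformly among
#' earlier nodes) in which a fraction of nodes receive one extra parent —
#' the shallow, sparse, multi-parent shape of ontology is-a graphs.  Path
#' counts stay small, which is the regime the NodeCodes labeling is
#' designed for.
#'
#' @param n number of nodes.
#' @param extra_parent_prob probability that a node has a second parent.
#' @param seed integer seed (mandatory).
#' @return an [sb_dag()].
#' @export
generate_ontology_dag <- function(n, extra_parent_prob = 0.05, seed) {
  stopifnot(n >= 0, extra_parent_prob >= 0, extra_parent_prob <= 1)
  .with_seed(seed, {
    nodes <- if (n > 0) sprintf("t%06d", seq_len(n)) else character()
    if (n < 2) return(sb_dag(NULL, nodes = nodes))
    parent1 <- vapply(2:n, function(j) sample.int(j - 1L, 1L), integer(1))
    edges <- data.frame(parent = nodes[parent1], child = nodes[2:n],
                        stringsAsFactors = FALSE)
    extra <- which(stats::runif(n - 1L) < extra_parent_prob & (2:n) > 2L)
    if (length(extra)) {
      j <- extra + 1L
      parent2 <- vapply(j, function(jj) {
        p <- sample.int(jj - 1L, 1L)
        if (nodes[p] == edges$parent[jj - 1L]) p <- if (p == 1L) 2L else
          p - 1L
        p
      }, integer(1))
      edges <- rbind(edges, data.frame(parent = nodes[parent2],
                                       child = nodes[j],
                                       stringsAsFactors = FALSE))
    }
    sb_dag(edges, nodes = nodes)
  })
}
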