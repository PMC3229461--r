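test_that("record counts match an independent XML element walk", {
  doc <- toy_sbml()
  b <- parse_sbml_document(doc, "ds1", deterministic_ids = TRUE)
  walk <- xml_walk_counts(doc)
  expect_equal(nrow(b$species), walk$species)
  expect_equal(nrow(b$reactions), walk$reactions)
  expect_equal(nrow(b$compartments), walk$compartments)
  expect_equal(nrow(b$reaction_species),
               walk$reactants_products + walk$modifiers)
  expect_equal(nrow(b$kinetic_laws), walk$kinetic_laws)
  expect_equal(sort(b$reaction_species$roleId),
               sort(c("reactant", "reactant", "product")))
})

test_that("sbmlId is preserved exactly once per identified element", {
  doc <- toy_sbml("Hynne2001_Glycolysis", with_name = FALSE)
  b <- parse_sbml_document(doc, "ds1", deterministic_ids = TRUE)
  expect_identical(b$model$sbmlId, "Hynne2001_Glycolysis")
  expect_true(is.na(b$model$name))
  all_sbml_ids <- c(b$model$sbmlId, b$species$sbmlId, b$reactions$sbmlId,
                    b$compartments$sbmlId, b$kinetic_law_parameters$sbmlId)
  expect_false(anyDuplicated(all_sbml_ids) > 0)
  # every id attribute in the document is held by exactly one record
  doc_ids <- xml2::xml_attr(
    xml2::xml_find_all(xml2::read_xml(doc), "//*[@id]"), "id")
  expect_setequal(doc_ids, all_sbml_ids)
})

test_that("every non-DataSource record exposes the four Sbase fields", {
  b <- parse_sbml_document(toy_sbml(), "ds1", deterministic_ids = TRUE)
  sbase <- c("id", "metaId", "sboTerm", "notes", "annotation")
  for (tab in names(b)) {
    if (tab == "unit_compositions") next  # composition rows, not entities
    expect_true(all(sbase %in% names(b[[tab]])), info = tab)
  }
})

test_that("minimal model parses to a bundle with only a model record", {
  doc <- paste0('<?xml version="1.0"?>',
                '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2"',
                ' version="3"><model id="empty"><listOfSpecies/></model>',
                '</sbml>')
  b <- parse_sbml_document(doc, "ds1", deterministic_ids = TRUE)
  expect_equal(nrow(b$species), 0L)
  expect_equal(nrow(b$reactions), 0L)
  expect_identical(b$model$sbmlId, "empty")
  expect_identical(b$model$sbmlVersion, 3L)
})

test_that("malformed XML, wrong level and duplicate ids are rejected", {
  expect_error(parse_sbml_document("<sbml><model>", "ds1"),
               "malformed XML")
  l3 <- paste0('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
               ' level="3" version="1"><model id="m"/></sbml>')
  expect_error(parse_sbml_document(l3, "ds1"), "unsupported SBML level")
  dup <- paste0('<?xml version="1.0"?>',
                '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2"',
                ' version="1"><model id="m"><listOfCompartments>',
                '<compartment id="c"/></listOfCompartments><listOfSpecies>',
                '<species id="c" compartment="c"/>',
                '</listOfSpecies></model></sbml>')
  expect_error(parse_sbml_document(dup, "ds1"), "duplicate sbmlId")
})

test_that("SBML defaults apply and absent attributes stay absent", {
  doc <- paste0('<?xml version="1.0"?>',
                '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2"',
                ' version="1"><model id="m"><listOfCompartments>',
                '<compartment id="c"/></listOfCompartments><listOfSpecies>',
                '<species id="s" compartment="c"/></listOfSpecies>',
                '<listOfReactions><reaction id="r"><listOfReactants>',
                '<speciesReference species="s"/></listOfReactants>',
                '</reaction></listOfReactions></model></sbml>')
  b <- parse_sbml_document(doc, "ds1", deterministic_ids = TRUE)
  expect_true(b$reactions$reversible)       # SBML default
  expect_false(b$species$constant)          # SBML default
  expect_false(b$species$boundaryCondition)
  expect_true(is.na(b$species$initialAmount))
  expect_true(is.na(b$species$initialConcentration))
  expect_true(is.na(b$species$charge))
  expect_equal(b$reaction_species$stoichiometry, 1)  # SBML default
})

test_that("species referencing an unknown compartment is an integrity error", {
  doc <- paste0('<?xml version="1.0"?>',
                '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2"',
                ' version="1"><model id="m"><listOfSpecies>',
                '<species id="s" compartment="nowhere"/>',
                '</listOfSpecies></model></sbml>')
  expect_error(parse_sbml_document(doc, "ds1"), "unknown compartment")
})

test_that("function references resolve to arguments with kinds", {
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfFunctionDefinitions>',
    '<functionDefinition id="pow3">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><lambda>',
    '<bvar><ci>x</ci></bvar><apply><power/><ci>x</ci><cn>3</cn></apply>',
    '</lambda></math></functionDefinition></listOfFunctionDefinitions>',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="S1" compartment="c"/></listOfSpecies>',
    '</model></sbml>')
  b <- parse_sbml_document(doc, "ds1", deterministic_ids = TRUE)

  m1 <- paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<apply><ci>pow3</ci><ci>S1</ci></apply></math>')
  args <- resolve_function_references(m1, b)
  expect_setequal(args$kind, c("function", "species"))
  frow <- args[args$kind == "function", ]
  expect_identical(frow$symbol, "pow3")
  expect_identical(frow$functionId, b$function_definitions$id[1])

  # numeric-literal-only expression has no arguments
  m2 <- paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<cn>42</cn></math>')
  expect_equal(nrow(resolve_function_references(m2, b)), 0L)

  # unresolved identifiers are flagged, not fatal
  m3 <- paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<ci>mystery</ci></math>')
  expect_identical(resolve_function_references(m3, b)$kind, "unresolved")
})

test_that("unit definitions partition into base and user units", {
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfUnitDefinitions>',
    '<unitDefinition id="mmol_per_l"><listOfUnits>',
    '<unit kind="mole" scale="-3"/>',
    '<unit kind="litre" exponent="-1"/>',
    '</listOfUnits></unitDefinition></listOfUnitDefinitions></model></sbml>')
  b <- parse_sbml_document(doc, "ds1", deterministic_ids = TRUE)
  u <- normalize_unit_definitions(b)
  expect_equal(nrow(u$user), 1L)
  expect_equal(nrow(u$compositions), 2L)
  expect_false(any(is.na(u$user$modelId)))  # user units carry the model id
  expect_equal(u$compositions$scale, c(-3L, 0L))
  expect_equal(u$compositions$exponent, c(1L, -1L))

  # a unit composed of another user unit is rejected
  bad <- b
  bad$unit_compositions$baseUnitKind[1] <- "mmol_per_l"
  expect_error(normalize_unit_definitions(bad), "non-base unit")

  # built-in base units live outside any model
  st <- store_open(":memory:")
  on.exit(store_close(st))
  second <- sbpathdb:::st_query(
    st, "SELECT modelId FROM UnitDefinition WHERE sbmlId = 'second'")
  expect_equal(nrow(second), 1L)
  expect_true(is.na(second$modelId))
})

test_that("directory ingest parses every file and can skip broken ones", {
  td <- withr::local_tempdir()
  writeLines(toy_sbml("m1"), file.path(td, "m1.xml"))
  writeLines(toy_sbml("m2"), file.path(td, "m2.xml"))
  writeLines("<broken", file.path(td, "m3.xml"))
  expect_error(parse_sbml_directory(td, "ds1"), "malformed")
  expect_warning(
    bundles <- parse_sbml_directory(td, "ds1", on_error = "skip"),
    "skipping")
  expect_length(bundles, 2L)
  expect_identical(bundles[["m1.xml"]]$model$sbmlId, "m1")
})
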