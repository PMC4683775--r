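odm_header <- '<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3">'

test_that("import maps tags to categories and attributes to slots", {
  m <- example_domain_model()
  doc <- paste0(odm_header, '<Study OID="S1"/></ODM>')
  ids <- import_xml(m, odm_mapping(), doc)
  expect_length(ids, 1L)
  expect_identical(m$instances[[ids[1]]]$category, "Study")
  expect_identical(slot_value1(m, ids[1], ":NAME"), "S1")
})

test_that("import follows declared subtags, fills text slots and nests containment", {
  m <- example_domain_model()
  doc <- paste0(odm_header,
    '<Study OID="S1">',
    '<GlobalVariables><StudyName>LIFE pilot</StudyName></GlobalVariables>',
    '<MetaDataVersion>',
    '<ItemGroupDef OID="IG1" Name="Socio-demographic data">',
    '<ItemDef OID="IT1" Name="AGE" DataType="integer">',
    '<Description><TranslatedText>Age in years</TranslatedText></Description>',
    '</ItemDef>',
    '</ItemGroupDef>',
    '</MetaDataVersion></Study></ODM>')
  ids <- import_xml(m, odm_mapping(), doc)
  study <- ids[1]
  expect_identical(slot_value1(m, study, "name"), "LIFE pilot")
  kids <- contained_children(m, study)
  expect_length(kids, 1L)
  expect_identical(m$instances[[kids]]$category, "Module")
  item <- contained_children(m, kids)
  expect_identical(slot_value1(m, item, "description"), "Age in years")
  expect_identical(slot_value1(m, item, "data_type"), "integer")
})

test_that("reference tags resolve through their key attribute", {
  m <- example_domain_model()
  doc <- paste0(odm_header,
    '<Study OID="S1"><MetaDataVersion>',
    '<ItemGroupDef OID="IG1" Name="G">',
    '<ItemDef OID="IT1" Name="DYSPNEA"><CodeListRef CodeListOID="CL1"/></ItemDef>',
    '</ItemGroupDef>',
    '<CodeList OID="CL1" Name="YesNo">',
    '<CodeListItem CodedValue="YES"/><CodeListItem CodedValue="NO"/>',
    '</CodeList>',
    '</MetaDataVersion></Study></ODM>')
  import_xml(m, odm_mapping(), doc)
  item <- instances_of(m, "Item")[1]
  cl <- slot_value1(m, item, "codelist")
  expect_identical(m$instances[[cl]]$category, "Codelist")
  expect_identical(unlist(slot_value(m, cl, "codes")), c("YES", "NO"))
  # codelists are definitions, not part of the study hierarchy
  expect_null(studyframes:::containment_parent(m, cl))
})

test_that("root mismatch and unmapped elements are rejected in strict mode", {
  m <- example_domain_model()
  expect_error(import_xml(m, odm_mapping(),
                          '<Wrong xmlns="http://www.cdisc.org/ns/odm/v1.3"/>'),
               class = "studyframes_root_mismatch")
  expect_error(import_xml(m, odm_mapping(), "<ODM/>"),
               class = "studyframes_root_mismatch")
  bad <- paste0(odm_header, '<Study OID="S"><Bogus/></Study></ODM>')
  expect_error(import_xml(m, odm_mapping(), bad),
               class = "studyframes_unmapped")
  # lenient mode skips and continues
  m2 <- example_domain_model()
  ids <- import_xml(m2, odm_mapping(), bad, strict = FALSE)
  expect_length(ids, 1L)
})

test_that("export inverts import and omits empty optional attributes", {
  m <- example_domain_model()
  s <- create_instance(m, "Study", list(`:NAME` = "S1"))$id
  doc <- export_xml(m, odm_mapping(), s)
  study_el <- xml2::xml_find_first(doc, "//*[local-name()='Study']")
  expect_identical(xml2::xml_attr(study_el, "OID"), "S1")
  # name slot empty: no StudyName element
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='StudyName']"), 0L)
  # no instances at all: document still has its root element
  empty <- export_xml(example_domain_model(), odm_mapping(), character())
  expect_identical(xml2::xml_name(xml2::xml_root(empty)), "ODM")
})

test_that("export is byte-stable across runs", {
  p <- generate_random_project(8, seed = 11)
  a <- as.character(generate_odm_document(p))
  b <- as.character(generate_odm_document(p))
  expect_identical(a, b)
})

test_that("ODM round trip is isomorphic on generated projects", {
  for (seed in 1:10) {
    p <- generate_random_project(n_items = 5 + (seed %% 7), seed = seed)
    doc <- generate_odm_document(p)
    m2 <- example_domain_model()
    import_xml(m2, odm_mapping(), doc)
    expect_true(projects_isomorphic(p, m2), label = sprintf("seed %d", seed))
    # and the re-export is canonically equivalent XML
    expect_true(xml_equivalent(doc, generate_odm_document(m2)),
                label = sprintf("xml seed %d", seed))
  }
})

test_that("import leaves the mapping document untouched", {
  mp <- odm_mapping()
  before <- mapping_to_list(mp)
  m <- example_domain_model()
  import_xml(m, mp, paste0(odm_header, '<Study OID="S1"/></ODM>'))
  expect_identical(mapping_to_list(mp), before)
})

test_that("mapping documents round-trip through their JSON form", {
  mp <- odm_mapping()
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_mapping(mp, f)
  expect_identical(mapping_to_list(load_mapping(f)), mapping_to_list(mp))
  # and the copy shipped under extdata matches the built-in mapping
  shipped <- system.file("extdata", "odm.mapping.json", package = "studyframes")
  expect_identical(mapping_to_list(load_mapping(shipped)), mapping_to_list(mp))
})

test_that("table import/export round-trips slot values", {
  m <- example_domain_model()
  mp <- table_mapping("items-csv", "Item",
                      c(name = "name", description = "description",
                        data_type = "data_type"))
  df <- data.frame(name = c("AGE", "SEX"),
                   description = c("Age in years", ""),
                   data_type = c("integer", "text"),
                   stringsAsFactors = FALSE)
  ids <- import_table(m, mp, df)
  expect_length(ids, 2L)
  expect_identical(slot_value1(m, ids[1], "name"), "AGE")
  expect_null(slot_value1(m, ids[2], "description"))

  out <- export_table(m, mp, ids)
  expect_identical(out$name, df$name)
  expect_identical(out$description, df$description)
  expect_identical(out$data_type, df$data_type)

  # header-only export for zero instances
  expect_identical(nrow(export_table(m, mp, character())), 0L)

  # errors: missing mapped column, duplicate headers
  expect_error(import_table(m, mp, data.frame(name = "A")),
               class = "studyframes_invalid")
  dup <- df; names(dup) <- c("name", "name", "data_type")
  expect_error(import_table(m, mp, dup), class = "studyframes_invalid")
})

test_that("table and XML paths yield slot-identical instances from equivalent content", {
  mx <- example_domain_model()
  import_xml(mx, odm_mapping(), paste0(odm_header,
    '<Study OID="S1"><MetaDataVersion>',
    '<ItemGroupDef OID="IG1" Name="G">',
    '<ItemDef OID="IT1" Name="AGE" DataType="integer"/>',
    '</ItemGroupDef></MetaDataVersion></Study></ODM>'))
  mt <- example_domain_model()
  tid <- import_table(mt, table_mapping("t", "Item",
                                        c(`:NAME` = ":NAME", Name = "name",
                                          DataType = "data_type")),
                      data.frame(`:NAME` = "IT1", Name = "AGE",
                                 DataType = "integer", check.names = FALSE))
  xid <- instances_of(mx, "Item")[1]
  expect_identical(mx$instances[[xid]]$slot_values,
                   mt$instances[[tid]]$slot_values)
})

test_that("CRF preview renders groups as headings and items as fields", {
  m <- build_example_project()
  page <- instances_of(m, "Page")[1]
  txt <- render_crf_preview(m, page)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "# B1")
  expect_true(any(grepl("^## Socio-demographic data", lines)))
  expect_true(any(grepl("DYSPNEA_AT_REST.*\\[YES \\| NO\\]", lines)))
  expect_true(any(grepl("SYSTOLIC_BLOOD_PRESURE.*\\(mmHg\\)", lines)))
  # empty group: heading only
  m2 <- example_domain_model()
  g <- create_instance(m2, "Page", list(name = "Empty"))$id
  expect_identical(render_crf_preview(m2, g), "# Empty\n")
  # non-group roots are rejected
  it <- create_instance(m2, "Item", list(name = "I"))$id
  expect_error(render_crf_preview(m2, it), class = "studyframes_not_group")
})
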