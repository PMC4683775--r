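test_that("bootstrapped task ontology has the expected shape", {
  m <- bootstrap_task_ontology()
  expect_setequal(category_children(m, "_ELEMENT"),
                  c("_CONSTANT", "_OBJECT", "_GROUP", "_ANNOTATION", "_EXPORT"))
  expect_true(all(c("_FORMAT_MAPPING", "_ANNOTATION_TYPE") %in%
                    category_children(m, "_CONFIG")))
  expect_true(all(c("_MATH_EXPRESSION_RELATOR", "_NUMBER", "_STUDY_ELEMENT")
                  %in% category_children(m, "_MATH")))
  expect_true(m$categories[["_FORMAT_MAPPING"]]$hidden)
  expect_true(m$categories[["_CONFIG"]]$hidden)
  ann_slots <- m$categories[["_ANNOTATING_ONTOLOGY_ROOT"]]$template_slots
  expect_identical(ann_slots[["_annotations"]]$inverse_of,
                   "_annotating_concepts")
  slots <- names(m$categories[["_ANNOTATION"]]$template_slots)
  expect_true(all(c("_annotated_elements", "_annotation_type",
                    "_annotating_concepts") %in% slots))
  expect_true("_contains" %in% names(m$categories[["_GROUP"]]$template_slots))
})

test_that("bootstrap is idempotent and hidden status is closed downward", {
  expect_identical(model_to_list(bootstrap_task_ontology()),
                   model_to_list(bootstrap_task_ontology()))
  m <- bootstrap_task_ontology()
  hidden <- vapply(m$categories, function(c) isTRUE(c$hidden), TRUE)
  for (nm in names(m$categories)[hidden]) {
    for (kid in category_children(m, nm)) {
      expect_true(m$categories[[kid]]$hidden,
                  label = sprintf("child %s of hidden %s is hidden", kid, nm))
    }
  }
  # hidden closure also holds for categories added later under hidden parents
  add_category <- studyframes:::add_category
  add_category(m, "X_TAG", parent = "_TAG")
  expect_true(m$categories[["X_TAG"]]$hidden)
})

test_that("define_category places domain categories and inherits slots", {
  m <- bootstrap_task_ontology()
  define_category(m, "Item", "_OBJECT",
                  slots = list(slot_definition("name", cardinality_min = 1),
                               slot_definition("description"),
                               slot_definition("unit_of_measure"),
                               slot_definition("range"),
                               slot_definition("codelist"),
                               slot_definition("rules")))
  expect_length(m$categories[["Item"]]$template_slots, 6L)
  expect_identical(m$categories[["Item"]]$layer, "DO")
  define_category(m, "Study", "_GROUP")
  expect_true(category_is_a(m, "Study", "_GROUP"))
  # groups pass their _contains template slot down
  expect_true("_contains" %in% names(studyframes:::effective_slots(m, "Study")))
  expect_error(define_category(m, "Item", "_OBJECT"),
               class = "studyframes_duplicate")
  expect_error(define_category(m, "Z", "NoSuchParent"),
               class = "studyframes_unknown")
  expect_error(define_category(m, "MyTag", "_FORMAT_MAPPING"),
               class = "studyframes_hidden_parent")
})

test_that("create_instance enforces category, slots and value kinds", {
  m <- example_domain_model()
  mod <- create_instance(m, "Module", list(name = "Socio-demographic data"))
  expect_identical(slot_value1(m, mod$id, "name"), "Socio-demographic data")
  it <- create_instance(m, "Item", list(name = "DYSPNEA_AT_REST"))
  expect_true(is_instance_of(m, it$id, "_OBJECT"))
  expect_error(create_instance(m, "NoSuchClass", list()),
               class = "studyframes_unknown")
  expect_error(create_instance(m, "_ELEMENT", list()),
               class = "studyframes_abstract")
  expect_error(create_instance(m, "Item", list(bogus = "x")),
               class = "studyframes_unknown_slot")
  # value_kind is authoritative; numeric-looking strings are kept as strings
  cl <- create_instance(m, "Codelist", list(codes = list("01", "02")))
  expect_identical(slot_value(m, cl$id, "codes"), list("01", "02"))
  expect_error(create_instance(m, "Item", list(name = 12)),
               class = "studyframes_kind_mismatch")
  # ids come from a deterministic per-model counter
  m2 <- example_domain_model()
  a <- create_instance(m2, "Module", list(name = "a"))$id
  b <- create_instance(m2, "Module", list(name = "b"))$id
  expect_identical(c(a, b), c("inst-1", "inst-2"))
})

test_that("validate_instance reports cardinality and facet breaches as data", {
  m <- bootstrap_task_ontology()
  define_category(m, "Measurement", "_OBJECT", slots = list(
    slot_definition("name", cardinality_min = 1),
    slot_definition("value", value_kind = "number",
                    facets = facet_set(minimum = 0, maximum = 150)),
    slot_definition("status",
                    facets = facet_set(allowed_values = c("ok", "bad")))))
  missing <- create_instance(m, "Measurement", list())
  v <- validate_instance(m, missing)
  expect_length(v, 1L)
  expect_identical(v[[1]]$kind, "missing-value")

  toohigh <- create_instance(m, "Measurement",
                             list(name = "sbp", value = 200))
  v <- validate_instance(m, toohigh)
  expect_length(v, 1L)
  expect_identical(v[[1]]$kind, "facet")

  bad_enum <- create_instance(m, "Measurement",
                              list(name = "x", status = "odd"))
  expect_identical(validate_instance(m, bad_enum)[[1]]$kind, "facet")

  ok <- create_instance(m, "Measurement", list(name = "sbp", value = 120,
                                               status = "ok"))
  expect_identical(validate_instance(m, ok), list())

  # validation is pure: the serialized model is unchanged
  before <- model_to_list(m)
  invisible(validate_instance(m, toohigh))
  expect_identical(model_to_list(m), before)
})

test_that("instance references are validated against facets and existence", {
  m <- example_domain_model()
  cl <- create_instance(m, "Codelist", list(codes = "YES"))$id
  it <- create_instance(m, "Item", list(name = "A", codelist = cl))$id
  expect_identical(validate_instance(m, it), list())
  dangling <- create_instance(m, "Item",
                              list(name = "B", codelist = "inst-999"))$id
  kinds <- vapply(validate_instance(m, dangling), `[[`, "", "kind")
  expect_true("unresolved-reference" %in% kinds)
  # allowed_categories facet: an Item is not a Codelist
  wrong <- create_instance(m, "Item", list(name = "C", codelist = it))$id
  kinds <- vapply(validate_instance(m, wrong), `[[`, "", "kind")
  expect_true("facet" %in% kinds)
})

test_that("annotation instances keep the concept-side inverse consistent", {
  m <- build_example_project()
  for (aid in names(m$annotations)) {
    a <- m$annotations[[aid]]
    for (cid in a$concepts) {
      expect_true(aid %in% m$concept_index[[cid]])
    }
  }
  for (cid in names(m$concept_index)) {
    for (aid in m$concept_index[[cid]]) {
      expect_true(cid %in% m$annotations[[aid]]$concepts)
    }
  }
})
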