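mini_obo <- function() {
  c("format-version: 1.2",
    "ontology: test-onto",
    "",
    "[Term]",
    "id: T:1",
    "name: Root finding",
    "",
    "[Term]",
    "id: T:2",
    "name: Congestive heart failure",
    "is_a: T:1 ! Root finding",
    "",
    "[Term]",
    "id: T:3",
    "name: Elevated systolic blood pressure",
    "is_a: T:1",
    "",
    "[Term]",
    "id: T:4",
    "is_a: T:2",
    "",
    "[Term]",
    "id: T:9",
    "name: Gone",
    "is_obsolete: true")
}

test_that("load_obo honours id, name, is_a and skips obsolete terms", {
  m <- bootstrap_task_ontology()
  n <- load_obo(m, mini_obo())
  expect_identical(n, 4L)
  expect_identical(m$concepts[["T:2"]]$label, "Congestive heart failure")
  expect_identical(m$concepts[["T:2"]]$parents, "T:1")
  # term without a name falls back to its id as label
  expect_identical(m$concepts[["T:4"]]$label, "T:4")
  expect_false("T:9" %in% names(m$concepts))
  expect_identical(m$concepts[["T:1"]]$ontology, "test-onto")
  # duplicate ids are rejected
  expect_error(load_obo(m, mini_obo()), class = "studyframes_duplicate")
  # is_a cycles are rejected
  m2 <- bootstrap_task_ontology()
  expect_error(load_obo(m2, c("[Term]", "id: A:1", "is_a: A:2",
                              "[Term]", "id: A:2", "is_a: A:1")),
               class = "studyframes_cycle")
})

test_that("several ontologies can be loaded side by side", {
  m <- bootstrap_task_ontology()
  load_obo(m, c("[Term]", "id: X:1", "name: x"), ontology = "ont-x")
  load_obo(m, c("[Term]", "id: Y:1", "name: y"), ontology = "ont-y")
  expect_identical(m$concepts[["X:1"]]$ontology, "ont-x")
  expect_identical(m$concepts[["Y:1"]]$ontology, "ont-y")
})

test_that("annotation types are unique named instances of _ANNOTATION_TYPE", {
  m <- bootstrap_task_ontology()
  id1 <- define_annotation_type(m, "symptom_of")
  id2 <- define_annotation_type(m, "risk_factor_of")
  expect_true(is_instance_of(m, id1, "_ANNOTATION_TYPE"))
  expect_false(identical(id1, id2))
  expect_error(define_annotation_type(m, "symptom_of"),
               class = "studyframes_duplicate")
})

test_that("create_annotation validates codes, ranges and concepts", {
  m <- build_example_project()
  dys <- instances_of(m, "Item")[1]
  sbp <- instances_of(m, "Item")[2]
  expect_error(create_annotation(m, element_condition(dys, code = "MAYBE"),
                                 "symptom_of", "MP:0001635"),
               class = "studyframes_invalid")
  expect_error(create_annotation(m, element_condition(dys, range = "[1;2]"),
                                 "symptom_of", "MP:0001635"),
               class = "studyframes_invalid")
  expect_error(create_annotation(m, element_condition(sbp, range = "[121;]"),
                                 "symptom_of", "NO:SUCH"),
               class = "studyframes_unknown")
  expect_error(create_annotation(m, element_condition(sbp, code = "YES"),
                                 "symptom_of", "MP:0001635"),
               class = "studyframes_invalid")  # no codelist on sbp
  ann <- create_annotation(m,
                           list(element_condition(dys, code = "NO"),
                                element_condition(sbp, range = "[0;120]")),
                           "risk_factor_of", c("MP:0001626", "MP:0000001"))
  expect_length(ann$conditions, 2L)
  expect_true(is_instance_of(m, ann$id, "_ANNOTATION"))
})

test_that("evaluate_annotation ANDs element/value conditions", {
  m <- build_example_project()
  dys_ann <- annotations_of_concept(m, "MP:0001635")[[1]]
  sbp_ann <- annotations_of_concept(m, "MP:0004421")[[1]]
  dys <- dys_ann$conditions[[1]]$element
  sbp <- sbp_ann$conditions[[1]]$element

  expect_true(evaluate_annotation(dys_ann, stats::setNames(list("YES"), dys)))
  expect_false(evaluate_annotation(dys_ann, stats::setNames(list("NO"), dys)))
  expect_false(evaluate_annotation(dys_ann, list()))

  expect_true(evaluate_annotation(sbp_ann, stats::setNames(list(121), sbp)))
  expect_false(evaluate_annotation(sbp_ann, stats::setNames(list(120), sbp)))
  expect_true(evaluate_annotation(sbp_ann, stats::setNames(list("130"), sbp)))
  # non-numeric against a range: condition is false, not an error
  expect_false(evaluate_annotation(sbp_ann, stats::setNames(list("high"), sbp)))

  # multi-condition annotation needs every condition to hold
  both <- create_annotation(m,
                            list(element_condition(dys, code = "YES"),
                                 element_condition(sbp, range = "[121;]")),
                            "risk_factor_of", "MP:0001626")
  rec <- stats::setNames(list("YES", 140), c(dys, sbp))
  expect_true(evaluate_annotation(both, rec))
  rec[[sbp]] <- 100
  expect_false(evaluate_annotation(both, rec))
  rec[[sbp]] <- NULL
  expect_false(evaluate_annotation(both, rec))
})

test_that("empty records never satisfy an annotation", {
  m <- build_example_project()
  for (aid in names(m$annotations)) {
    expect_false(evaluate_annotation(m$annotations[[aid]], list()))
  }
})

test_that("concept queries return annotations of the concept and optionally descendants", {
  m <- build_example_project()
  chf <- annotations_of_concept(m, "MP:0001635", include_subclasses = FALSE)
  expect_length(chf, 1L)
  expect_identical(chf[[1]]$conditions[[1]]$code, "YES")
  # parent concept only collects through the subclass closure
  expect_length(annotations_of_concept(m, "MP:0001626", FALSE), 0L)
  up <- annotations_of_concept(m, "MP:0001626", TRUE)
  expect_length(up, 2L)
  expect_length(annotations_of_concept(m, "MP:0000001", TRUE), 2L)
  expect_error(annotations_of_concept(m, "NO:SUCH"),
               class = "studyframes_unknown")
  # monotone: subclass closure only adds
  for (cid in names(m$concepts)) {
    narrow <- vapply(annotations_of_concept(m, cid, FALSE), `[[`, "", "id")
    wide <- vapply(annotations_of_concept(m, cid, TRUE), `[[`, "", "id")
    expect_true(all(narrow %in% wide))
  }
})

test_that("inverse index equals a full scan after randomized create/delete sequences", {
  set.seed(501)
  m <- build_example_project()
  dys <- annotations_of_concept(m, "MP:0001635")[[1]]$conditions[[1]]$element
  sbp <- annotations_of_concept(m, "MP:0004421")[[1]]$conditions[[1]]$element
  pool <- names(m$concepts)
  for (step in 1:80) {
    if (length(m$annotations) == 0L || stats::runif(1) < 0.6) {
      cond <- if (stats::runif(1) < 0.5) {
        element_condition(dys, code = sample(c("YES", "NO"), 1))
      } else {
        element_condition(sbp, range = sprintf("[%d;]", sample(50:200, 1)))
      }
      create_annotation(m, cond, sample(c("symptom_of", "risk_factor_of"), 1),
                        sample(pool, sample(1:3, 1)))
    } else {
      delete_annotation(m, sample(names(m$annotations), 1))
    }
    for (cid in pool) {
      expect_setequal(vapply(annotations_of_concept(m, cid, FALSE),
                             `[[`, "", "id"),
                      brute_annotations_of(m, cid))
    }
  }
})

test_that("range literals parse, test membership, and round-trip", {
  r <- parse_range_literal("[121;]")
  expect_identical(r$lower, 121)
  expect_null(r$upper)
  expect_true(range_contains(r, 121))
  expect_false(range_contains(r, 120.99))

  r2 <- parse_range_literal("[1;5]")
  expect_true(range_contains(r2, 5))   # inclusive upper bound
  expect_true(range_contains(r2, 1))
  expect_false(range_contains(r2, 5.01))

  expect_error(parse_range_literal("[;]"), class = "studyframes_parse")
  expect_error(parse_range_literal("121"), class = "studyframes_parse")
  expect_error(parse_range_literal("[5;1]"), class = "studyframes_parse")

  # parse . format is the identity on well-formed literals
  set.seed(502)
  for (i in 1:50) {
    lo <- sample(c(NA, sample(-50:100, 1)), 1)
    hi <- if (is.na(lo)) sample(0:200, 1) else sample(lo:200, 1)
    txt <- sprintf("[%s;%s]",
                   if (is.na(lo)) "" else lo,
                   if (is.na(hi)) "" else hi)
    expect_identical(format_range_literal(parse_range_literal(txt)), txt)
  }
})
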