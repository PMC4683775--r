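# Project persistence (a single JSON document), structural equality and
# isomorphism, and fixture builders reproducing the worked examples.

PROJECT_FORMAT_VERSION <- "1.0"

KNOWN_PROJECT_FIELDS <- c("format_version", "categories", "instances",
                          "contains_edges", "hierarchy_rules", "concepts",
                          "annotations", "concept_index", "mappings",
                          "counter")

slot_to_list <- function(s) {
  out <- list(name = s$name, value_kind = s$value_kind,
              cardinality_min = s$cardinality_min,
              cardinality_max = if (is.infinite(s$cardinality_max)) "unbounded"
                                else s$cardinality_max)
  f <- s$facets
  fl <- Filter(Negate(is.null),
               list(minimum = f$minimum, maximum = f$maximum,
                    default = f$default,
                    allowed_categories = f$allowed_categories,
                    allowed_values = f$allowed_values))
  if (length(fl)) out$facets <- fl
  if (!is.null(s$inverse_of)) out$inverse_of <- s$inverse_of
  out
}

slot_from_list <- function(x) {
  f <- x$facets %||% list()
  slot_definition(
    x$name, value_kind = x$value_kind,
    cardinality_min = x$cardinality_min,
    cardinality_max = if (identical(x$cardinality_max, "unbounded")) Inf
                      else x$cardinality_max,
    facets = facet_set(minimum = f$minimum %||% NULL,
                       maximum = f$maximum %||% NULL,
                       default = f$default %||% NULL,
                       allowed_categories =
                         unlist(f$allowed_categories %||% NULL),
                       allowed_values = unlist(f$allowed_values %||% NULL)),
    inverse_of = x$inverse_of %||% NULL)
}

#' Serialize a model to a plain list (the project-JSON shape)
#'
#' The list round-trips through JSON: [model_from_list()] restores a
#' structurally identical model. Unknown fields read from a newer-minor
#' project file are preserved and re-emitted.
#'
#' @param model An `ontology_model`.
#' @return A named list with a top-level `format_version`.
#' @export
model_to_list <- function(model) {
  e <- model$contains_edges
  out <- list(
    format_version = PROJECT_FORMAT_VERSION,
    counter = model$counter,
    categories = unname(lapply(model$categories, function(c) {
      list(name = c$name, parent = c$parent, layer = c$layer,
           hidden = isTRUE(c$hidden), abstract = isTRUE(c$abstract),
           template_slots = unname(lapply(c$template_slots, slot_to_list)))
    })),
    instances = unname(lapply(model$instances, function(r) {
      list(id = r$id, category = r$category,
           slot_values = lapply(r$slot_values, function(v) unname(v)))
    })),
    contains_edges = if (nrow(e)) {
      lapply(order(e$parent, e$position), function(i) {
        list(parent = e$parent[i], child = e$child[i],
             position = as.integer(e$position[i]))
      })
    } else list(),
    hierarchy_rules = model$hierarchy_rules,
    concepts = unname(model$concepts),
    annotations = unname(lapply(model$annotations, function(a) {
      list(id = a$id, type = a$type, concepts = as.list(a$concepts),
           conditions = lapply(a$conditions, function(cond) {
             Filter(Negate(is.null),
                    list(element = cond$element, code = cond$code,
                         range = if (!is.null(cond$range))
                           format_range_literal(cond$range)))
           }))
    })),
    mappings = unname(lapply(model$mappings, mapping_to_list))
  )
  c(out, model$extra_fields)
}

require_field <- function(x, field, where) {
  if (is.null(x[[field]])) {
    ose_abort(sprintf("project document lacks required field '%s' at %s",
                      field, where), "studyframes_schema")
  }
  x[[field]]
}

#' @rdname model_to_list
#' @param x A list as produced by `model_to_list()` (e.g., parsed JSON).
#' @export
model_from_list <- function(x) {
  ver <- as.character(require_field(x, "format_version", "$"))
  major <- strsplit(ver, ".", fixed = TRUE)[[1]][1]
  if (!identical(major, strsplit(PROJECT_FORMAT_VERSION, ".",
                                 fixed = TRUE)[[1]][1])) {
    ose_abort(sprintf(
      "project format_version '%s' is not supported (expected %s.x)",
      ver, strsplit(PROJECT_FORMAT_VERSION, ".", fixed = TRUE)[[1]][1]),
      "studyframes_version")
  }
  m <- new_ontology_model()
  for (i in seq_along(require_field(x, "categories", "$"))) {
    c <- x$categories[[i]]
    nm <- require_field(c, "name", sprintf("$.categories[%d]", i))
    add_category(m, nm, parent = json_opt(c$parent),
                 layer = c$layer %||% "DO", hidden = isTRUE(c$hidden),
                 abstract = isTRUE(c$abstract),
                 slots = lapply(c$template_slots %||% list(), slot_from_list))
  }
  for (i in seq_along(require_field(x, "instances", "$"))) {
    r <- x$instances[[i]]
    id <- require_field(r, "id", sprintf("$.instances[%d]", i))
    cat <- require_field(r, "category", sprintf("$.instances[%d]", i))
    if (!category_exists(m, cat)) {
      ose_abort(sprintf("$.instances[%d]: unknown category '%s'", i, cat),
                "studyframes_schema")
    }
    m$instances[[id]] <- list(id = id, category = cat,
                              slot_values = lapply(r$slot_values %||% list(),
                                                   function(v) as.list(v)))
  }
  edges <- x$contains_edges %||% list()
  if (length(edges)) {
    m$contains_edges <- data.frame(
      parent = vapply(edges, function(e) as.character(e$parent), ""),
      child = vapply(edges, function(e) as.character(e$child), ""),
      position = vapply(edges, function(e) as.integer(e$position), 0L),
      stringsAsFactors = FALSE)
  }
  m$hierarchy_rules <- lapply(x$hierarchy_rules %||% list(), function(r) {
    list(upper = r$upper, lower = r$lower)
  })
  for (cc in x$concepts %||% list()) {
    add_concept(m, cc$id, label = cc$label %||% cc$id,
                parents = unlist(cc$parents %||% character()),
                ontology = cc$ontology %||% "default")
  }
  for (a in x$annotations %||% list()) {
    ann <- list(
      id = a$id, type = a$type, concepts = unlist(a$concepts),
      conditions = lapply(a$conditions, function(cond) {
        element_condition(cond$element, code = cond$code %||% NULL,
                          range = cond$range %||% NULL)
      }))
    m$annotations[[ann$id]] <- ann
    for (cid in ann$concepts) {
      m$concept_index[[cid]] <- c(m$concept_index[[cid]], ann$id)
    }
  }
  for (mp in x$mappings %||% list()) {
    mm <- mapping_from_list(mp)
    m$mappings[[mm$name]] <- mm
  }
  m$counter <- as.integer(x$counter %||% length(m$instances))
  m$extra_fields <- x[setdiff(names(x), KNOWN_PROJECT_FIELDS)]
  m
}

#' Save / load a project as a single JSON document
#'
#' @param model An `ontology_model`.
#' @param path File path.
#' @return `load_project()` returns the restored model; `save_project()` the
#'   path, invisibly.
#' @export
save_project <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      ose_abort(sprintf("cannot parse project file '%s': %s",
                        path, conditionMessage(e)), "studyframes_schema")
    })
  model_from_list(x)
}

#' Structural equality and isomorphism of projects
#'
#' `models_identical()` requires bit-identical structure including instance
#' ids. `projects_isomorphic()` compares up to instance-id relabelling:
#' instances are keyed by `(category, :NAME/name)` — adequate whenever those
#' keys are unique, as they are for all shipped fixtures and generators —
#' and categories, slot values (references followed through the relabelling),
#' containment order, rules, concepts and annotations must agree.
#'
#' @param a,b `ontology_model`s.
#' @return Logical.
#' @export
models_identical <- function(a, b) {
  identical(model_to_list(a), model_to_list(b))
}

canonical_instance_key <- function(model, id) {
  rec <- get_instance(model, id)
  slots <- names(effective_slots(model, rec$category))
  nm <- NULL
  for (sl in intersect(c(":NAME", "name"), slots)) {
    nm <- nm %||% slot_value1(model, id, sl)
  }
  paste(rec$category, nm %||% id, sep = "::")
}

canonical_project <- function(model) {
  ids <- names(model$instances)
  keys <- vapply(ids, function(id) canonical_instance_key(model, id), "")
  if (anyDuplicated(keys)) {
    ose_abort("instances are not uniquely keyed by (category, name); cannot canonicalize",
              "studyframes_invalid")
  }
  remap <- stats::setNames(keys, ids)
  map_val <- function(v, kind) {
    if (kind == "instance_ref" && is_string(v) && v %in% names(remap)) {
      remap[[v]]
    } else v
  }
  inst <- lapply(ids, function(id) {
    rec <- model$instances[[id]]
    slots <- effective_slots(model, rec$category)
    sv <- lapply(stats::setNames(names(rec$slot_values),
                                 names(rec$slot_values)), function(sn) {
      kind <- slots[[sn]]$value_kind %||% "string"
      lapply(rec$slot_values[[sn]], map_val, kind = kind)
    })
    list(key = remap[[id]], category = rec$category,
         slot_values = sv[order(names(sv))])
  })
  inst <- inst[order(vapply(inst, `[[`, "", "key"))]
  e <- model$contains_edges
  edges <- if (nrow(e)) {
    el <- lapply(seq_len(nrow(e)), function(i) {
      list(parent = remap[[e$parent[i]]], child = remap[[e$child[i]]],
           position = as.integer(e$position[i]))
    })
    el[order(vapply(el, `[[`, "", "parent"),
             vapply(el, `[[`, 0L, "position"))]
  } else list()
  list(
    categories = lapply(model$categories[order(names(model$categories))],
                        function(c) {
      list(name = c$name, parent = c$parent, layer = c$layer,
           hidden = isTRUE(c$hidden),
           template_slots = lapply(c$template_slots, slot_to_list))
    }),
    instances = inst,
    edges = edges,
    rules = model$hierarchy_rules,
    concepts = model$concepts[order(names(model$concepts) %||% character())],
    annotations = unname(lapply(sort_ids(names(model$annotations)),
                                function(aid) {
      a <- model$annotations[[aid]]
      list(type = remap[[a$type]] %||% a$type,
           concepts = sort(a$concepts),
           conditions = lapply(a$conditions, function(cond) {
             list(element = remap[[cond$element]] %||% cond$element,
                  code = cond$code,
                  range = if (!is.null(cond$range))
                    format_range_literal(cond$range))
           }))
    }))
  )
}

#' @rdname models_identical
#' @export
projects_isomorphic <- function(a, b) {
  identical(canonical_project(a), canonical_project(b))
}

#' Build the example domain ontology
#'
#' Bootstraps the task ontology and adds the example clinical-trial domain:
#' `Study`, `Page`, `Module` below `_GROUP`; `Item`, `Unit_of_Measure`,
#' `Codelist` below `_OBJECT`; hierarchy rules licensing
#' Study–Page, Study–Module, Page–Module and Module–Item containment. Items
#' carry the slots `name`, `description`, `unit_of_measure`, `range`,
#' `codelist`, `rules` plus the mapping key `:NAME` and `data_type`.
#'
#' @return An `ontology_model` with categories and rules but no instances.
#' @export
example_domain_model <- function() {
  m <- bootstrap_task_ontology()
  key <- function() slot_definition(":NAME")
  define_category(m, "Study", "_GROUP",
                  slots = list(key(), slot_definition("name")))
  define_category(m, "Page", "_GROUP",
                  slots = list(key(), slot_definition("name")))
  define_category(m, "Module", "_GROUP",
                  slots = list(key(), slot_definition("name"),
                               slot_definition("description")))
  define_category(m, "Unit_of_Measure", "_OBJECT",
                  slots = list(key(), slot_definition("name")))
  define_category(m, "Codelist", "_OBJECT",
                  slots = list(key(), slot_definition("name"),
                               slot_definition("codes",
                                               cardinality_max = Inf)))
  define_category(m, "Item", "_OBJECT",
                  slots = list(
                    key(),
                    slot_definition("name", cardinality_min = 1),
                    slot_definition("description"),
                    slot_definition("data_type"),
                    slot_definition("unit_of_measure",
                                    value_kind = "instance_ref",
                                    facets = facet_set(
                                      allowed_categories = "Unit_of_Measure")),
                    slot_definition("range"),
                    slot_definition("codelist", value_kind = "instance_ref",
                                    facets = facet_set(
                                      allowed_categories = "Codelist")),
                    slot_definition("rules", value_kind = "expression_ref",
                                    cardinality_max = Inf)))
  add_hierarchy_rule(m, "Study", "Page")
  add_hierarchy_rule(m, "Study", "Module")
  add_hierarchy_rule(m, "Page", "Module")
  add_hierarchy_rule(m, "Module", "Item")
  m
}

MINI_PHENOTYPE_OBO <- c(
  "format-version: 1.2",
  "ontology: mini-phenotype",
  "",
  "[Term]",
  "id: MP:0000001",
  "name: Phenotypic abnormality",
  "",
  "[Term]",
  "id: MP:0001626",
  "name: Abnormality of the cardiovascular system",
  "is_a: MP:0000001 ! Phenotypic abnormality",
  "",
  "[Term]",
  "id: MP:0001635",
  "name: Congestive heart failure",
  "is_a: MP:0001626 ! Abnormality of the cardiovascular system",
  "",
  "[Term]",
  "id: MP:0004421",
  "name: Elevated systolic blood pressure",
  "is_a: MP:0001626 ! Abnormality of the cardiovascular system"
)

#' Build the worked-example project
#'
#' A deterministic, seed-independent fixture reproducing the worked
#' examples: Page `B1` containing Module `Socio-demographic data`; the
#' dyspnea-at-rest item with a YES/NO codelist annotated (type `symptom_of`)
#' with the concept *Congestive heart failure*; the systolic-blood-pressure
#' item (unit mmHg, no codelist) annotated with range `[121;]` (i.e. >= 121)
#' with *Elevated systolic blood pressure*; a small synthetic phenotype
#' concept hierarchy carrying those concepts; hierarchy rules; and one rule
#' expression on the blood-pressure item.
#'
#' @return An `ontology_model`.
#' @export
build_example_project <- function() {
  m <- example_domain_model()
  load_obo(m, MINI_PHENOTYPE_OBO)

  study <- create_instance(m, "Study", list(`:NAME` = "S1",
                                            name = "Heart failure study"))$id
  page <- create_instance(m, "Page", list(`:NAME` = "B1", name = "B1"))$id
  module <- create_instance(m, "Module",
                            list(`:NAME` = "IG.SOCIO",
                                 name = "Socio-demographic data"))$id
  yn <- create_instance(m, "Codelist",
                        list(`:NAME` = "CL.YESNO", name = "Yes/No",
                             codes = list("YES", "NO")))$id
  mmHg <- create_instance(m, "Unit_of_Measure",
                          list(`:NAME` = "U.MMHG", name = "mmHg"))$id
  # spelling of the blood-pressure item name kept as in the source material
  dyspnea <- create_instance(m, "Item",
                             list(`:NAME` = "IT.DYSPNEA",
                                  name = "DYSPNEA_AT_REST",
                                  description = "Dyspnea at rest",
                                  data_type = "text",
                                  codelist = yn))$id
  sbp <- create_instance(m, "Item",
                         list(`:NAME` = "IT.SBP",
                              name = "SYSTOLIC_BLOOD_PRESURE",
                              description = "Systolic blood pressure",
                              data_type = "integer",
                              unit_of_measure = mmHg,
                              rules = "(> item:SYSTOLIC_BLOOD_PRESURE 121)"))$id

  add_to_group(m, study, page)
  add_to_group(m, page, module)
  add_to_group(m, module, dyspnea)
  add_to_group(m, module, sbp)

  define_annotation_type(m, "symptom_of")
  define_annotation_type(m, "risk_factor_of")
  create_annotation(m, element_condition(dyspnea, code = "YES"),
                    "symptom_of", "MP:0001635")
  create_annotation(m, element_condition(sbp, range = "[121;]"),
                    "symptom_of", "MP:0004421")
  m
}

random_word <- function(n = 1L) {
  syll <- c("ka", "lo", "mi", "ra", "te", "su", "ne", "vo", "di", "pa")
  vapply(seq_len(n), function(i) {
    paste(sample(syll, sample(2:4, 1), replace = TRUE), collapse = "")
  }, "")
}

#' Generate a reproducible random project
#'
#' Produces a study skeleton on the example domain ontology: one study, a
#' set of modules, `n_items` items spread over them, and codelists attached
#' to roughly a third of the items. The output is deterministic for a given
#' `(n_items, seed)` pair, always satisfies the frame and hierarchy
#' invariants, and only populates slots covered by the shipped ODM mapping,
#' so the generated projects round-trip through [export_xml()] /
#' [import_xml()].
#'
#' @param n_items Number of items (>= 0); 0 yields an empty study skeleton.
#' @param seed Integer seed.
#' @return An `ontology_model`.
#' @export
generate_random_project <- function(n_items, seed = 1L) {
  stopifnot(n_items >= 0)
  with_preserved_seed(seed, {
    m <- example_domain_model()
    study <- create_instance(m, "Study",
                             list(`:NAME` = "ST.1",
                                  name = paste(random_word(2),
                                               collapse = " ")))$id
    if (n_items > 0) {
      n_modules <- sample(seq_len(max(1L, ceiling(n_items / 4))), 1L)
      modules <- vapply(seq_len(n_modules), function(i) {
        id <- create_instance(m, "Module",
                              list(`:NAME` = sprintf("IG.%03d", i),
                                   name = random_word()))$id
        add_to_group(m, study, id)
        id
      }, "")
      n_codelists <- max(1L, n_items %/% 3L)
      codelists <- vapply(seq_len(n_codelists), function(i) {
        create_instance(m, "Codelist",
                        list(`:NAME` = sprintf("CL.%03d", i),
                             name = random_word(),
                             codes = as.list(toupper(
                               random_word(sample(2:5, 1L))))))$id
      }, "")
      for (i in seq_len(n_items)) {
        sv <- list(`:NAME` = sprintf("IT.%04d", i),
                   name = toupper(random_word()),
                   data_type = sample(c("text", "integer", "float"), 1L))
        if (stats::runif(1) < 0.5) sv$description <- paste(random_word(3),
                                                           collapse = " ")
        if (stats::runif(1) < 0.35) sv$codelist <- sample(codelists, 1L)
        item <- create_instance(m, "Item", sv)$id
        add_to_group(m, sample(modules, 1L), item)
      }
    }
    m
  })
}

#' Export a project as an ODM-style document
#'
#' Convenience wrapper: exports all `Study` instances of the model through
#' the given mapping.
#'
#' @param model An `ontology_model`.
#' @param mapping An XML mapping (default: the shipped [odm_mapping()]).
#' @return An `xml_document`.
#' @export
generate_odm_document <- function(model, mapping = odm_mapping()) {
  export_xml(model, mapping, root_instances = instances_of(model, "Study"))
}
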