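#' Slot definition
#'
#' A slot describes a property or attribute of a category. Facets constrain
#' the values a slot may take; cardinality bounds constrain how many values
#' an instance may carry.
#'
#' @param name Slot name (non-empty string).
#' @param value_kind One of `"string"`, `"number"`, `"boolean"`,
#'   `"instance_ref"`, `"concept_ref"`, `"expression_ref"`.
#' @param cardinality_min Non-negative integer.
#' @param cardinality_max Positive integer, or `Inf` for unbounded.
#' @param facets A [facet_set()].
#' @param inverse_of Optional name of the inverse slot. Only meaningful for
#'   `instance_ref` / `concept_ref` slots.
#' @return An object of class `slot_definition`.
#' @export
slot_definition <- function(name,
                            value_kind = "string",
                            cardinality_min = 0L,
                            cardinality_max = 1L,
                            facets = facet_set(),
                            inverse_of = NULL) {
  if (!is_string(name) || !nzchar(name)) {
    ose_abort("slot name must be a non-empty string", "studyframes_invalid")
  }
  kinds <- c("string", "number", "boolean", "instance_ref", "concept_ref",
             "expression_ref")
  if (!is_string(value_kind) || !value_kind %in% kinds) {
    ose_abort(sprintf("unknown value_kind '%s' for slot '%s'", value_kind, name),
              "studyframes_invalid")
  }
  cardinality_min <- as.numeric(cardinality_min)
  cardinality_max <- as.numeric(cardinality_max)
  if (cardinality_min < 0 || cardinality_max < 1 ||
      cardinality_min > cardinality_max) {
    ose_abort(sprintf("invalid cardinality [%s, %s] for slot '%s'",
                      cardinality_min, cardinality_max, name),
              "studyframes_invalid")
  }
  structure(
    list(name = name, value_kind = value_kind,
         cardinality_min = cardinality_min, cardinality_max = cardinality_max,
         facets = facets, inverse_of = inverse_of),
    class = "slot_definition"
  )
}

#' Facet set
#'
#' Facets are constraints on a slot's values: numeric bounds, a default,
#' an allowed-category restriction for instance references, or an enumerated
#' value list.
#'
#' @param minimum,maximum Optional numeric bounds (inclusive).
#' @param default Optional default value; must satisfy the other facets.
#' @param allowed_categories Optional character vector of category names an
#'   `instance_ref` value may instantiate.
#' @param allowed_values Optional vector of permitted literal values.
#' @return An object of class `facet_set`.
#' @export
facet_set <- function(minimum = NULL, maximum = NULL, default = NULL,
                      allowed_categories = NULL, allowed_values = NULL) {
  if (!is.null(minimum) && !is.null(maximum) && minimum > maximum) {
    ose_abort("facet minimum exceeds maximum", "studyframes_invalid")
  }
  if (!is.null(default)) {
    if (!is.null(minimum) && is.numeric(default) && default < minimum ||
        !is.null(maximum) && is.numeric(default) && default > maximum) {
      ose_abort("facet default violates numeric bounds", "studyframes_invalid")
    }
    if (!is.null(allowed_values) && !default %in% allowed_values) {
      ose_abort("facet default not among allowed_values", "studyframes_invalid")
    }
  }
  structure(
    list(minimum = minimum, maximum = maximum, default = default,
         allowed_categories = allowed_categories,
         allowed_values = allowed_values),
    class = "facet_set"
  )
}

new_violation <- function(kind, message, instance = NULL, slot = NULL,
                          parent = NULL, child = NULL) {
  structure(
    list(kind = kind, message = message, instance = instance, slot = slot,
         parent = parent, child = child),
    class = "ose_violation"
  )
}

#' @export
format.ose_violation <- function(x, ...) {
  sprintf("[%s] %s", x$kind, x$message)
}

#' @export
print.ose_violation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

new_ontology_model <- function() {
  m <- new.env(parent = emptyenv())
  m$categories <- list()       # name -> category definition
  m$instances <- list()        # id -> instance record
  m$contains_edges <- data.frame(parent = character(), child = character(),
                                 position = integer(),
                                 stringsAsFactors = FALSE)
  m$hierarchy_rules <- list()  # list of hierarchy_rule()
  m$concepts <- list()         # concept id -> concept record
  m$annotations <- list()      # annotation id -> annotation record
  m$concept_index <- list()    # concept id -> character vector of annotation ids
  m$mappings <- list()         # name -> format mapping
  m$counter <- 0L
  m$extra_fields <- list()     # unknown project-file fields, preserved on save
  class(m) <- "ontology_model"
  m
}

add_category <- function(model, name, parent = NULL, layer = "TO",
                         hidden = FALSE, abstract = FALSE, slots = list()) {
  if (name %in% names(model$categories)) {
    ose_abort(sprintf("category '%s' already exists", name),
              "studyframes_duplicate")
  }
  if (!is.null(parent)) {
    if (!parent %in% names(model$categories)) {
      ose_abort(sprintf("unknown parent category '%s'", parent),
                "studyframes_unknown")
    }
    # hidden status is closed downward
    if (isTRUE(model$categories[[parent]]$hidden)) hidden <- TRUE
  }
  named <- stats::setNames(slots, vapply(slots, `[[`, "", "name"))
  def <- structure(
    list(name = name, parent = parent, layer = layer, hidden = hidden,
         abstract = abstract, template_slots = named),
    class = "category_def"
  )
  model$categories[[name]] <- def
  invisible(def)
}

#' Bootstrap the task ontology
#'
#' Creates a fresh model seeded with the generic task ontology every project
#' is built on: the user-visible `_ELEMENT` subtree (constants, objects,
#' groups, annotations, export formats), the hidden `_CONFIG` subtree holding
#' format mappings and annotation types, `_ANNOTATING_ONTOLOGY_ROOT` under
#' which external ontologies are inserted, and the `_MATH` subtree backing the
#' expression engine. Domain categories (Study, Item, ...) are added with
#' [define_category()] as subcategories of these.
#'
#' @return An `ontology_model` (environment-backed; operations mutate it in
#'   place).
#' @examples
#' m <- bootstrap_task_ontology()
#' category_children(m, "_ELEMENT")
#' @export
bootstrap_task_ontology <- function() {
  m <- new_ontology_model()

  add_category(m, "_ELEMENT", abstract = TRUE)
  add_category(m, "_CONSTANT", "_ELEMENT",
               slots = list(slot_definition("name", cardinality_min = 1),
                            slot_definition("value")))
  add_category(m, "_OBJECT", "_ELEMENT")
  add_category(m, "_GROUP", "_ELEMENT",
               slots = list(slot_definition("_contains",
                                            value_kind = "instance_ref",
                                            cardinality_max = Inf)))
  add_category(m, "_ANNOTATION", "_ELEMENT",
               slots = list(
                 slot_definition("_annotated_elements",
                                 value_kind = "instance_ref",
                                 cardinality_min = 1, cardinality_max = Inf),
                 slot_definition("_annotation_type",
                                 value_kind = "instance_ref",
                                 cardinality_min = 1, cardinality_max = 1),
                 slot_definition("_annotating_concepts",
                                 value_kind = "concept_ref",
                                 cardinality_min = 1, cardinality_max = Inf,
                                 inverse_of = "_annotations")))
  add_category(m, "_EXPORT", "_ELEMENT")

  add_category(m, "_CONFIG", hidden = TRUE, abstract = TRUE)
  add_category(m, "_FORMAT_MAPPING", "_CONFIG")
  add_category(m, "_ROOT_TAG", "_FORMAT_MAPPING")
  add_category(m, "_TAG", "_FORMAT_MAPPING")
  add_category(m, "_ANNOTATION_TYPE", "_CONFIG",
               slots = list(slot_definition("name", cardinality_min = 1)))

  # concept-side inverse of _annotating_concepts lives on the ontology root
  add_category(m, "_ANNOTATING_ONTOLOGY_ROOT", abstract = TRUE,
               slots = list(slot_definition("_annotations",
                                            value_kind = "instance_ref",
                                            cardinality_max = Inf,
                                            inverse_of = "_annotating_concepts")))

  add_category(m, "_MATH", abstract = TRUE)
  add_category(m, "_MATH_EXPRESSION_RELATOR", "_MATH")
  add_category(m, "_NUMBER", "_MATH")
  add_category(m, "_STUDY_ELEMENT", "_MATH")

  m
}

#' @export
print.ontology_model <- function(x, ...) {
  cat("<ontology_model>\n")
  cat("  categories:", length(x$categories),
      sprintf("(%d hidden)", sum(vapply(x$categories, function(c) isTRUE(c$hidden), TRUE))), "\n")
  cat("  instances: ", length(x$instances), "\n")
  cat("  contains edges:", nrow(x$contains_edges), "\n")
  cat("  hierarchy rules:", length(x$hierarchy_rules), "\n")
  cat("  concepts:  ", length(x$concepts), "\n")
  cat("  annotations:", length(x$annotations), "\n")
  invisible(x)
}

category_exists <- function(model, name) {
  is_string(name) && name %in% names(model$categories)
}

get_category <- function(model, name) {
  if (!category_exists(model, name)) {
    ose_abort(sprintf("unknown category '%s'", name), "studyframes_unknown")
  }
  model$categories[[name]]
}

#' Category tree queries
#'
#' `category_children()` lists the direct subcategories of a category;
#' `category_is_a()` tests reflexive-transitive subcategory descent (a
#' category is-a itself).
#'
#' @param model An `ontology_model`.
#' @param name,ancestor Category names.
#' @return `category_children()`: character vector; `category_is_a()`: logical.
#' @export
category_children <- function(model, name) {
  get_category(model, name)
  kids <- vapply(model$categories, function(c) identical(c$parent, name), TRUE)
  names(model$categories)[kids]
}

#' @rdname category_children
#' @export
category_is_a <- function(model, name, ancestor) {
  if (!category_exists(model, name)) return(FALSE)
  cur <- name
  seen <- character()
  while (!is.null(cur)) {
    if (identical(cur, ancestor)) return(TRUE)
    if (cur %in% seen) return(FALSE)  # defensive: malformed parent chain
    seen <- c(seen, cur)
    cur <- model$categories[[cur]]$parent
  }
  FALSE
}

# All effective slots of a category: template slots accumulated from the root
# down, a child's slot of the same name overriding its ancestor's.
effective_slots <- function(model, category) {
  chain <- character()
  cur <- category
  while (!is.null(cur)) {
    chain <- c(cur, chain)
    cur <- get_category(model, cur)$parent
  }
  slots <- list()
  for (cat in chain) {
    for (s in model$categories[[cat]]$template_slots) {
      slots[[s$name]] <- s
    }
  }
  slots
}

#' Define a domain-ontology category
#'
#' Adds a new domain category below an existing one. The new category has
#' layer `"DO"`, inherits every template slot of its ancestors and adds the
#' given ones.
#'
#' @param model An `ontology_model`.
#' @param name New category name (unique within the model).
#' @param parent Existing category name; must not be hidden.
#' @param slots List of [slot_definition()]s owned by the new category.
#' @return The category definition, invisibly.
#' @examples
#' m <- bootstrap_task_ontology()
#' define_category(m, "Item", "_OBJECT",
#'                 slots = list(slot_definition("name", cardinality_min = 1)))
#' @export
define_category <- function(model, name, parent, slots = list()) {
  if (name %in% names(model$categories)) {
    ose_abort(sprintf("category '%s' already exists", name),
              "studyframes_duplicate")
  }
  pdef <- get_category(model, parent)
  if (isTRUE(pdef$hidden)) {
    ose_abort(sprintf(
      "cannot place study-element category '%s' under hidden category '%s'",
      name, parent), "studyframes_hidden_parent")
  }
  add_category(model, name, parent = parent, layer = "DO", slots = slots)
}

next_instance_id <- function(model) {
  model$counter <- model$counter + 1L
  sprintf("inst-%d", model$counter)
}

check_value_kind <- function(value, kind) {
  switch(kind,
         string = is_string(value),
         number = is_number(value),
         boolean = is.logical(value) && length(value) == 1L && !is.na(value),
         instance_ref = is_string(value),
         concept_ref = is_string(value),
         expression_ref = is_string(value),
         FALSE)
}

# Normalize user-supplied slot values to an ordered list of scalars.
as_value_list <- function(v) {
  if (is.null(v)) return(list())
  if (is.list(v)) return(v)
  as.list(v)
}

#' Create an instance of a category
#'
#' @param model An `ontology_model`.
#' @param category Name of an existing, instantiable category (abstract task
#'   ontology roots cannot be instantiated).
#' @param slot_values Named list mapping slot names to a value or list of
#'   values. Values are checked against the slot's `value_kind`; strings that
#'   happen to look numeric are not coerced (codes like `"01"` survive
#'   round-trips).
#' @return The stored instance record (a list with `id`, `category`,
#'   `slot_values`).
#' @export
create_instance <- function(model, category, slot_values = list()) {
  cdef <- get_category(model, category)
  if (isTRUE(cdef$abstract)) {
    ose_abort(sprintf("category '%s' is abstract and cannot be instantiated",
                      category), "studyframes_abstract")
  }
  slots <- effective_slots(model, category)
  vals <- list()
  for (sn in names(slot_values)) {
    if (!sn %in% names(slots)) {
      ose_abort(sprintf("unknown slot '%s' for category '%s'", sn, category),
                "studyframes_unknown_slot")
    }
    vlist <- as_value_list(slot_values[[sn]])
    kind <- slots[[sn]]$value_kind
    for (v in vlist) {
      if (!check_value_kind(v, kind)) {
        ose_abort(sprintf(
          "value '%s' does not match value_kind '%s' of slot '%s'",
          paste(format(v), collapse = ","), kind, sn),
          "studyframes_kind_mismatch")
      }
    }
    if (length(vlist)) vals[[sn]] <- vlist
  }
  rec <- list(id = next_instance_id(model), category = category,
              slot_values = vals)
  model$instances[[rec$id]] <- rec
  rec
}

instance_exists <- function(model, id) {
  is_string(id) && id %in% names(model$instances)
}

get_instance <- function(model, id) {
  if (!instance_exists(model, id)) {
    ose_abort(sprintf("unknown instance '%s'", id), "studyframes_unknown")
  }
  model$instances[[id]]
}

#' Read or write a slot value on a stored instance
#'
#' `slot_value()` returns the ordered list of values (possibly empty);
#' `slot_value1()` the first value or `NULL`. `set_slot_value()` replaces the
#' values, after kind-checking each against the slot definition.
#'
#' @param model An `ontology_model`.
#' @param id Instance id.
#' @param slot Slot name.
#' @param values Value or list of values.
#' @return `slot_value()`: list; `slot_value1()`: scalar or `NULL`.
#' @export
slot_value <- function(model, id, slot) {
  rec <- get_instance(model, id)
  rec$slot_values[[slot]] %||% list()
}

#' @rdname slot_value
#' @export
slot_value1 <- function(model, id, slot) {
  v <- slot_value(model, id, slot)
  if (length(v)) v[[1]] else NULL
}

#' @rdname slot_value
#' @export
set_slot_value <- function(model, id, slot, values) {
  rec <- get_instance(model, id)
  slots <- effective_slots(model, rec$category)
  if (!slot %in% names(slots)) {
    ose_abort(sprintf("unknown slot '%s' for category '%s'", slot,
                      rec$category), "studyframes_unknown_slot")
  }
  vlist <- as_value_list(values)
  for (v in vlist) {
    if (!check_value_kind(v, slots[[slot]]$value_kind)) {
      ose_abort(sprintf("value does not match value_kind '%s' of slot '%s'",
                        slots[[slot]]$value_kind, slot),
                "studyframes_kind_mismatch")
    }
  }
  if (length(vlist)) {
    rec$slot_values[[slot]] <- vlist
  } else {
    rec$slot_values[[slot]] <- NULL
  }
  model$instances[[id]] <- rec
  invisible(rec)
}

append_slot_value <- function(model, id, slot, value) {
  cur <- slot_value(model, id, slot)
  set_slot_value(model, id, slot, c(cur, list(value)))
}

#' Does an instance instantiate a category (or one of its subcategories)?
#'
#' @param model An `ontology_model`.
#' @param id Instance id.
#' @param category Category name.
#' @return Logical.
#' @export
is_instance_of <- function(model, id, category) {
  rec <- get_instance(model, id)
  category_is_a(model, rec$category, category)
}

#' List instances of a category
#'
#' @param model An `ontology_model`.
#' @param category Category name.
#' @param closure Include instances of subcategories (default `TRUE`).
#' @return Character vector of instance ids in creation order.
#' @export
instances_of <- function(model, category, closure = TRUE) {
  get_category(model, category)
  hit <- vapply(model$instances, function(r) {
    if (closure) category_is_a(model, r$category, category)
    else identical(r$category, category)
  }, TRUE)
  names(model$instances)[hit]
}

#' Validate an instance against its category's slots and facets
#'
#' Checks cardinality bounds, value kinds, numeric facets, enumerated value
#' facets, allowed-category facets, and that instance / concept references
#' resolve. The model is never mutated; violations are returned as data.
#'
#' @param model An `ontology_model`.
#' @param instance Instance id or record.
#' @return A list of violation objects; empty if conformant.
#' @export
validate_instance <- function(model, instance) {
  rec <- if (is_string(instance)) get_instance(model, instance) else instance
  out <- list()
  note <- function(kind, msg, slot = NULL) {
    out[[length(out) + 1L]] <<- new_violation(kind, msg,
                                              instance = rec$id, slot = slot)
  }
  if (!category_exists(model, rec$category)) {
    note("unknown-category",
         sprintf("instance '%s' has unknown category '%s'", rec$id, rec$category))
    return(out)
  }
  slots <- effective_slots(model, rec$category)
  for (sn in names(rec$slot_values)) {
    if (!sn %in% names(slots)) {
      note("unknown-slot",
           sprintf("instance '%s' carries unknown slot '%s'", rec$id, sn), sn)
    }
  }
  for (sn in names(slots)) {
    sd <- slots[[sn]]
    vals <- rec$slot_values[[sn]] %||% list()
    n <- length(vals)
    if (n < sd$cardinality_min) {
      note("missing-value",
           sprintf("slot '%s' of instance '%s' has %d value(s), minimum is %g",
                   sn, rec$id, n, sd$cardinality_min), sn)
    }
    if (n > sd$cardinality_max) {
      note("cardinality",
           sprintf("slot '%s' of instance '%s' has %d value(s), maximum is %g",
                   sn, rec$id, n, sd$cardinality_max), sn)
    }
    for (v in vals) {
      if (!check_value_kind(v, sd$value_kind)) {
        note("kind-mismatch",
             sprintf("slot '%s' of instance '%s': value does not match kind '%s'",
                     sn, rec$id, sd$value_kind), sn)
        next
      }
      f <- sd$facets
      if (sd$value_kind == "number") {
        if (!is.null(f$minimum) && v < f$minimum) {
          note("facet", sprintf("slot '%s': value %g below minimum %g",
                                sn, v, f$minimum), sn)
        }
        if (!is.null(f$maximum) && v > f$maximum) {
          note("facet", sprintf("slot '%s': value %g above maximum %g",
                                sn, v, f$maximum), sn)
        }
      }
      if (!is.null(f$allowed_values) && !v %in% f$allowed_values) {
        note("facet", sprintf("slot '%s': value '%s' not among allowed values",
                              sn, v), sn)
      }
      if (sd$value_kind == "instance_ref") {
        if (!instance_exists(model, v)) {
          note("unresolved-reference",
               sprintf("slot '%s': no instance '%s'", sn, v), sn)
        } else if (!is.null(f$allowed_categories) &&
                   !any(vapply(f$allowed_categories,
                               function(ac) is_instance_of(model, v, ac), TRUE))) {
          note("facet",
               sprintf("slot '%s': instance '%s' not of an allowed category",
                       sn, v), sn)
        }
      }
      if (sd$value_kind == "concept_ref" && !v %in% names(model$concepts)) {
        note("unresolved-reference",
             sprintf("slot '%s': no concept '%s'", sn, v), sn)
      }
    }
  }
  out
}
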