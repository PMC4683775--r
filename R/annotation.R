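# Annotating ontologies and typed annotation of element/value combinations.
#
# Concepts from external ontologies (e.g., phenotype ontologies) live in a
# dedicated store on the model, conceptually under _ANNOTATING_ONTOLOGY_ROOT.
# Annotations are _ANNOTATION instances whose conditions pair a study element
# with an optional codelist value or numeric range; all conditions are
# AND-connected. The concept-side inverse slot _annotations is realized as an
# index kept consistent on every create/delete.

#' Insert a single concept under the annotating-ontology root
#'
#' @param model An `ontology_model`.
#' @param id Term id (unique across all loaded ontologies).
#' @param label Human-readable label; defaults to the id.
#' @param parents Character vector of parent concept ids (is_a).
#' @param ontology Name tag of the ontology the concept belongs to.
#' @return The concept id, invisibly.
#' @export
add_concept <- function(model, id, label = id, parents = character(),
                        ontology = "default") {
  if (id %in% names(model$concepts)) {
    ose_abort(sprintf("duplicate concept id '%s'", id), "studyframes_duplicate")
  }
  model$concepts[[id]] <- list(id = id, label = label,
                               parents = as.character(parents),
                               ontology = ontology)
  check_concept_acyclic(model)
  invisible(id)
}

# is_a graph must stay acyclic; DFS with colouring over the concept store.
check_concept_acyclic <- function(model) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack) {
      ose_abort(sprintf("is_a cycle involving concept '%s'", id),
                "studyframes_cycle")
    }
    if (isTRUE(state[[id]])) return(invisible(NULL))
    for (p in model$concepts[[id]]$parents) {
      if (p %in% names(model$concepts)) visit(p, c(stack, id))
    }
    state[[id]] <- TRUE
    invisible(NULL)
  }
  for (id in names(model$concepts)) visit(id, character())
  invisible(NULL)
}

#' Load an annotating ontology from an OBO flat file
#'
#' Parses OBO 1.2-style `[Term]` stanzas, honouring `id`, `name`, `is_a` and
#' `is_obsolete`; all other lines are ignored. Obsolete terms are skipped; a
#' term without a name gets its id as label. Concepts are inserted under the
#' annotating-ontology root, each load under its own ontology tag so several
#' ontologies can coexist.
#'
#' @param model An `ontology_model`.
#' @param input Path to an OBO file, or a character vector of OBO lines.
#' @param ontology Optional ontology tag; defaults to the header's
#'   `ontology:` line, else a generated name.
#' @return Number of concepts loaded.
#' @export
load_obo <- function(model, input, ontology = NULL) {
  lines <- if (length(input) == 1L && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    as.character(input)
  }
  header_name <- sub("^ontology:\\s*", "",
                     grep("^ontology:", lines, value = TRUE)[1])
  if (is.null(ontology)) {
    ontology <- if (!is.na(header_name) && nzchar(header_name)) header_name
    else sprintf("ontology-%d", length(unique(vapply(model$concepts,
                                                     `[[`, "", "ontology"))) + 1L)
  }

  terms <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      terms[[length(terms) + 1L]] <<- cur
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)          # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {    # [Typedef] etc.
      flush()
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
      else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
      else if (grepl("^is_a:", ln)) {
        cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
      } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    }
  }
  flush()

  for (t in terms) {
    add_concept(model, t$id, label = t$name %||% t$id,
                parents = t$parents, ontology = ontology)
  }
  length(terms)
}

concept_exists <- function(model, id) {
  is_string(id) && id %in% names(model$concepts)
}

# Reflexive-transitive is_a descendants of a concept.
concept_descendants <- function(model, id, include_self = TRUE) {
  kids_of <- function(cid) {
    hit <- vapply(model$concepts, function(c) cid %in% c$parents, TRUE)
    names(model$concepts)[hit]
  }
  out <- character()
  queue <- id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% out) next
    out <- c(out, cur)
    queue <- c(queue, kids_of(cur))
  }
  if (include_self) out else setdiff(out, id)
}

#' Define an annotation type
#'
#' Annotation types (e.g., `annotated_with`, `risk_factor_of`, `symptom_of`)
#' are instances of the configuration category `_ANNOTATION_TYPE`.
#'
#' @param model An `ontology_model`.
#' @param name Type name, unique among annotation types.
#' @return The instance id of the new annotation type.
#' @export
define_annotation_type <- function(model, name) {
  existing <- instances_of(model, "_ANNOTATION_TYPE")
  for (id in existing) {
    if (identical(slot_value1(model, id, "name"), name)) {
      ose_abort(sprintf("annotation type '%s' already defined", name),
                "studyframes_duplicate")
    }
  }
  create_instance(model, "_ANNOTATION_TYPE", list(name = name))$id
}

resolve_annotation_type <- function(model, type) {
  ids <- instances_of(model, "_ANNOTATION_TYPE")
  if (type %in% ids) return(type)
  for (id in ids) {
    if (identical(slot_value1(model, id, "name"), type)) return(id)
  }
  ose_abort(sprintf("unknown annotation type '%s'", type), "studyframes_unknown")
}

#' Element condition of an annotation
#'
#' Pairs a study element with at most one of a codelist value or a numeric
#' range. An element with a codelist may only be conditioned on one of its
#' codes; ranges are only allowed on elements without a codelist.
#'
#' @param element Instance id of the annotated element.
#' @param code Optional codelist value.
#' @param range Optional range, as a `range_literal` or its text form
#'   (e.g., `"[121;]"`).
#' @return An object of class `element_condition`.
#' @export
element_condition <- function(element, code = NULL, range = NULL) {
  if (!is.null(code) && !is.null(range)) {
    ose_abort("a condition may carry a code or a range, not both",
              "studyframes_invalid")
  }
  if (!is.null(range) && !inherits(range, "range_literal")) {
    range <- parse_range_literal(range)
  }
  structure(list(element = element, code = code, range = range),
            class = "element_condition")
}

# Codes of the codelist referenced by an element's `codelist` slot, or NULL
# when the element has no codelist.
element_codelist_codes <- function(model, element) {
  rec <- get_instance(model, element)
  if (!"codelist" %in% names(effective_slots(model, rec$category))) return(NULL)
  cl <- slot_value1(model, element, "codelist")
  if (is.null(cl)) return(NULL)
  unlist(slot_value(model, cl, "codes"), use.names = FALSE)
}

#' Create a typed annotation
#'
#' Links one or more element conditions (AND-connected) to concepts of an
#' annotating ontology via an annotation type. The annotation is stored as an
#' `_ANNOTATION` instance; each concept's `_annotations` inverse index is
#' updated.
#'
#' @param model An `ontology_model`.
#' @param conditions A single [element_condition()] or a list of them.
#' @param type Annotation-type instance id or name.
#' @param concepts Character vector of concept ids.
#' @return The annotation record (with `id`, `conditions`, `type`,
#'   `concepts`).
#' @export
create_annotation <- function(model, conditions, type, concepts) {
  if (inherits(conditions, "element_condition")) conditions <- list(conditions)
  if (length(conditions) < 1L || length(concepts) < 1L) {
    ose_abort("an annotation needs at least one condition and one concept",
              "studyframes_invalid")
  }
  type_id <- resolve_annotation_type(model, type)
  for (cid in concepts) {
    if (!concept_exists(model, cid)) {
      ose_abort(sprintf("unknown concept '%s'", cid), "studyframes_unknown")
    }
  }
  for (cond in conditions) {
    get_instance(model, cond$element)
    if (!is_instance_of(model, cond$element, "_ELEMENT")) {
      ose_abort(sprintf("'%s' is not a study element", cond$element),
                "studyframes_not_element")
    }
    codes <- element_codelist_codes(model, cond$element)
    if (!is.null(cond$code)) {
      if (is.null(codes)) {
        ose_abort(sprintf("element '%s' has no codelist; cannot condition on a code",
                          cond$element), "studyframes_invalid")
      }
      if (!cond$code %in% codes) {
        ose_abort(sprintf("code '%s' is not in the codelist of element '%s'",
                          cond$code, cond$element), "studyframes_invalid")
      }
    }
    if (!is.null(cond$range) && !is.null(codes)) {
      ose_abort(sprintf("element '%s' has a codelist; ranges cannot be annotated",
                        cond$element), "studyframes_invalid")
    }
  }
  inst <- create_instance(model, "_ANNOTATION", list(
    `_annotated_elements` = lapply(conditions, `[[`, "element"),
    `_annotation_type` = type_id,
    `_annotating_concepts` = as.list(concepts)))
  ann <- list(id = inst$id, conditions = conditions, type = type_id,
              concepts = as.character(concepts))
  model$annotations[[ann$id]] <- ann
  for (cid in concepts) {
    model$concept_index[[cid]] <- c(model$concept_index[[cid]], ann$id)
  }
  ann
}

#' Delete an annotation
#'
#' Removes the annotation instance and withdraws it from every concept's
#' inverse index.
#'
#' @param model An `ontology_model`.
#' @param id Annotation id.
#' @return Invisibly `NULL`.
#' @export
delete_annotation <- function(model, id) {
  ann <- model$annotations[[id]]
  if (is.null(ann)) {
    ose_abort(sprintf("unknown annotation '%s'", id), "studyframes_unknown")
  }
  for (cid in ann$concepts) {
    left <- setdiff(model$concept_index[[cid]], id)
    if (length(left)) model$concept_index[[cid]] <- left
    else model$concept_index[[cid]] <- NULL
  }
  model$annotations[[id]] <- NULL
  model$instances[[id]] <- NULL
  invisible(NULL)
}

#' Evaluate an annotation against a data record
#'
#' An annotation holds iff every condition holds: the element must have a
#' value in the record, a code condition requires equality with the code, and
#' a range condition requires a numeric value within the inclusive bounds. A
#' non-numeric value against a range condition makes that condition false
#' (logged, not an error). An empty record therefore never satisfies any
#' annotation.
#'
#' @param annotation An annotation record from [create_annotation()].
#' @param record Named list or vector mapping element ids to observed values.
#' @return Logical.
#' @export
evaluate_annotation <- function(annotation, record) {
  record <- as.list(record)
  for (cond in annotation$conditions) {
    v <- record[[cond$element]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) return(FALSE)
    if (!is.null(cond$code)) {
      if (!identical(as.character(v), as.character(cond$code))) return(FALSE)
    } else if (!is.null(cond$range)) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        ose_log(sprintf("non-numeric value '%s' against range condition on '%s'",
                        v, cond$element))
        return(FALSE)
      }
      if (!range_contains(cond$range, num)) return(FALSE)
    }
  }
  TRUE
}

#' Annotations attached to a concept
#'
#' Returns every annotation whose annotating concepts include the given
#' concept; with `include_subclasses`, annotations on any is_a descendant are
#' included too. Order is deterministic (by annotation id).
#'
#' @param model An `ontology_model`.
#' @param concept Concept id.
#' @param include_subclasses Also collect annotations of is_a descendants.
#' @return A list of annotation records.
#' @export
annotations_of_concept <- function(model, concept, include_subclasses = FALSE) {
  if (!concept_exists(model, concept)) {
    ose_abort(sprintf("unknown concept '%s'", concept), "studyframes_unknown")
  }
  ids <- if (include_subclasses) concept_descendants(model, concept) else concept
  ann_ids <- unique(unlist(model$concept_index[ids], use.names = FALSE))
  lapply(sort_ids(ann_ids), function(a) model$annotations[[a]])
}

#' Parse a range literal
#'
#' Ranges are written `"[lower;upper]"` with either bound optional but not
#' both, and both bounds inclusive: `"[121;]"` means `>= 121`.
#'
#' @param text Range text.
#' @return An object of class `range_literal` with `lower`, `upper`, `text`.
#' @export
parse_range_literal <- function(text) {
  if (!is_string(text)) {
    ose_abort("range literal must be a string", "studyframes_parse")
  }
  num <- "[-+]?[0-9]+(?:\\.[0-9]+)?"
  pat <- sprintf("^\\[\\s*(%s)?\\s*;\\s*(%s)?\\s*\\]$", num, num)
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) == 0L) {
    ose_abort(sprintf("malformed range literal '%s'", text), "studyframes_parse")
  }
  lower <- if (nzchar(m[2])) as.numeric(m[2]) else NULL
  upper <- if (nzchar(m[3])) as.numeric(m[3]) else NULL
  if (is.null(lower) && is.null(upper)) {
    ose_abort(sprintf("range literal '%s' has no bounds", text),
              "studyframes_parse")
  }
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    ose_abort(sprintf("range literal '%s' has lower > upper", text),
              "studyframes_parse")
  }
  structure(list(lower = lower, upper = upper, text = text),
            class = "range_literal")
}

#' @rdname parse_range_literal
#' @param range A `range_literal`.
#' @export
format_range_literal <- function(range) {
  fmt <- function(x) if (is.null(x)) "" else format(x, scientific = FALSE,
                                                    trim = TRUE)
  sprintf("[%s;%s]", fmt(range$lower), fmt(range$upper))
}

#' @rdname parse_range_literal
#' @param x Number to test.
#' @export
range_contains <- function(range, x) {
  (is.null(range$lower) || x >= range$lower) &&
    (is.null(range$upper) || x <= range$upper)
}
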