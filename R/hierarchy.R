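# Study structure: an ordered containment forest over instances, validated
# against declared class-level hierarchy rules.

containment_parent <- function(model, id) {
  e <- model$contains_edges
  hit <- e$child == id
  if (any(hit)) e$parent[hit][1] else NULL
}

#' Children of a group, in sibling order
#'
#' @param model An `ontology_model`.
#' @param group Instance id.
#' @return Character vector of child instance ids ordered by position.
#' @export
contained_children <- function(model, group) {
  e <- model$contains_edges
  rows <- e[e$parent == group, , drop = FALSE]
  rows$child[order(rows$position)]
}

renumber_siblings <- function(model, group) {
  e <- model$contains_edges
  idx <- which(e$parent == group)
  idx <- idx[order(e$position[idx])]
  e$position[idx] <- seq_along(idx) - 1L
  model$contains_edges <- e
  invisible(NULL)
}

is_containment_ancestor <- function(model, maybe_ancestor, id) {
  cur <- containment_parent(model, id)
  while (!is.null(cur)) {
    if (identical(cur, maybe_ancestor)) return(TRUE)
    cur <- containment_parent(model, cur)
  }
  FALSE
}

#' Place a study element inside a group
#'
#' Inserts a containment edge from `group` to `element` at the given 0-based
#' sibling position (default: append). Sibling positions are renumbered
#' contiguously. The containment relation is a forest: an element has at most
#' one parent and no cycles are allowed.
#'
#' @param model An `ontology_model`.
#' @param group Instance id of a group (its category descends from `_GROUP`).
#' @param element Instance id of a study element.
#' @param position Optional 0-based insertion position among siblings.
#' @return The inserted edge as a list `(parent, child, position)`, invisibly.
#' @export
add_to_group <- function(model, group, element, position = NULL) {
  get_instance(model, element)
  get_instance(model, group)
  if (!is_instance_of(model, group, "_GROUP")) {
    ose_abort(sprintf("instance '%s' is not a group", group),
              "studyframes_not_group")
  }
  if (!is_instance_of(model, element, "_ELEMENT")) {
    ose_abort(sprintf("instance '%s' is not a study element", element),
              "studyframes_not_element")
  }
  if (!is.null(containment_parent(model, element))) {
    ose_abort(sprintf("instance '%s' already has a parent", element),
              "studyframes_duplicate_parent")
  }
  if (identical(group, element) ||
      is_containment_ancestor(model, element, group)) {
    ose_abort("edge would create a containment cycle", "studyframes_cycle")
  }
  k <- length(contained_children(model, group))
  if (is.null(position)) position <- k
  position <- max(0L, min(as.integer(position), k))
  e <- model$contains_edges
  # shift: occupy a half-position, then renumber
  e <- rbind(e, data.frame(parent = group, child = element,
                           position = position - 0.5,
                           stringsAsFactors = FALSE))
  model$contains_edges <- e
  renumber_siblings(model, group)
  invisible(list(parent = group, child = element, position = position))
}

#' Remove a study element from a group
#'
#' @param model An `ontology_model`.
#' @param group,element Instance ids; the edge must exist.
#' @return Invisibly `NULL`.
#' @export
remove_from_group <- function(model, group, element) {
  e <- model$contains_edges
  hit <- e$parent == group & e$child == element
  if (!any(hit)) {
    ose_abort(sprintf("instance '%s' is not contained in '%s'", element, group),
              "studyframes_not_in_group")
  }
  model$contains_edges <- e[!hit, , drop = FALSE]
  renumber_siblings(model, group)
  invisible(NULL)
}

#' Move a study element to another group
#'
#' Equivalent to remove-then-add, performed atomically: if the move would
#' create a cycle or the target is not a group, the model is left unchanged.
#'
#' @param model An `ontology_model`.
#' @param element Instance id currently contained in some group.
#' @param new_group Target group instance id.
#' @param position Optional 0-based position among the target's children.
#' @return The new edge, invisibly.
#' @export
move_element <- function(model, element, new_group, position = NULL) {
  old <- containment_parent(model, element)
  if (is.null(old)) {
    ose_abort(sprintf("instance '%s' is not contained in any group", element),
              "studyframes_not_in_group")
  }
  get_instance(model, new_group)
  if (!is_instance_of(model, new_group, "_GROUP")) {
    ose_abort(sprintf("instance '%s' is not a group", new_group),
              "studyframes_not_group")
  }
  if (identical(new_group, element) ||
      is_containment_ancestor(model, element, new_group)) {
    ose_abort("move would create a containment cycle", "studyframes_cycle")
  }
  remove_from_group(model, old, element)
  add_to_group(model, new_group, element, position)
}

#' Declare a hierarchy rule
#'
#' A rule `(upper, lower)` states, at the class level, that whenever an
#' instance of `upper` contains an instance `y`, then `y` instantiates
#' `lower`. Instantiation is closed over subcategories.
#'
#' @param model An `ontology_model`.
#' @param upper,lower Category names descending from `_ELEMENT`.
#' @return The rule, invisibly.
#' @export
add_hierarchy_rule <- function(model, upper, lower) {
  for (cat in c(upper, lower)) {
    get_category(model, cat)
    if (!category_is_a(model, cat, "_ELEMENT")) {
      ose_abort(sprintf("'%s' is not a study-element category", cat),
                "studyframes_invalid")
    }
  }
  rule <- list(upper = upper, lower = lower)
  model$hierarchy_rules[[length(model$hierarchy_rules) + 1L]] <- rule
  invisible(rule)
}

#' Check one hierarchy rule as a universal statement
#'
#' Evaluates the class-level containment rule: for every containment edge
#' `(x, y)` where `x` instantiates `upper` (or a subcategory), `y` must
#' instantiate `lower`. Vacuously true when no such `x` exists.
#'
#' @param model An `ontology_model`.
#' @param rule A list with `upper` and `lower` category names.
#' @return Logical.
#' @export
check_hierarchy_rule <- function(model, rule) {
  get_category(model, rule$upper)
  get_category(model, rule$lower)
  e <- model$contains_edges
  if (nrow(e) == 0L) return(TRUE)
  for (i in seq_len(nrow(e))) {
    if (is_instance_of(model, e$parent[i], rule$upper) &&
        !is_instance_of(model, e$child[i], rule$lower)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Validate the study structure against the declared hierarchy rules
#'
#' Two readings are supported. `"strict"` enforces each declared rule as a
#' universal: any edge whose parent instantiates a rule's upper category and
#' whose child does not instantiate its lower category is a violation; this
#' forbids mixed-type children under one upper category. `"any_of"` (the
#' default) treats rules as licenses: every edge must be covered by at least
#' one rule whose upper matches the parent and whose lower matches the child.
#' With no declared rules, `"any_of"` reports nothing (there is no policy to
#' license against).
#'
#' @param model An `ontology_model`.
#' @param rule_mode `"any_of"` or `"strict"`.
#' @return A list of violations describing offending edges; empty if valid.
#' @export
validate_structure <- function(model, rule_mode = c("any_of", "strict")) {
  rule_mode <- match.arg(rule_mode)
  e <- model$contains_edges
  out <- list()
  if (nrow(e) == 0L) return(out)
  if (rule_mode == "strict") {
    for (rule in model$hierarchy_rules) {
      for (i in seq_len(nrow(e))) {
        if (is_instance_of(model, e$parent[i], rule$upper) &&
            !is_instance_of(model, e$child[i], rule$lower)) {
          out[[length(out) + 1L]] <- new_violation(
            "hierarchy-rule",
            sprintf("edge %s -> %s violates rule (%s, %s)",
                    e$parent[i], e$child[i], rule$upper, rule$lower),
            parent = e$parent[i], child = e$child[i])
        }
      }
    }
  } else {
    if (length(model$hierarchy_rules) == 0L) return(out)
    for (i in seq_len(nrow(e))) {
      licensed <- any(vapply(model$hierarchy_rules, function(rule) {
        is_instance_of(model, e$parent[i], rule$upper) &&
          is_instance_of(model, e$child[i], rule$lower)
      }, TRUE))
      if (!licensed) {
        out[[length(out) + 1L]] <- new_violation(
          "unlicensed-edge",
          sprintf("edge %s -> %s licensed by no hierarchy rule",
                  e$parent[i], e$child[i]),
          parent = e$parent[i], child = e$child[i])
      }
    }
  }
  out
}

#' Containment descendants in depth-first pre-order
#'
#' @param model An `ontology_model`.
#' @param instance Instance id.
#' @return Character vector of descendant instance ids (never includes
#'   `instance` itself); empty for leaves.
#' @export
descendants <- function(model, instance) {
  get_instance(model, instance)
  out <- character()
  walk <- function(id) {
    for (ch in contained_children(model, id)) {
      out <<- c(out, ch)
      walk(ch)
    }
  }
  walk(instance)
  out
}
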