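# Independent oracles and generators used across the suite.

# Brute-force evaluation of the class-level containment rule as a quantified
# formula: for all instances x, y, if x instantiates `upper` and there is a
# containment edge x -> y, then y must instantiate `lower`. Category descent
# is re-derived here by walking parent chains, independently of the package
# internals.
oracle_cat_is_a <- function(model, cat, anc) {
  while (!is.null(cat)) {
    if (identical(cat, anc)) return(TRUE)
    cat <- model$categories[[cat]]$parent
  }
  FALSE
}

oracle_instance_of <- function(model, id, cat) {
  oracle_cat_is_a(model, model$instances[[id]]$category, cat)
}

brute_check_rule <- function(model, rule) {
  e <- model$contains_edges
  for (x in names(model$instances)) {
    for (y in names(model$instances)) {
      has_edge <- any(e$parent == x & e$child == y)
      if (has_edge &&
          oracle_instance_of(model, x, rule$upper) &&
          !oracle_instance_of(model, y, rule$lower)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Per-edge licensing oracle for the any_of reading.
brute_unlicensed_edges <- function(model) {
  e <- model$contains_edges
  bad <- character()
  for (i in seq_len(nrow(e))) {
    lic <- FALSE
    for (r in model$hierarchy_rules) {
      if (oracle_instance_of(model, e$parent[i], r$upper) &&
          oracle_instance_of(model, e$child[i], r$lower)) lic <- TRUE
    }
    if (!lic) bad <- c(bad, paste(e$parent[i], e$child[i]))
  }
  bad
}

# A small random study model exercising mixed, partly rule-breaking
# containment. Edges are added through the API (so forest invariants hold by
# construction) but category pairs are chosen freely.
random_hierarchy_model <- function(n_instances = 20) {
  m <- example_domain_model()
  cats <- c("Study", "Page", "Module", "Item")
  ids <- vapply(seq_len(n_instances), function(i) {
    cat <- sample(cats, 1)
    create_instance(m, cat, stats::setNames(
      list(sprintf("%s_%d", cat, i)), "name"))$id
  }, "")
  groups <- ids[vapply(ids, function(id) is_instance_of(m, id, "_GROUP"), TRUE)]
  for (id in ids) {
    if (length(groups) && stats::runif(1) < 0.8) {
      g <- sample(groups, 1)
      try(add_to_group(m, g, id), silent = TRUE)  # skip cycles/self
    }
  }
  m
}

# Independent recursive evaluator for well-typed expression trees (division
# restricted by the generator to nonzero literal denominators).
oracle_eval <- function(node, bindings = list()) {
  switch(node$kind,
    number = node$value,
    boolean = node$value,
    element_ref = bindings[[node$name]],
    constant_ref = bindings[[node$name]],
    relator = {
      vals <- lapply(node$args, oracle_eval, bindings = bindings)
      op <- node$operator
      if (op == "AND") all(unlist(vals))
      else if (op == "OR") any(unlist(vals))
      else if (op == "NOT") !vals[[1]]
      else if (op == "=") unlist(vals)[1] == unlist(vals)[2]
      else if (op %in% c(">", "<", ">=", "<=")) do.call(op, vals)
      else if (op %in% c("+", "*")) Reduce(op, unlist(vals))
      else if (op == "-") vals[[1]] - vals[[2]]
      else if (op == "/") vals[[1]] / vals[[2]]
      else stop("oracle: unknown operator ", op)
    })
}

# Random well-typed expression trees. `vars` names become item: references.
gen_expr <- function(depth, type = "boolean", vars = character()) {
  leaf_numeric <- function() {
    if (length(vars) && stats::runif(1) < 0.3) {
      studyframes::parse_expression(paste0("item:", sample(vars, 1)))
    } else {
      studyframes::parse_expression(as.character(sample(1:9, 1)))
    }
  }
  if (type == "numeric") {
    if (depth <= 0 || stats::runif(1) < 0.3) return(leaf_numeric())
    op <- sample(c("+", "-", "*", "/"), 1)
    args <- if (op %in% c("+", "*")) {
      lapply(seq_len(sample(2:3, 1)), function(i)
        gen_expr(depth - 1, "numeric", vars))
    } else if (op == "/") {
      list(gen_expr(depth - 1, "numeric", vars), leaf_literal_nonzero())
    } else {
      list(gen_expr(depth - 1, "numeric", vars),
           gen_expr(depth - 1, "numeric", vars))
    }
    structure(list(kind = "relator", operator = op, args = args),
              class = "expression_node")
  } else {
    if (depth <= 0 || stats::runif(1) < 0.2) {
      return(studyframes::parse_expression(sample(c("true", "false"), 1)))
    }
    op <- sample(c("AND", "OR", "NOT", ">", "<", ">=", "<=", "="), 1)
    args <- if (op %in% c("AND", "OR")) {
      lapply(seq_len(sample(2:3, 1)), function(i)
        gen_expr(depth - 1, "boolean", vars))
    } else if (op == "NOT") {
      list(gen_expr(depth - 1, "boolean", vars))
    } else {
      list(gen_expr(depth - 1, "numeric", vars),
           gen_expr(depth - 1, "numeric", vars))
    }
    structure(list(kind = "relator", operator = op, args = args),
              class = "expression_node")
  }
}

leaf_literal_nonzero <- function() {
  studyframes::parse_expression(as.character(sample(1:9, 1)))
}

# Brute-force inverse: annotations of a concept by scanning every annotation.
brute_annotations_of <- function(model, concept) {
  hits <- Filter(function(a) concept %in% a$concepts, model$annotations)
  unname(vapply(hits, `[[`, "", "id"))
}
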