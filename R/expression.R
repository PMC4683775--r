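# Typed rule expressions: s-expression surface syntax, arity/type checking,
# canonical serialization, and strict bottom-up evaluation.

#' Default operator table
#'
#' The built-in inventory: variadic boolean `AND`/`OR`, unary `NOT`, binary
#' comparisons `>`, `<`, `>=`, `<=`, `=`, variadic `+` and `*`, binary `-`
#' and `/`. The table can be extended: each entry has `name`, `arity` (an
#' integer, or `NA` for variadic with `min_arity`), `operand` (`"boolean"`,
#' `"numeric"` or `"any"`) and `result` (`"boolean"` or `"numeric"`).
#'
#' @return A named list of operator descriptors.
#' @export
default_operator_table <- function() {
  op <- function(name, arity, operand, result, min_arity = 2L) {
    list(name = name, arity = arity, operand = operand, result = result,
         min_arity = min_arity)
  }
  ops <- list(
    op("AND", NA, "boolean", "boolean"),
    op("OR",  NA, "boolean", "boolean"),
    op("NOT", 1L, "boolean", "boolean"),
    op(">",  2L, "numeric", "boolean"),
    op("<",  2L, "numeric", "boolean"),
    op(">=", 2L, "numeric", "boolean"),
    op("<=", 2L, "numeric", "boolean"),
    op("=",  2L, "any",     "boolean"),
    op("+",  NA, "numeric", "numeric"),
    op("*",  NA, "numeric", "numeric"),
    op("-",  2L, "numeric", "numeric"),
    op("/",  2L, "numeric", "numeric")
  )
  stats::setNames(ops, vapply(ops, `[[`, "", "name"))
}

expr_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "expression_node")
}

tokenize_expression <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Static type of a node: "numeric", "boolean", or "any" for references
# (items and constants may bind to numbers or strings).
node_type <- function(node, operators) {
  switch(node$kind,
         number = "numeric",
         boolean = "boolean",
         element_ref = "any",
         constant_ref = "any",
         relator = operators[[node$operator]]$result)
}

# Resolve item:NAME against _ELEMENT instances by their name / :NAME slot.
resolve_element_ref <- function(model, name) {
  for (id in instances_of(model, "_ELEMENT")) {
    slots <- names(effective_slots(model, model$instances[[id]]$category))
    for (sl in intersect(c("name", ":NAME"), slots)) {
      if (identical(slot_value1(model, id, sl), name)) return(id)
    }
  }
  ose_abort(sprintf("unresolved study-element reference 'item:%s'", name),
            "studyframes_unresolved")
}

resolve_constant_ref <- function(model, name) {
  for (id in instances_of(model, "_CONSTANT")) {
    if (identical(slot_value1(model, id, "name"), name)) return(id)
  }
  ose_abort(sprintf("unresolved constant reference 'const:%s'", name),
            "studyframes_unresolved")
}

#' Parse a rule expression
#'
#' Grammar: `(OP arg ...)`, numeric literals, `true` / `false`,
#' `const:NAME`, `item:NAME`. The resulting tree is validated: operators must
#' be known, arities must match, and operand types must be consistent (e.g.,
#' `AND` over numeric arguments is rejected). When a model is supplied,
#' element and constant references are resolved against it.
#'
#' @param text Expression text.
#' @param model Optional `ontology_model` for reference resolution.
#' @param operators Operator table, by default [default_operator_table()].
#' @return The root `expression_node`.
#' @examples
#' parse_expression("(AND (> 2 1) true)")
#' @export
parse_expression <- function(text, model = NULL,
                             operators = default_operator_table()) {
  toks <- tokenize_expression(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NULL
  advance <- function() {
    t <- peek()
    if (is.null(t)) ose_abort("unexpected end of expression", "studyframes_parse")
    pos <<- pos + 1L
    t
  }
  num_pat <- "^[-+]?[0-9]+(\\.[0-9]+)?$"

  parse_node <- function() {
    t <- advance()
    if (t == "(") {
      opname <- advance()
      if (opname %in% c("(", ")")) {
        ose_abort("expected an operator after '('", "studyframes_parse")
      }
      if (is.null(operators[[opname]])) {
        ose_abort(sprintf("unknown operator '%s'", opname),
                  "studyframes_parse")
      }
      args <- list()
      while (!is.null(peek()) && peek() != ")") {
        args[[length(args) + 1L]] <- parse_node()
      }
      if (is.null(peek())) {
        ose_abort("missing ')' in expression", "studyframes_parse")
      }
      advance()  # consume ")"
      expr_node("relator", operator = opname, args = args)
    } else if (t == ")") {
      ose_abort("unexpected ')'", "studyframes_parse")
    } else if (grepl(num_pat, t)) {
      expr_node("number", value = as.numeric(t))
    } else if (t %in% c("true", "false")) {
      expr_node("boolean", value = identical(t, "true"))
    } else if (grepl("^const:", t)) {
      name <- sub("^const:", "", t)
      ref <- if (!is.null(model)) resolve_constant_ref(model, name)
      expr_node("constant_ref", name = name, ref = ref)
    } else if (grepl("^item:", t)) {
      name <- sub("^item:", "", t)
      ref <- if (!is.null(model)) resolve_element_ref(model, name)
      expr_node("element_ref", name = name, ref = ref)
    } else {
      ose_abort(sprintf("unexpected token '%s'", t), "studyframes_parse")
    }
  }

  node <- parse_node()
  if (!is.null(peek())) {
    ose_abort(sprintf("trailing input after expression: '%s'", peek()),
              "studyframes_parse")
  }
  check_expression(node, operators)
  node
}

# Static validation: arity and operand types, bottom-up.
check_expression <- function(node, operators = default_operator_table()) {
  if (node$kind != "relator") return(node_type(node, operators))
  od <- operators[[node$operator]]
  if (is.null(od)) {
    ose_abort(sprintf("unknown operator '%s'", node$operator),
              "studyframes_parse")
  }
  n <- length(node$args)
  if (is.na(od$arity)) {
    if (n < od$min_arity) {
      ose_abort(sprintf("operator '%s' needs at least %d arguments, got %d",
                        od$name, od$min_arity, n), "studyframes_arity")
    }
  } else if (n != od$arity) {
    ose_abort(sprintf("operator '%s' takes %d argument(s), got %d",
                      od$name, od$arity, n), "studyframes_arity")
  }
  for (a in node$args) {
    at <- check_expression(a, operators)
    if (od$operand != "any" && at != "any" && at != od$operand) {
      ose_abort(sprintf("operator '%s' expects %s arguments, got %s",
                        od$name, od$operand, at), "studyframes_type")
    }
  }
  od$result
}

#' Evaluate a rule expression
#'
#' Strict bottom-up evaluation: every element reference must have a binding
#' and every constant reference must resolve; a missing binding is an error
#' rather than a silently propagated null (rules guard data entry, so silent
#' nulls would hide defects). With `partial = TRUE`, unknowns propagate as
#' `NA` under Kleene three-valued logic instead, for screening use.
#'
#' @param node An `expression_node`.
#' @param bindings Named list/vector mapping element ids (or the names used
#'   in `item:` references) to values.
#' @param constants Named list mapping constant names (or ids) to values.
#' @param partial Return `NA` for unknowns instead of erroring.
#' @return A number, a logical, or `NA` in partial mode.
#' @export
evaluate_expression <- function(node, bindings = list(), constants = list(),
                                partial = FALSE) {
  bindings <- as.list(bindings)
  constants <- as.list(constants)
  lookup <- function(keys, table, what) {
    for (k in keys) {
      if (!is.null(k) && !is.null(table[[k]])) return(table[[k]])
    }
    if (partial) return(NA)
    ose_abort(sprintf("unbound %s reference '%s'", what, keys[[1]] %||% "?"),
              "studyframes_unbound")
  }
  need_num <- function(v, op) {
    if (length(v) == 1L && is.na(v)) return(NA_real_)
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) {
      ose_abort(sprintf("operator '%s' applied to non-numeric value '%s'",
                        op, v), "studyframes_type")
    }
    n
  }
  ev <- function(node) {
    switch(node$kind,
      number = node$value,
      boolean = node$value,
      element_ref = lookup(list(node$name, node$ref), bindings, "study-element"),
      constant_ref = lookup(list(node$name, node$ref), constants, "constant"),
      relator = {
        op <- node$operator
        args <- lapply(node$args, ev)
        switch(op,
          AND = {
            vals <- vapply(args, function(a) as.logical(a)[1], NA)
            if (any(vals %in% FALSE)) FALSE
            else if (anyNA(vals)) NA
            else TRUE
          },
          OR = {
            vals <- vapply(args, function(a) as.logical(a)[1], NA)
            if (any(vals %in% TRUE)) TRUE
            else if (anyNA(vals)) NA
            else FALSE
          },
          NOT = !as.logical(args[[1]])[1],
          "=" = {
            if (anyNA(args[[1]]) || anyNA(args[[2]])) NA
            else {
              a <- args[[1]]; b <- args[[2]]
              if (is.numeric(a) || is.numeric(b)) {
                na <- suppressWarnings(as.numeric(a))
                nb <- suppressWarnings(as.numeric(b))
                if (!is.na(na) && !is.na(nb)) na == nb
                else identical(as.character(a), as.character(b))
              } else identical(as.character(a), as.character(b))
            }
          },
          ">" = , "<" = , ">=" = , "<=" = {
            a <- need_num(args[[1]], op); b <- need_num(args[[2]], op)
            if (is.na(a) || is.na(b)) NA else do.call(op, list(a, b))
          },
          "+" = , "*" = {
            nums <- vapply(args, need_num, 0, op = op)
            if (anyNA(nums)) NA else Reduce(op, nums)
          },
          "-" = {
            a <- need_num(args[[1]], op); b <- need_num(args[[2]], op)
            if (is.na(a) || is.na(b)) NA else a - b
          },
          "/" = {
            a <- need_num(args[[1]], op); b <- need_num(args[[2]], op)
            if (is.na(a) || is.na(b)) NA
            else if (b == 0) {
              ose_abort("division by zero", "studyframes_division")
            } else a / b
          },
          ose_abort(sprintf("operator '%s' has no evaluation rule", op),
                    "studyframes_unknown"))
      })
  }
  ev(node)
}

format_expr_number <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Serialize an expression tree to canonical text
#'
#' Inverse of [parse_expression()]: `parse(serialize(t))` is structurally
#' identical to `t`.
#'
#' @param node An `expression_node`.
#' @return A single string.
#' @export
serialize_expression <- function(node) {
  switch(node$kind,
         number = format_expr_number(node$value),
         boolean = if (isTRUE(node$value)) "true" else "false",
         element_ref = paste0("item:", node$name),
         constant_ref = paste0("const:", node$name),
         relator = sprintf("(%s %s)", node$operator,
                           paste(vapply(node$args, serialize_expression, ""),
                                 collapse = " ")),
         ose_abort("invalid expression node", "studyframes_invalid"))
}
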