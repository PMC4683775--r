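# Declarative mapping between external formats and domain categories/slots.
# One generic engine per format TYPE (xml, table); a concrete format is a
# configuration document, never code.

#' Tag specification of an XML mapping
#'
#' Each TagSpec describes one element name of the external format and how it
#' maps onto the domain ontology:
#'
#' * a *definition* tag (`category` set): each matching element becomes one
#'   instance; mapped attributes and text fill slots; nesting between two
#'   definition tags becomes a containment edge. With `contains = FALSE` the
#'   tag is a definition *section*: imported instances get no containment
#'   edge, and export emits every instance of the category (ODM's CodeList
#'   under MetaDataVersion).
#' * a *reference* tag (`ref_attribute` set): the attribute holds the key
#'   (`ref_slot`) of an existing instance of `category`; the resolved target
#'   is linked to the enclosing instance either by containment
#'   (`ref_into = "contains"`) or through an `instance_ref` slot
#'   (`ref_into = "<slot>"`). This covers ODM's referential style
#'   (ItemRef/CodeListRef OIDs).
#' * a *structural* tag (neither): passed through transparently; attribute
#'   and text mappings, if any, apply to the enclosing instance (appending
#'   for multi-valued slots).
#'
#' @param tag XML element name.
#' @param category Mapped category name, or `NULL` for structural tags.
#' @param text_slot Slot receiving the element text, or `NULL`.
#' @param attributes Named character vector/list mapping attribute names to
#'   slot names.
#' @param subtags Ordered character vector of declared child tag names.
#' @param is_root Exactly one TagSpec per mapping is the root.
#' @param contains For definition tags: create/emit containment (default
#'   `TRUE`).
#' @param ref_attribute For reference tags: the attribute holding the key.
#' @param ref_slot Key slot on the target category (default `":NAME"`).
#' @param ref_into `"contains"` or the name of an `instance_ref` slot on the
#'   enclosing instance.
#' @return An object of class `tag_spec`.
#' @export
tag_spec <- function(tag, category = NULL, text_slot = NULL,
                     attributes = character(), subtags = character(),
                     is_root = FALSE, contains = TRUE,
                     ref_attribute = NULL, ref_slot = ":NAME",
                     ref_into = "contains") {
  structure(
    list(tag = tag, category = category, text_slot = text_slot,
         attributes = as.list(attributes), subtags = as.character(subtags),
         is_root = is_root, contains = contains,
         ref_attribute = ref_attribute, ref_slot = ref_slot,
         ref_into = ref_into),
    class = "tag_spec"
  )
}

is_ref_spec <- function(spec) !is.null(spec$ref_attribute)
is_def_spec <- function(spec) !is.null(spec$category) && !is_ref_spec(spec)

#' Construct an XML format mapping
#'
#' @param name Mapping name.
#' @param tags List of [tag_spec()]s, exactly one with `is_root = TRUE`.
#' @param namespace Optional namespace URI; matched by URI, not prefix.
#' @return An object of class `format_mapping` with `format_type = "xml"`.
#' @export
xml_mapping <- function(name, tags, namespace = NULL) {
  named <- stats::setNames(tags, vapply(tags, `[[`, "", "tag"))
  roots <- vapply(named, function(t) isTRUE(t$is_root), TRUE)
  if (sum(roots) != 1L) {
    ose_abort("an XML mapping needs exactly one root TagSpec",
              "studyframes_invalid")
  }
  for (t in named) {
    missing <- setdiff(t$subtags, names(named))
    if (length(missing)) {
      ose_abort(sprintf("tag '%s' declares undeclared subtag(s): %s",
                        t$tag, paste(missing, collapse = ", ")),
                "studyframes_invalid")
    }
  }
  structure(list(name = name, format_type = "xml", tags = named,
                 root = names(named)[roots], namespace = namespace),
            class = "format_mapping")
}

#' Construct a delimited-table format mapping
#'
#' @param name Mapping name.
#' @param target_category Category instantiated per row.
#' @param columns Named character vector/list mapping column headers to slot
#'   names, in output column order.
#' @return An object of class `format_mapping` with `format_type = "table"`.
#' @export
table_mapping <- function(name, target_category, columns) {
  structure(list(name = name, format_type = "table",
                 target_category = target_category,
                 columns = as.list(columns)),
            class = "format_mapping")
}

# Convert imported text to the slot's value kind. Formats carry text only;
# the slot definition is authoritative for the kind.
convert_for_slot <- function(model, category, slot, text) {
  sd <- effective_slots(model, category)[[slot]]
  if (is.null(sd)) {
    ose_abort(sprintf("mapping references unknown slot '%s' of category '%s'",
                      slot, category), "studyframes_unknown_slot")
  }
  switch(sd$value_kind,
         number = {
           v <- suppressWarnings(as.numeric(text))
           if (is.na(v)) {
             ose_abort(sprintf("cannot read '%s' as a number for slot '%s'",
                               text, slot), "studyframes_kind_mismatch")
           }
           v
         },
         boolean = tolower(text) %in% c("true", "yes", "1"),
         text)
}

value_to_text <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE,
                            drop0trailing = TRUE)
  else if (is.logical(v)) tolower(as.character(v))
  else as.character(v)
}

#' Import an ODM-style XML document through a mapping
#'
#' Walks the document against the mapping's tag tree. Elements matching a
#' definition TagSpec become instances; mapped attributes and text fill
#' slots; nesting becomes containment edges in document order; structural
#' tags are traversed transparently; reference tags are resolved after the
#' walk. In strict mode an undeclared element is an error; in lenient mode it
#' is skipped with a log line.
#'
#' @param model An `ontology_model` already holding the mapped categories.
#' @param mapping An [xml_mapping()].
#' @param document An `xml2` document, a path, or an XML string.
#' @param strict Error on unmapped elements and unresolved references
#'   (default `TRUE`).
#' @return Character vector of created instance ids, in creation order.
#' @export
import_xml <- function(model, mapping, document, strict = TRUE) {
  stopifnot(identical(mapping$format_type, "xml"))
  doc <- if (inherits(document, "xml_document")) document
         else xml2::read_xml(document)
  root <- xml2::xml_root(doc)
  root_spec <- mapping$tags[[mapping$root]]
  if (!is.null(mapping$namespace)) {
    uris <- unique(unlist(xml2::xml_ns(doc)))
    if (!mapping$namespace %in% uris) {
      ose_abort(sprintf("document namespace does not include '%s'",
                        mapping$namespace), "studyframes_root_mismatch")
    }
    xml2::xml_ns_strip(doc)
  }
  if (!identical(xml2::xml_name(root), root_spec$tag)) {
    ose_abort(sprintf("document root <%s> does not match mapping root <%s>",
                      xml2::xml_name(root), root_spec$tag),
              "studyframes_root_mismatch")
  }

  created <- character()
  pending_refs <- list()

  apply_values <- function(el, spec, instance_id, category) {
    for (attr in names(spec$attributes)) {
      av <- xml2::xml_attr(el, attr)
      if (!is.na(av)) {
        append_slot_value(model, instance_id, spec$attributes[[attr]],
                          convert_for_slot(model, category,
                                           spec$attributes[[attr]], av))
      }
    }
    if (!is.null(spec$text_slot)) {
      # own text only (not descendant text): concatenate direct text nodes
      own <- xml2::xml_find_all(el, "./text()")
      txt <- trimws(paste(xml2::xml_text(own), collapse = ""))
      if (nzchar(txt)) {
        append_slot_value(model, instance_id, spec$text_slot,
                          convert_for_slot(model, category, spec$text_slot, txt))
      }
    }
  }

  walk <- function(el, spec, enclosing) {
    this_enclosing <- enclosing
    if (is_ref_spec(spec)) {
      key <- xml2::xml_attr(el, spec$ref_attribute)
      if (is.na(key)) {
        if (strict) ose_abort(sprintf(
          "reference tag <%s> lacks attribute '%s'", spec$tag,
          spec$ref_attribute), "studyframes_unresolved")
        ose_log(sprintf("skipping <%s> without '%s'", spec$tag,
                        spec$ref_attribute))
        return(invisible(NULL))
      }
      pending_refs[[length(pending_refs) + 1L]] <<-
        list(enclosing = enclosing, spec = spec, key = key)
      return(invisible(NULL))  # reference tags have no mapped children
    }
    if (is_def_spec(spec)) {
      inst <- create_instance(model, spec$category)
      created <<- c(created, inst$id)
      apply_values(el, spec, inst$id, spec$category)
      if (isTRUE(spec$contains) && !is.null(enclosing)) {
        add_to_group(model, enclosing, inst$id)
      }
      this_enclosing <- inst$id
    } else if (!is.null(enclosing)) {
      # structural tag: values flow to the enclosing instance
      encl_cat <- get_instance(model, enclosing)$category
      apply_values(el, spec, enclosing, encl_cat)
    }
    for (child in xml2::xml_children(el)) {
      cname <- xml2::xml_name(child)
      if (cname %in% spec$subtags) {
        walk(child, mapping$tags[[cname]], this_enclosing)
      } else if (strict) {
        ose_abort(sprintf("unmapped element <%s> under <%s>", cname, spec$tag),
                  "studyframes_unmapped")
      } else {
        ose_log(sprintf("skipping unmapped element <%s>", cname))
      }
    }
    invisible(NULL)
  }

  walk(root, root_spec, NULL)

  for (ref in pending_refs) {
    spec <- ref$spec
    target <- NULL
    for (id in instances_of(model, spec$category)) {
      if (identical(slot_value1(model, id, spec$ref_slot), ref$key)) {
        target <- id
        break
      }
    }
    if (is.null(target)) {
      if (strict) ose_abort(sprintf(
        "unresolved reference <%s %s=\"%s\">", spec$tag, spec$ref_attribute,
        ref$key), "studyframes_unresolved")
      ose_log(sprintf("unresolved reference '%s' skipped", ref$key))
      next
    }
    if (identical(spec$ref_into, "contains")) {
      add_to_group(model, ref$enclosing, target)
    } else {
      append_slot_value(model, ref$enclosing, spec$ref_into, target)
    }
  }
  created
}

#' Export instances to an ODM-style XML document through a mapping
#'
#' Inverse of [import_xml()]: instances become elements, slot values become
#' attributes/text, containment edges become nesting in sibling-ordinal
#' order. Empty optional attributes are omitted. Output is byte-stable for a
#' given project.
#'
#' @param model An `ontology_model`.
#' @param mapping An [xml_mapping()].
#' @param root_instances Instance ids placed at the top level (matched to the
#'   root's definition subtags by category).
#' @return An `xml_document`.
#' @export
export_xml <- function(model, mapping, root_instances = character()) {
  stopifnot(identical(mapping$format_type, "xml"))
  root_spec <- mapping$tags[[mapping$root]]

  new_el <- function(parent, name) {
    xml2::xml_add_child(parent, name)
  }

  fill_values <- function(el, spec, instance_id) {
    for (attr in names(spec$attributes)) {
      v <- slot_value1(model, instance_id, spec$attributes[[attr]])
      if (!is.null(v)) xml2::xml_set_attr(el, attr, value_to_text(v))
    }
    if (!is.null(spec$text_slot)) {
      v <- slot_value1(model, instance_id, spec$text_slot)
      if (!is.null(v)) xml2::xml_set_text(el, value_to_text(v))
    }
  }

  emit_children <- function(node, spec, enclosing) {
    for (ctag in spec$subtags) {
      cspec <- mapping$tags[[ctag]]
      if (is_ref_spec(cspec)) {
        targets <- if (identical(cspec$ref_into, "contains")) {
          if (is.null(enclosing)) character()
          else Filter(function(id) is_instance_of(model, id, cspec$category),
                      contained_children(model, enclosing))
        } else {
          if (is.null(enclosing)) character()
          else unlist(slot_value(model, enclosing, cspec$ref_into),
                      use.names = FALSE)
        }
        for (tid in targets) {
          key <- slot_value1(model, tid, cspec$ref_slot)
          el <- new_el(node, cspec$tag)
          xml2::xml_set_attr(el, cspec$ref_attribute,
                             value_to_text(key %||% ""))
        }
      } else if (is_def_spec(cspec)) {
        cands <- if (!isTRUE(cspec$contains)) {
          instances_of(model, cspec$category)
        } else if (is.null(enclosing)) {
          Filter(function(id) is_instance_of(model, id, cspec$category),
                 root_instances)
        } else {
          Filter(function(id) is_instance_of(model, id, cspec$category),
                 contained_children(model, enclosing))
        }
        for (id in cands) {
          el <- new_el(node, cspec$tag)
          fill_values(el, cspec, id)
          emit_children(el, cspec, id)
        }
      } else {
        # structural tag
        n_map <- length(cspec$attributes) + as.integer(!is.null(cspec$text_slot))
        if (length(cspec$subtags) == 0L && n_map == 1L && !is.null(enclosing)) {
          # leaf value carrier: one element per slot value
          slot <- if (length(cspec$attributes)) cspec$attributes[[1]]
                  else cspec$text_slot
          for (v in slot_value(model, enclosing, slot)) {
            el <- new_el(node, cspec$tag)
            if (length(cspec$attributes)) {
              xml2::xml_set_attr(el, names(cspec$attributes)[1],
                                 value_to_text(v))
            } else {
              xml2::xml_set_text(el, value_to_text(v))
            }
          }
        } else {
          el <- new_el(node, cspec$tag)
          if (!is.null(enclosing)) fill_values(el, cspec, enclosing)
          emit_children(el, cspec, enclosing)
        }
      }
    }
  }

  doc <- if (is.null(mapping$namespace)) {
    xml2::xml_new_root(root_spec$tag)
  } else {
    xml2::xml_new_root(root_spec$tag, xmlns = mapping$namespace)
  }
  if (is_def_spec(root_spec)) {
    matching <- Filter(function(id)
      is_instance_of(model, id, root_spec$category), root_instances)
    if (length(matching) != 1L) {
      ose_abort("a category-mapped root tag requires exactly one root instance",
                "studyframes_invalid")
    }
    fill_values(doc, root_spec, matching[[1]])
    emit_children(doc, root_spec, matching[[1]])
  } else {
    emit_children(doc, root_spec, NULL)
  }
  doc
}

#' Canonical, namespace/attribute-order-insensitive XML comparison
#'
#' @param a,b `xml2` documents/nodes, paths, or XML strings.
#' @return Logical: are the two documents structurally equivalent (same
#'   element tree, attribute sets, and whitespace-normalized text)?
#' @export
xml_equivalent <- function(a, b) {
  identical(xml_canonical_string(a), xml_canonical_string(b))
}

xml_canonical_string <- function(x) {
  doc <- if (inherits(x, c("xml_document", "xml_node"))) x else xml2::read_xml(x)
  node <- xml2::xml_root(doc)
  canon <- function(el) {
    at <- xml2::xml_attrs(el)
    at <- at[!grepl("^xmlns", names(at))]
    at <- at[order(names(at))]
    own <- xml2::xml_find_all(el, "./text()")
    txt <- trimws(paste(xml2::xml_text(own), collapse = " "))
    txt <- gsub("\\s+", " ", txt)
    kids <- vapply(xml2::xml_children(el), canon, "")
    sprintf("<%s|%s|%s>[%s]", xml2::xml_name(el),
            paste(names(at), at, sep = "=", collapse = ","),
            txt, paste(kids, collapse = ""))
  }
  canon(node)
}

#' Import a delimited table through a mapping
#'
#' One instance of the mapping's target category is created per row; mapped
#' columns fill slots. Multi-valued slots are encoded as `|`-separated cell
#' values.
#'
#' @param model An `ontology_model`.
#' @param mapping A [table_mapping()].
#' @param table A data frame or a CSV path (RFC 4180, header row required).
#' @return Character vector of created instance ids.
#' @export
import_table <- function(model, mapping, table) {
  stopifnot(identical(mapping$format_type, "table"))
  df <- if (is.data.frame(table)) table
        else utils::read.csv(table, colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) {
    ose_abort("duplicate column headers in table", "studyframes_invalid")
  }
  missing <- setdiff(names(mapping$columns), names(df))
  if (length(missing)) {
    ose_abort(sprintf("table lacks mapped column(s): %s",
                      paste(missing, collapse = ", ")), "studyframes_invalid")
  }
  cat <- mapping$target_category
  slots <- effective_slots(model, cat)
  ids <- character()
  for (i in seq_len(nrow(df))) {
    inst <- create_instance(model, cat)
    ids <- c(ids, inst$id)
    for (col in names(mapping$columns)) {
      cell <- as.character(df[[col]][i])
      if (is.na(cell) || !nzchar(cell)) next
      slot <- mapping$columns[[col]]
      multi <- (slots[[slot]]$cardinality_max %||% 1) > 1
      parts <- if (multi) strsplit(cell, "|", fixed = TRUE)[[1]] else cell
      for (p in parts) {
        append_slot_value(model, inst$id, slot,
                          convert_for_slot(model, cat, slot, p))
      }
    }
  }
  ids
}

#' Export instances to a delimited table through a mapping
#'
#' @param model An `ontology_model`.
#' @param mapping A [table_mapping()].
#' @param instances Instance ids of the target category; one row each, in
#'   the given order. Columns follow the mapping order.
#' @param path Optional CSV output path; when `NULL` the data frame is
#'   returned.
#' @return A data frame (invisibly when written to `path`).
#' @export
export_table <- function(model, mapping, instances, path = NULL) {
  stopifnot(identical(mapping$format_type, "table"))
  cols <- names(mapping$columns)
  out <- as.data.frame(
    stats::setNames(replicate(length(cols),
                              character(length(instances)),
                              simplify = FALSE), cols),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(instances)) {
    for (col in cols) {
      vals <- slot_value(model, instances[[j]], mapping$columns[[col]])
      out[[col]][j] <- paste(vapply(vals, value_to_text, ""), collapse = "|")
    }
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

instance_title <- function(model, id) {
  slots <- names(effective_slots(model, get_instance(model, id)$category))
  for (sl in intersect(c("name", ":NAME"), slots)) {
    v <- slot_value1(model, id, sl)
    if (!is.null(v)) return(as.character(v))
  }
  id
}

#' Render a case-report-form preview
#'
#' Produces a deterministic markdown outline of a study subtree: group titles
#' become headings by containment depth; items become labelled fields showing
#' codelist options, units of measure and ranges.
#'
#' @param model An `ontology_model`.
#' @param root Instance id of a group.
#' @return A single markdown string.
#' @export
render_crf_preview <- function(model, root) {
  get_instance(model, root)
  if (!is_instance_of(model, root, "_GROUP")) {
    ose_abort(sprintf("instance '%s' is not a group", root),
              "studyframes_not_group")
  }
  lines <- character()
  emit <- function(id, depth) {
    if (is_instance_of(model, id, "_GROUP")) {
      lines <<- c(lines, paste(strrep("#", min(depth, 6L)),
                               instance_title(model, id)), "")
      for (ch in contained_children(model, id)) emit(ch, depth + 1L)
    } else {
      label <- instance_title(model, id)
      extras <- character()
      slots <- names(effective_slots(model, get_instance(model, id)$category))
      if ("unit_of_measure" %in% slots) {
        u <- slot_value1(model, id, "unit_of_measure")
        if (!is.null(u)) extras <- c(extras,
                                     sprintf("(%s)", instance_title(model, u)))
      }
      codes <- element_codelist_codes(model, id)
      if (!is.null(codes) && length(codes)) {
        extras <- c(extras, sprintf("[%s]", paste(codes, collapse = " | ")))
      } else if ("range" %in% slots) {
        r <- slot_value1(model, id, "range")
        if (!is.null(r)) extras <- c(extras, sprintf("range %s", r))
      }
      lines <<- c(lines, paste(c(sprintf("- **%s**: ______", label), extras),
                               collapse = " "))
    }
  }
  emit(root, 1L)
  paste(sub("\\s+$", "", lines), collapse = "\n")
}

#' The shipped ODM 1.3-style mapping
#'
#' Covers the metadata elements `ODM / Study / GlobalVariables / StudyName /
#' MetaDataVersion / ItemGroupDef / ItemDef / Description / TranslatedText /
#' CodeListRef / CodeList / CodeListItem`. The engine is dialect-agnostic;
#' this document is one dialect. Studies map to `Study`, item groups to
#' `Module`, items to `Item`, codelists to `Codelist`; `OID` attributes map
#' to the `:NAME` slot, `CodeListRef` resolves into the item's `codelist`
#' slot, and `CodeList` is a definition section (no containment).
#'
#' @return A [xml_mapping()].
#' @export
odm_mapping <- function() {
  xml_mapping(
    name = "odm-1.3-metadata",
    namespace = "http://www.cdisc.org/ns/odm/v1.3",
    tags = list(
      tag_spec("ODM", is_root = TRUE, subtags = "Study"),
      tag_spec("Study", category = "Study",
               attributes = c(OID = ":NAME"),
               subtags = c("GlobalVariables", "MetaDataVersion")),
      tag_spec("GlobalVariables", subtags = "StudyName"),
      tag_spec("StudyName", text_slot = "name"),
      tag_spec("MetaDataVersion",
               subtags = c("ItemGroupDef", "CodeList")),
      tag_spec("ItemGroupDef", category = "Module",
               attributes = c(OID = ":NAME", Name = "name"),
               subtags = "ItemDef"),
      tag_spec("ItemDef", category = "Item",
               attributes = c(OID = ":NAME", Name = "name",
                              DataType = "data_type"),
               subtags = c("Description", "CodeListRef")),
      tag_spec("Description", subtags = "TranslatedText"),
      tag_spec("TranslatedText", text_slot = "description"),
      tag_spec("CodeListRef", category = "Codelist",
               ref_attribute = "CodeListOID", ref_slot = ":NAME",
               ref_into = "codelist"),
      tag_spec("CodeList", category = "Codelist", contains = FALSE,
               attributes = c(OID = ":NAME", Name = "name"),
               subtags = "CodeListItem"),
      tag_spec("CodeListItem", attributes = c(CodedValue = "codes"))
    )
  )
}

#' Serialize / restore mapping documents as JSON
#'
#' The JSON shape is `{name, format_type, root, namespace, tags: [{tag,
#' category, text_slot, attributes, subtags, is_root, contains,
#' ref_attribute, ref_slot, ref_into}]}` for XML mappings and `{name,
#' format_type, target_category, columns}` for table mappings.
#'
#' @param mapping A `format_mapping`.
#' @return `mapping_to_list()`: a plain list; `load_mapping()`: a
#'   `format_mapping`.
#' @export
mapping_to_list <- function(mapping) {
  if (identical(mapping$format_type, "table")) {
    return(list(name = mapping$name, format_type = "table",
                target_category = mapping$target_category,
                columns = mapping$columns))
  }
  list(
    name = mapping$name, format_type = "xml", root = mapping$root,
    namespace = mapping$namespace,
    tags = unname(lapply(mapping$tags, function(t) {
      out <- list(tag = t$tag, is_root = isTRUE(t$is_root),
                  contains = isTRUE(t$contains))
      for (f in c("category", "text_slot", "ref_attribute", "ref_slot",
                  "ref_into")) {
        if (!is.null(t[[f]])) out[[f]] <- t[[f]]
      }
      if (length(t$attributes)) out$attributes <- t$attributes
      if (length(t$subtags)) out$subtags <- as.list(t$subtags)
      out
    }))
  )
}

#' @rdname mapping_to_list
#' @param x A list as produced by `mapping_to_list()` (e.g., parsed JSON).
#' @export
mapping_from_list <- function(x) {
  if (identical(x$format_type, "table")) {
    return(table_mapping(x$name, x$target_category, x$columns))
  }
  tags <- lapply(x$tags, function(t) {
    tag_spec(t$tag,
             category = json_opt(t$category),
             text_slot = json_opt(t$text_slot),
             attributes = unlist(t$attributes %||% list()),
             subtags = unlist(t$subtags %||% character()),
             is_root = isTRUE(t$is_root),
             contains = !identical(t$contains, FALSE),
             ref_attribute = json_opt(t$ref_attribute),
             ref_slot = json_opt(t$ref_slot) %||% ":NAME",
             ref_into = json_opt(t$ref_into) %||% "contains")
  })
  xml_mapping(x$name, tags, namespace = json_opt(x$namespace))
}

#' @rdname mapping_to_list
#' @param path JSON file path.
#' @export
load_mapping <- function(path) {
  mapping_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' @rdname mapping_to_list
#' @export
save_mapping <- function(mapping, path) {
  jsonlite::write_json(mapping_to_list(mapping), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
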