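---
title: "Frame-based study metadata: model, validation and mappings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-based study metadata: model, validation and mappings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studyframes)
```

## The frame model

`studyframes` represents study metadata with frames: *categories* (classes)
carry *template slots*, slots are constrained by *facets*, and the metadata
themselves are *instances* with slot values. Three layers are
distinguished by a tag on each category: `TLO` (foundational), `TO` (the
generic task ontology bootstrapped by `bootstrap_task_ontology()`), and
`DO` (organization-specific domain categories added with
`define_category()`). The task ontology is fixed: `_ELEMENT` with exactly
the subclasses `_CONSTANT`, `_OBJECT`, `_GROUP`, `_ANNOTATION` and
`_EXPORT`; a hidden `_CONFIG` subtree holding format mappings and
annotation types; `_ANNOTATING_ONTOLOGY_ROOT` for external ontology
concepts; and a `_MATH` subtree naming the building blocks of rule
expressions. Hidden status is closed downward — everything configuration
stays invisible to study editors — and the `_ELEMENT`, `_CONFIG`, `_MATH`
and `_ANNOTATING_ONTOLOGY_ROOT` roots are abstract (non-instantiable).

Design choices worth stating explicitly:

* **Mutable model.** An `ontology_model` is environment-backed; operations
  mutate it in place and return the created record. This matches how a
  metadata repository is used (a long-lived, stateful knowledge base edited
  by many small operations) and keeps operation signatures natural.
* **Instance ids** are opaque strings from a per-model counter
  (`inst-1`, `inst-2`, ...). Imports are therefore reproducible and
  diff-able; no timestamps or UUIDs.
* **No silent coercion.** A slot's `value_kind` is authoritative; the
  string `"01"` stays a string even though it parses as a number, so
  codelist codes survive round-trips. Conversion happens only at format
  boundaries (`import_xml()`/`import_table()`), where the external
  representation is text by nature and the slot definition says what it
  means.
* **Multi-valued slots are ordered lists**, and order is preserved across
  save/load and export/import.
* **Validation returns data, not errors.** `validate_instance()` and
  `validate_structure()` return violation objects (one per breached
  cardinality bound, facet, or unlicensed edge) and never mutate the model;
  creation-time checks (`create_instance()`) throw, because there the caller
  is constructing new state.
* Higher-order categories of the foundational ontology are represented by
  the layer tag only; no executable higher-order logic is needed for any
  operation the package performs.

## Study hierarchy and its two validation readings

The study structure is an ordered containment forest over instances: a
child has at most one parent, sibling positions are contiguous ordinals,
and cycles are rejected (moves are atomic — a failing move leaves the model
untouched). Class-level structure policy is written as hierarchy rules
`(upper, lower)` with the universal reading

> for all instances x, y: if x instantiates `upper` (or a subcategory) and
> x contains y, then y instantiates `lower` (or a subcategory).

Taken literally, a set of such universals forbids mixed children: a `Page`
that contains both a `Module` and a free-standing `Item` violates
`(Page, Module)` no matter what other rules exist. Real case report forms
mix. The package therefore implements both readings, selectable in
`validate_structure()`:

* `strict` — every declared rule is enforced as the literal universal;
  use this to reproduce the formal semantics exactly;
* `any_of` (default) — rules act as licenses, and every edge must be
  covered by at least one rule matching both endpoints. With no rules
  declared, `any_of` reports nothing: there is no declared policy to
  license against.

`check_hierarchy_rule()` evaluates a single rule and is tested for
equivalence against a brute-force double loop over instances × edges
(models up to 50 instances, randomized), with category descent re-derived
independently in the test oracle.

## Format mappings

Import/export is implemented once per format *type* and configured per
concrete format by a declarative mapping document (JSON-serializable; see
`inst/extdata/odm.mapping.json`). For XML, each `tag_spec()` is either a
*definition* tag (element ↔ instance; attributes/text ↔ slots; nesting ↔
containment), a *definition section* (`contains = FALSE`: instances without
containment, exported model-wide — ODM's `CodeList` under
`MetaDataVersion`), a *reference* tag (an attribute holds the key of an
existing instance, linked into containment or into an `instance_ref` slot —
ODM's `CodeListRef`), or a *structural* tag passed through transparently
(its attribute/text mappings apply to the enclosing instance, appending for
multi-valued slots, as with `CodeListItem/@CodedValue`). References are
resolved in a second phase after the document walk, so definition order does
not matter.

The shipped ODM mapping is one dialect of ODM 1.3 metadata covering
`ODM/Study/GlobalVariables/StudyName/MetaDataVersion/ItemGroupDef/ItemDef/
Description/TranslatedText/CodeListRef/CodeList/CodeListItem`; clinical
*data* (`ClinicalData`/`ItemData`) is deliberately out of scope — the
package manages metadata. The engine is dialect-agnostic: the mapping
document, not code, is what changes per format. The table engine covers the
spreadsheet role via CSV (RFC 4180, header row required); multi-valued
slots are encoded as `|`-separated cells.

Round-trip comparison needs two notions of equality: `models_identical()`
(bit-identical structure) and `projects_isomorphic()` (equality up to
instance-id relabelling, keying instances by category + name — adequate
whenever names are unique, which the generators guarantee). XML equivalence
(`xml_equivalent()`) is attribute-order-insensitive and
whitespace-normalized, and namespaces are matched by URI, not prefix.

## Annotation semantics

Annotating ontologies load from OBO 1.2 flat files (`[Term]` stanzas; `id`,
`name`, `is_a` honored; obsolete terms skipped; a nameless term gets its id
as label; `is_a` cycles and duplicate ids rejected). Concept identity is
the term id, never the label, and several ontologies can coexist, each
under its own tag.

An annotation links one or more AND-connected element conditions to
concepts via a typed relation. A condition is an element alone (presence
suffices), an element + codelist code (the code must be a member of the
element's codelist), or an element + inclusive numeric range — ranges are
only legal on elements *without* a codelist. Range literals follow
`"[lower;upper]"` with either bound optional: `"[121;]"` means ≥ 121. The
lower bound's inclusivity is given by that reading; the upper bound is
made inclusive symmetrically. During evaluation a non-numeric value against
a range makes the condition false rather than raising, because screening a
half-filled record is a normal situation; the event is logged when
`options(studyframes.verbose = TRUE)`.

The concept-side inverse (`_annotations`, the inverse slot of
`_annotating_concepts`) is realized as an index updated on every
create/delete, rather than as a meta-class slot; the tests assert its
equivalence with a full scan of all annotations after randomized mutation
sequences.

## Rule expressions

Expressions are typed trees over numbers, booleans, constants and study
elements, written as s-expressions (`(AND (> item:SBP 121) ...)`) — a
surface syntax chosen for unambiguous round-tripping
(`parse_expression()` ∘ `serialize_expression()` is the identity, checked
on 200 generator-produced random trees per run). The operator floor is
variadic `AND`/`OR` (≥ 2 arguments), unary `NOT`, binary comparisons
(`=` also accepts string pairs), variadic `+`/`*` and binary `-`/`/`; the
table is user-extensible. Arity and operand types are checked statically at
parse time, and the type system is sound in the tested sense: well-typed
trees never raise type errors during evaluation.

Evaluation is strict: a missing binding or constant is an error, not a
silently propagated null — rules guard data entry, and silent nulls hide
defects. `partial = TRUE` switches to Kleene three-valued logic (`NA`
propagates; `AND` with a false argument is still false) for screening
incomplete records. Division by zero is always an error.

## Fixtures and generators

`build_example_project()` is deterministic and seed-independent: Page `B1`
containing Module `Socio-demographic data`; a dyspnea-at-rest item with a
YES/NO codelist annotated as `symptom_of` *Congestive heart failure*; a
systolic-blood-pressure item (mmHg, no codelist) annotated with range
`[121;]` as `symptom_of` *Elevated systolic blood pressure*; a four-concept
synthetic phenotype mini-hierarchy (shipped as
`inst/extdata/synthetic_phenotype.obo` — a stand-in written for this
package, not an excerpt of any published ontology, with MP-prefixed
placeholder ids); hierarchy rules; and one stored rule expression. The item
name `SYSTOLIC_BLOOD_PRESURE` is spelled as in the source material.

`generate_random_project(n_items, seed)` emulates realistic small studies:
one study, up to `ceiling(n_items/4)` modules, items with random names,
data types, optional descriptions, and codelists on roughly a third of
items — the attribute coverage of the shipped ODM mapping, so generated
projects exercise the full round trip. What it does **not** emulate:
multi-study documents, non-unique item names, clinical data values,
annotations, and deliberately malformed input (those are covered by
targeted unit tests instead). Passing round-trip tests on these projects
therefore demonstrates mapping-engine correctness for well-formed metadata,
not robustness against arbitrary real-world ODM exports. Generation is
seeded and restores the caller's RNG state.

Problem sizes used by the test suite and the acceptance script — 100
generated projects for the round trip, random models of 5–50 instances for
the rule checker, 150–200 mutation steps for the inverse index, 200 random
trees of depth ≤ 5 for the expression engine — were chosen as the smallest
sizes at which every code path (empty projects, codelist-free items,
variadic operators, deleted annotations) is routinely exercised.

## Persistence

A project is one JSON document (`format_version` 1.0) containing
categories, instances, containment edges, hierarchy rules, concepts,
annotations and registered mappings. Unbounded cardinality is serialized as
the string `"unbounded"` (JSON has no infinity). Loading checks the major
version (a newer major is an explicit error, never a partial load), reports
missing required fields by path, and preserves unknown top-level fields so
that files from newer minor versions survive a load/save cycle.

## Known limitations

* The containment structure is a forest, not a DAG: shared children are
  rejected. Reuse of an item across groups is expressed by separate
  instances or by annotations, not shared containment.
* No OWL import and no reasoning beyond the is_a transitive closure of
  loaded concepts.
* `projects_isomorphic()` requires instances to be uniquely keyed by
  category + name; projects violating that must be compared with
  `models_identical()` or a custom matching.
* The table engine does not represent containment; it targets one category
  per mapping.
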