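# studyframes

Frame-based representation and management of clinical and epidemiological
study metadata, as a headless R library with a small `ose` command-line
front end.

## The problem

Before a clinical or epidemiological study can collect data, its *metadata*
must be specified: every item (a questionnaire question, a measurement) with
its attributes (name, description, data type, unit of measure, codelist,
range, rules), and the study structure that groups items into modules,
pages, assessments and studies. Research organizations specify these
differently — different attributes, different grouping levels, different
study software — so the same metadata gets re-entered again and again.

`studyframes` addresses this with an ontology-founded frame model:

* **Frames.** Study metadata are instances of *categories* (classes)
  carrying *slots* (attributes) constrained by *facets* (cardinality,
  min/max, allowed values). A generic, bootstrapped **task ontology** (class
  names starting with `_`) provides the study-element scaffold — `_ELEMENT`
  with subclasses `_CONSTANT`, `_OBJECT`, `_GROUP`, `_ANNOTATION`,
  `_EXPORT`, a hidden `_CONFIG` subtree, and `_ANNOTATING_ONTOLOGY_ROOT` —
  and each organization plugs in its own **domain ontology** (`Study`,
  `Page`, `Module`, `Item`, `Codelist`, ...) as subcategories, with freely
  defined slots.
* **Study hierarchy.** Instances are arranged in an ordered containment
  forest via the `_contains` relation (e.g., Page `B1` contains Module
  `Socio-demographic data`). Class-level hierarchy rules
  `upper HIERARCHY_SUBCLASS lower`, read as
  `(∀ x y) (x :: upper ∧ contains(x, y) → y :: lower)`,
  are validated either literally (`strict`) or as per-edge licenses
  (`any_of`).
* **Declarative format mappings.** Import/export engines are written once
  per format *type* (ODM-style XML, delimited tables) and configured per
  concrete format by a declarative mapping document: tags map to categories,
  attributes and text map to slots, nesting maps to containment, and
  reference tags (`ItemRef`/`CodeListRef`-style OID attributes) resolve to
  existing instances. A ready-made ODM 1.3-style metadata mapping ships with
  the package, plus a plain-text case report form (CRF) preview.
* **Semantic annotation.** External ontologies (phenotype ontologies,
  LOINC-like catalogues) load from OBO flat files. Annotations link
  AND-connected element/value conditions — an item with a codelist answer, or
  an item with a numeric range such as `[121;]` (≥ 121) — to ontology
  concepts through typed relations (`symptom_of`, `risk_factor_of`), with a
  concept-side inverse index for reverse queries.
* **Rule expressions.** Typed expression trees over numbers, constants and
  study elements (`(> item:SYSTOLIC_BLOOD_PRESURE 121)`), with arity/type
  checking, canonical s-expression serialization and strict evaluation.

## Worked example

The built-in fixture reproduces a small cardiology metadata specification:

```r
library(studyframes)
m <- build_example_project()
cat(render_crf_preview(m, instances_of(m, "Page")[1]))
```

```
# B1

## Socio-demographic data

- **DYSPNEA_AT_REST**: ______ [YES | NO]
- **SYSTOLIC_BLOOD_PRESURE**: ______ (mmHg)
```

The dyspnea item alone is not a symptom of congestive heart failure — only
the combination *item answered AND answer = YES* is, so that combination is
what carries the annotation. Likewise the blood-pressure item is annotated
with *Elevated systolic blood pressure* only together with the range
`[121;]`:

```r
dys_ann <- annotations_of_concept(m, "MP:0001635")[[1]]   # heart failure
dys <- dys_ann$conditions[[1]]$element
evaluate_annotation(dys_ann, setNames(list("YES"), dys))  # TRUE
evaluate_annotation(dys_ann, setNames(list("NO"),  dys))  # FALSE

sbp_ann <- annotations_of_concept(m, "MP:0004421")[[1]]   # elevated SBP
sbp <- sbp_ann$conditions[[1]]$element
evaluate_annotation(sbp_ann, setNames(list(121), sbp))    # TRUE  (inclusive)
evaluate_annotation(sbp_ann, setNames(list(120), sbp))    # FALSE
```

Rule expressions stored on items evaluate against data bindings:

```r
rule <- slot_value1(m, sbp, "rules")                # "(> item:SYSTOLIC_BLOOD_PRESURE 121)"
node <- parse_expression(rule, model = m)
evaluate_expression(node, list(SYSTOLIC_BLOOD_PRESURE = 130))   # TRUE
```

And the structure validates against the declared hierarchy rules:

```r
check_hierarchy_rule(m, list(upper = "Page", lower = "Module"))  # TRUE
validate_structure(m, "any_of")                                  # list() — valid
```

Round-tripping through the shipped ODM mapping preserves the project up to
instance-id relabelling:

```r
p   <- generate_random_project(12, seed = 7)
doc <- generate_odm_document(p)            # ODM-style XML
m2  <- example_domain_model()
import_xml(m2, odm_mapping(), doc)
projects_isomorphic(p, m2)                 # TRUE
```

## Command line

```sh
exec/ose init-example project.json
exec/ose validate --rules strict project.json     # exit 1, one line per bad edge
exec/ose eval --expr "(> item:SBP 121)" --bind SBP=130
exec/ose export --mapping inst/extdata/odm.mapping.json --out study.xml project.json
```

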