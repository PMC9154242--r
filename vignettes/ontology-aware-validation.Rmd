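---
title: "Ontology-aware validation of JSON metadata: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-aware validation of JSON metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontovalid)
```

## The validation model

A metadata document is valid when it satisfies two layers of constraints.
The structural layer is ordinary draft-07 JSON Schema: types, required
members, array shapes, enumerations, combinators, `$ref` composition. The
semantic layer interprets selected string values as ontology term
identifiers (CURIEs, `PREFIX:LOCALID`) or taxon references and checks them
against loaded knowledge: existence, obsolescence, subsumption, and
taxonomic resolvability.

Both layers run in one pass. A schema compiles once — custom-keyword
parameter blocks are checked against their metaschemas, every `$ref` must
resolve, the dialect must be draft-07 — and the compiled validator collects
*all* failures of a document, never stopping at the first: submission
brokering needs the complete defect list, not the first defect. Errors are
structured (`keyword`, `instancePath` as a JSON Pointer, `message`, `params`)
and ordered deterministically: instance document order first, then schema
path. `valid` is true exactly when the error list is empty.

### Subsumption

Ontologies are multi-relation directed acyclic graphs. For a term $t$ and a
relation set $R$, the ancestor set is the transitive closure over edges
whose relation lies in $R$; with `direct = TRUE` it is the single-hop parent
set instead. The queried term is never its own ancestor — reflexivity is a
separate, explicit toggle (`include_self`). `rdfs:subClassOf` and `is_a` are
one internal relation; when a keyword omits `relations`, subclass-only is
the default, because subclass constraint is the semantics the keywords
exist to express. `part_of` and any relation declared in a loaded OBO file
are available by name and unknown relation names are rejected when the
schema compiles, not when a document arrives.

### The four keywords

`graph_restriction` is the expressive one: the value must (a) be a member
of at least one ontology in `ontologies` and (b) descend from at least one
class in `classes` under `relations`, with `direct` and `include_self`
toggles. The semantics is OR across both lists — a conjunction is expressed
by schema composition (`allOf` of two keyword blocks), so the keyword
itself stays a disjunction. `isChildTermOf` is the fixed simple case:
non-reflexive, transitive, subclass-only. `isValidTerm` checks existence,
and `isValidTaxonomy` resolution to exactly one taxon — a name shared by
several taxa is an error listing every candidate taxId, because silently
picking one would corrupt downstream metadata.

Three semantic decisions deserve their rationale:

* **Obsolete terms fail** every keyword, with the replacement id named when
  the ontology records one. The purpose of strict validation is quality
  control; a deprecated identifier in new metadata is a defect even though
  the term technically "exists".
* **Membership is graph presence, not prefix matching.** Ontologies import
  foreign terms routinely (the fixture mirrors this: `MINI:`-prefixed terms
  live inside `minimondo`), so "the id's prefix looks right" proves
  nothing; presence in the loaded graph is the testable criterion.
* **Malformed values are validation errors, never exceptions.** A validator
  must report on bad data, not crash on it. A custom keyword reached by a
  non-string instance (or a non-CURIE string) yields a
  malformed-identifier error; silently ignoring the keyword would hide
  schema bugs.

## The backend contract

Keyword checks call four operations — `term_exists`, `find_term`,
`is_descendant`, `taxon_exists` — behind an S3 contract with two
implementations. The default is local: OBO 1.2 flat files parsed into
graphs (cycles are a load-time error, since closure semantics on a cyclic
"hierarchy" is undefined), taxonomy from pipe-delimited nodes/names dump
text with case-insensitive, whitespace-collapsed name keys (real dumps mix
both freely). A remote OLS-style HTTP client implements the same generics
and is interchangeable, but every test runs against the local backend, so
the package is fully functional and testable offline.

Backend answers are pure functions of the query and the loaded content.
Query caching (`local_backend(cache = TRUE)`) memoizes ancestor sets and
existence verdicts; transparency — cached and uncached backends give
identical answers — is asserted by tests, and caching never changes report
bytes.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `relations` | `graph_restriction` | subclass only | the constraint the keywords exist for |
| `direct` | `graph_restriction`, queries | `FALSE` | transitive closure is the usual reading of "is a" |
| `include_self` | `graph_restriction`, queries | `FALSE` | "subclass of X" excludes X itself unless asked |
| `ontologies` | keywords | required | scoping membership is the point of the check |
| `cache` | `local_backend()` | `FALSE` | opt-in; transparent by invariant |
| `timeout` | `remote_backend()` | 10 s | conventional HTTP client default |

## The synthetic-data generators

`generate_dag_ontology(n_terms, max_parents, part_of_fraction,
obsolete_fraction, seed)` emits random ontology DAGs whose edges always
point from a higher-index term to a lower-index one — acyclic by
construction, so the generator cannot produce input the loader would
reject, and the ground-truth closure is computable by an independent
oracle (boolean adjacency-matrix multiplication to a fixpoint). Closure
testing uses 30-term graphs with up to 3 parents per term and a quarter of
edges `part_of`: small enough that exhaustive all-pairs checking over
hundreds of seeds stays cheap, large and multi-relational enough to contain
diamonds, deep chains and relation-restricted paths. Round-trip testing
uses 40–50-term graphs with 10% obsolete terms so the serializer's
obsolescence and replacement lines are exercised.

`disease_example_fixture()` realizes the canonical disease constraint. The
two anchor classes keep their real spellings (`PATO:0000461`,
`MONDO:0000001`) so the `graph_restriction` block reads exactly as it would
in production; all descendants carry the fixture prefix `MINI:` so the
fixture asserts nothing about the real PATO or MONDO.
`miappe_like_fixture()` plays the same role for a plant-phenotyping
checklist: required fields, `isValidTaxonomy` on `organism`,
`graph_restriction` on a trait term, a `$ref` into a shared definitions
schema, and sample documents whose verdicts are fixed at construction.

What these fixtures do *not* emulate: the scale of real ontologies (MONDO
has tens of thousands of classes), equivalence axioms and property chains
(reasoning here is stored-edge closure only), OWL/RDF serializations, and
the messiness of real dump files. Green tests therefore demonstrate the
semantics of the keywords and the engine, not performance or robustness at
archive scale.

## The structural core and its conformance corpus

No conformant draft-07 validator core was available as an R dependency, so
the structural layer is implemented in this package, directly from the
draft-07 specification: type/enum/const, numeric and string assertions,
object and array applicators, `dependencies`, `propertyNames`,
combinators, `if`/`then`/`else`, boolean schemas, and `$ref` against the
current document and a local schema registry. Its verdicts are pinned by a
frozen corpus of 131 structural cases
(`inst/extdata/draft7_structural_suite_synthetic.json`) covering those
keyword families; the corpus is synthetic — constructed for this package,
with every expected verdict computed by an independent, widely used
draft-07 implementation (Python `jsonschema` 4.26) and frozen into the
file. Conservativity is tested separately: attaching the custom keyword
registry changes nothing on schemas that use no custom keyword.

Numerical and parsing choices: JSON numbers compare by value (`1.0` is an
integer and equals `1`; booleans never equal numbers); `multipleOf` uses a
relative tolerance of 1e-9 against the nearest integer quotient to absorb
binary floating-point error in fractional divisors; `pattern` and
`patternProperties` use Perl-compatible regular expressions, a close match
to the ECMA dialect over the constructs checklists actually use; string
length counts characters, not bytes. Dialects other than draft-07 are
rejected at compile time with a clear error rather than half-supported.

## Run modes and the wire contract

The CLI (`inst/cli/validator.R`) and the HTTP service are thin shells over
`compile_schema()`/`validate_document()`; one serializer produces every
report, so the three interfaces are byte-identical by construction and by
test. The HTTP request carries exactly one of `schema` (inline) or
`schema_id` (registry lookup — unknown ids are 404), and exactly one of
`data` (a single document) or `documents` (a non-empty batch validated
index-for-index, one schema per request). The split into two member names
resolves a genuine ambiguity: a single document may itself be a JSON array,
so "one field holding either a document or a list" cannot be decoded
reliably. Validity travels in the payload, never the HTTP status: a 200
with `"valid": false` is a successful validation of an invalid document.
Ontology and taxonomy content loads once at startup from a YAML config;
per-request loading would make latency depend on content size and tests on
filesystem state.

## Known limitations

* Reasoning is transitive closure over stored edges — no equivalence
  axioms, no property chains, no OWL semantics.
* `$ref` resolution covers local JSON Pointers and registered `$id`s
  (plus fragments); nested `$id` base-URI rescoping inside a document is
  not implemented, and remote HTTP resolution is deliberately absent.
* The regex dialect is PCRE, not ECMA-262; exotic patterns may differ.
* The remote backend is a functional stub contract: untested without
  network access, and it does not serve taxonomy queries.
* Error message *strings* are this package's own; only the structure
  (keyword, instance path, params) is contractual.
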