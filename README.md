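# ontovalid

Ontology-aware JSON Schema validation for life-science metadata, in R.

JSON Schema checks the *structure* of a metadata document — which fields
exist, their types, their shapes — but says nothing about whether
`"disease_ontology_id": "MONDO:0005148"` actually names an ontology term, let
alone whether that term sits below the right class in the right ontology.
Archives and brokers (BioSamples-style submission systems, MIAPPE-compliant
plant-phenotyping pipelines) need both kinds of check before accepting data.

`ontovalid` extends a draft-07 JSON Schema validator with four custom
keywords for semantic validation:

| keyword | constraint on the instance value |
|---|---|
| `isValidTerm` | the CURIE names an existing, non-obsolete ontology term |
| `isChildTermOf` | the term is a strict transitive subclass of a parent term |
| `isValidTaxonomy` | the value resolves to exactly one taxon (by taxId or name) |
| `graph_restriction` | the term belongs to one of the listed ontologies **and** descends from one of the listed classes via the listed relations |

The semantic engine is a local graph backend: ontologies load from OBO 1.2
flat files into multi-relation DAGs, taxonomies from NCBI-style
`nodes`/`names` dumps. For a term *t* and relation set *R*, the ancestor set
is the transitive closure

anc_R(t) = { u : t →_R … →_R u },

and `graph_restriction` with ontologies *O*, classes *C* passes *t* iff
*t* is a member of some ontology in *O* and some *c* ∈ *C* lies in anc_R(t)
(OR-semantics across both lists; `include_self` additionally admits *t* = *c*,
`direct` restricts the closure to single-hop parents). Everything runs
offline; a remote OLS-style backend implements the same query contract and
can be swapped in where network access exists.

Validation runs three ways over the same engine: as library calls, as a
one-shot CLI, and as an HTTP service with single and batch endpoints — all
three emit byte-identical report JSON.

## Worked example

The package ships a miniature realization of the classic disease
constraint: a schema whose `disease_ontology_id` may only hold subclasses of
`PATO:0000461` or `MONDO:0000001`:

```r
library(ontovalid)

fx <- disease_example_fixture()
v  <- compile_schema(fx$schema, backend = fx$backend)

validate_document(v, fx$valid_document)    # MINI:0000010 is_a MONDO:0000001
#> <validation_report: valid>

validate_document(v, fx$invalid_document)  # MINI:0000099, outside both trees
#> <validation_report: INVALID, 1 error(s)>
#>   [graph_restriction] at '/disease_ontology_id': term 'MINI:0000099' does not
#>   descend from any of the classes [PATO:0000461, MONDO:0000001] via relations [is_a]
```

The valid document passes because `MINI:0000010` is a loaded member of
ontology `minimondo` and `MONDO:0000001` is in its subclass closure; the
invalid one fails condition (b) of the keyword — it exists in the ontology
but descends from neither class — and the error says exactly that, with a
JSON Pointer to the offending value. Taxonomy checks report the same way:

```r
mf <- miappe_like_fixture()
mv <- compile_schema(mf$schema, registry = mf$registry, backend = mf$backend)
validate_document(mv, mf$documents[[7]]$document)
#> <validation_report: INVALID, 1 error(s)>
#>   [isValidTaxonomy] at '/organism': taxon 'cress' is ambiguous; candidate taxIds: 3701, 3702
```

From a shell, the same validation is

```sh
Rscript $(Rscript -e 'cat(system.file("cli","validator.R",package="ontovalid"))') \
  validate --schema disease-sample.json --data sample.json --config config.yaml
```

(exit 0 valid / 1 invalid / 2 usage error), or as a service:
`validator.R serve --port 3020 --config config.yaml`, then
`POST /validate` with `{"schema": ... , "data": ...}` or
`{"schema": ..., "documents": [...]}` for order-preserving batches.

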