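# Deterministic test-content generators: random ontology DAGs with known
# closure, a miniature disease ontology realizing the canonical
# graph_restriction example, a miniature taxonomy dump, and a MIAPPE-like
# checklist schema with sample documents of known verdicts. Everything
# builds in memory from code — no downloads, no bundled ontology releases.

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a random ontology DAG
#'
#' Produces a seeded random DAG for closure testing. Edges always point from
#' a higher-index term to a lower-index term, which guarantees acyclicity by
#' construction; each non-root term draws 1..`max_parents` parents. A
#' fraction of edges carry the `part_of` relation and a fraction of non-root
#' terms are marked obsolete (with a replacement), so all keyword code paths
#' have material to work on. The same spec always yields the same graph.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per term (must be < `n_terms`).
#' @param part_of_fraction Proportion of edges carrying `part_of` instead of
#'   `is_a`.
#' @param obsolete_fraction Proportion of non-root terms flagged obsolete.
#' @param seed Integer seed.
#' @param ontology_id Ontology short name; also the CURIE prefix
#'   (upper-cased).
#' @return An [ontology_graph()].
#' @export
generate_dag_ontology <- function(n_terms, max_parents = 3,
                                  part_of_fraction = 0,
                                  obsolete_fraction = 0, seed = 1,
                                  ontology_id = "toydag") {
  stopifnot(n_terms >= 1)
  if (max_parents >= n_terms && n_terms > 1)
    stop("max_parents (", max_parents, ") must be smaller than n_terms (",
         n_terms, ")", call. = FALSE)
  prefix <- toupper(ontology_id)
  ids <- sprintf("%s:%07d", prefix, seq_len(n_terms))
  with_preserved_rng(seed, {
    terms <- vector("list", n_terms)
    edges <- list()
    for (i in seq_len(n_terms)) {
      obsolete <- i > 1L && stats::runif(1) < obsolete_fraction
      terms[[i]] <- ontology_term(
        ids[[i]], label = paste("term", i), obsolete = obsolete,
        replaced_by = if (obsolete) ids[[sample.int(i - 1L, 1L)]])
      if (i == 1L) next
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents <- sort(sample.int(i - 1L, k))
      for (p in parents) {
        rel <- if (stats::runif(1) < part_of_fraction) "part_of" else SUBCLASS
        edges[[length(edges) + 1L]] <- c(ids[[i]], rel, ids[[p]])
      }
    }
    ontology_graph(ontology_id, terms = terms, edges = edges_frame(edges))
  })
}

#' Miniature disease-constraint fixture
#'
#' Realizes the canonical semantic-validation example: a schema whose
#' `disease_ontology_id` property carries a `graph_restriction` confining
#' values to subclasses of the disease classes `PATO:0000461` or
#' `MONDO:0000001` within the PATO/MONDO ontologies. The two anchor classes
#' keep their real CURIE spellings so the keyword block reads exactly as it
#' would in production; every descendant uses the fixture prefix `MINI:` so
#' no fact about the real ontologies is asserted.
#'
#' @return A list: `ontologies` (mini-MONDO and mini-PATO graphs), `backend`,
#'   `schema`, `valid_document` (subclass term) and `invalid_document`
#'   (in-ontology term outside both hierarchies).
#' @export
disease_example_fixture <- function() {
  minimondo <- ontology_graph("minimondo",
    terms = list(
      ontology_term("MONDO:0000001", "disease"),
      ontology_term("MINI:0000010", "fixture disease subclass"),
      ontology_term("MINI:0000011", "fixture disease sub-subclass"),
      ontology_term("MINI:0000099", "fixture term outside the hierarchy")),
    edges = edges_frame(list(
      c("MINI:0000010", SUBCLASS, "MONDO:0000001"),
      c("MINI:0000011", SUBCLASS, "MINI:0000010"))))
  minipato <- ontology_graph("minipato",
    terms = list(
      ontology_term("PATO:0000461", "normal"),
      ontology_term("MINI:0000020", "fixture quality subclass")),
    edges = edges_frame(list(
      c("MINI:0000020", SUBCLASS, "PATO:0000461"))))
  schema <- read_json_value('{
    "$schema": "http://json-schema.org/draft-07/schema#",
    "$id": "https://example.org/schemas/disease-sample.json",
    "type": "object",
    "required": ["sample_id", "disease_ontology_id"],
    "properties": {
      "sample_id": {"type": "string", "minLength": 1},
      "disease_ontology_id": {
        "type": "string",
        "graph_restriction": {
          "ontologies": ["minimondo", "minipato"],
          "classes": ["PATO:0000461", "MONDO:0000001"],
          "relations": ["rdfs:subClassOf"],
          "direct": false,
          "include_self": false
        }
      }
    }
  }')
  list(
    ontologies = list(minimondo = minimondo, minipato = minipato),
    backend = local_backend(list(minimondo, minipato)),
    schema = schema,
    valid_document = read_json_value(
      '{"sample_id": "S1", "disease_ontology_id": "MINI:0000010"}'),
    invalid_document = read_json_value(
      '{"sample_id": "S2", "disease_ontology_id": "MINI:0000099"}'))
}

#' Miniature taxonomy dump (nodes/names text)
#'
#' A small plant-flavoured taxonomy in NCBI dump dialect: root, kingdom, two
#' genus/species chains, a shared synonym ("cress") attached to two taxa to
#' exercise ambiguity reporting, and the common name "maize".
#'
#' @return List with `nodes_text` and `names_text` strings.
#' @export
mini_taxonomy_dump <- function() {
  nodes <- c(
    "1 | 1 | no rank |",
    "33090 | 1 | kingdom |",
    "4575 | 33090 | genus |",
    "4577 | 4575 | species |",
    "3701 | 33090 | genus |",
    "3702 | 3701 | species |")
  names <- c(
    "1 | root | | scientific name |",
    "33090 | Viridiplantae | | scientific name |",
    "4575 | Zea | | scientific name |",
    "4577 | Zea mays | | scientific name |",
    "4577 | maize | | common name |",
    "3701 | Arabidopsis | | scientific name |",
    "3702 | Arabidopsis thaliana | | scientific name |",
    "3702 | thale cress | | common name |",
    "3701 | cress | | common name |",
    "3702 | cress | | common name |")
  list(nodes_text = paste(nodes, collapse = "\n"),
       names_text = paste(names, collapse = "\n"))
}

#' MIAPPE-like checklist fixture
#'
#' A plant-phenotyping sample checklist in the spirit of MIAPPE: required
#' fields, an `organism` property validated with `isValidTaxonomy`, a
#' `trait_ontology_id` validated with `graph_restriction` against a
#' miniature trait ontology, and a `$ref` into a shared definitions schema.
#' Ships sample documents with verdicts fixed at construction.
#'
#' @return A list: `schema`, `definitions_schema`, `registry` (both schemas
#'   registered), `backend` (trait ontology + mini taxonomy), and
#'   `documents` — a list of records with `name`, `document`, `valid` and,
#'   for invalid ones, `expect_keyword`.
#' @export
miappe_like_fixture <- function() {
  minitrait <- ontology_graph("minitrait",
    terms = list(
      ontology_term("TRAIT:0000001", "plant trait"),
      ontology_term("TRAIT:0000100", "plant height"),
      ontology_term("TRAIT:0000101", "grain yield"),
      ontology_term("TRAIT:0000110", "grain yield per plot"),
      ontology_term("TRAIT:0000900", "retired trait", obsolete = TRUE,
                    replaced_by = "TRAIT:0000100"),
      ontology_term("TRAIT:0000999", "non-trait fixture term")),
    edges = edges_frame(list(
      c("TRAIT:0000100", SUBCLASS, "TRAIT:0000001"),
      c("TRAIT:0000101", SUBCLASS, "TRAIT:0000001"),
      c("TRAIT:0000110", SUBCLASS, "TRAIT:0000101"))))
  tax <- mini_taxonomy_dump()
  backend <- local_backend(list(minitrait),
                           taxonomy = load_taxonomy(tax$nodes_text,
                                                    tax$names_text))
  definitions_schema <- read_json_value('{
    "$schema": "http://json-schema.org/draft-07/schema#",
    "$id": "https://example.org/schemas/miappe-defs.json",
    "definitions": {
      "nonEmptyString": {"type": "string", "minLength": 1}
    }
  }')
  schema <- read_json_value('{
    "$schema": "http://json-schema.org/draft-07/schema#",
    "$id": "https://example.org/schemas/miappe-sample.json",
    "type": "object",
    "required": ["sample_name", "organism", "trait_ontology_id"],
    "properties": {
      "sample_name": {"$ref": "https://example.org/schemas/miappe-defs.json#/definitions/nonEmptyString"},
      "organism": {"type": ["string", "integer"], "isValidTaxonomy": true},
      "trait_ontology_id": {
        "type": "string",
        "graph_restriction": {
          "ontologies": ["minitrait"],
          "classes": ["TRAIT:0000001"],
          "relations": ["rdfs:subClassOf"],
          "direct": false,
          "include_self": false
        }
      },
      "description": {"type": "string"}
    }
  }')
  registry <- schema_registry()
  register_schema(registry, definitions_schema)
  register_schema(registry, schema)
  documents <- list(
    list(name = "pass",
         document = read_json_value('{"sample_name": "plot-17", "organism": "Zea mays", "trait_ontology_id": "TRAIT:0000110"}'),
         valid = TRUE),
    list(name = "pass_taxid",
         document = read_json_value('{"sample_name": "plot-18", "organism": 3702, "trait_ontology_id": "TRAIT:0000100"}'),
         valid = TRUE),
    list(name = "structural_fail_missing_required",
         document = read_json_value('{"sample_name": "plot-19", "trait_ontology_id": "TRAIT:0000100"}'),
         valid = FALSE, expect_keyword = "required"),
    list(name = "ontology_fail_out_of_hierarchy",
         document = read_json_value('{"sample_name": "plot-20", "organism": "Zea mays", "trait_ontology_id": "TRAIT:0000999"}'),
         valid = FALSE, expect_keyword = "graph_restriction"),
    list(name = "ontology_fail_obsolete",
         document = read_json_value('{"sample_name": "plot-21", "organism": "Zea mays", "trait_ontology_id": "TRAIT:0000900"}'),
         valid = FALSE, expect_keyword = "graph_restriction"),
    list(name = "taxonomy_fail_unknown",
         document = read_json_value('{"sample_name": "plot-22", "organism": "No Such Organism", "trait_ontology_id": "TRAIT:0000100"}'),
         valid = FALSE, expect_keyword = "isValidTaxonomy"),
    list(name = "taxonomy_fail_ambiguous",
         document = read_json_value('{"sample_name": "plot-23", "organism": "cress", "trait_ontology_id": "TRAIT:0000100"}'),
         valid = FALSE, expect_keyword = "isValidTaxonomy"))
  list(schema = schema, definitions_schema = definitions_schema,
       registry = registry, backend = backend, documents = documents)
}
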