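corpus_cases <- function() {
  path <- system.file("extdata", "draft7_structural_suite_synthetic.json",
                      package = "ontovalid")
  read_json_value(path = path)$cases
}

test_that("structural verdicts match the frozen draft-07 conformance corpus", {
  cases <- corpus_cases()
  expect_gte(length(cases), 100L)
  for (c in cases) {
    v <- compile_schema(c$schema)
    report <- validate_document(v, c$data)
    expect_identical(report$valid, c$valid,
                     label = paste0(c$group, ": ", c$description))
    expect_identical(report$valid, length(report$errors) == 0L)
  }
})

test_that("attaching the custom registry is conservative on plain schemas", {
  for (c in corpus_cases()[seq(1, 131, by = 7)]) {
    with_custom <- validate_document(compile_schema(c$schema), c$data)
    without <- validate_document(compile_schema(c$schema, keywords = list()),
                                 c$data)
    expect_identical(with_custom, without)
  }
})

test_that("unsupported dialects are rejected with a clear error", {
  expect_error(
    compile_schema('{"$schema": "https://json-schema.org/draft/2020-12/schema"}'),
    "only draft-07")
  expect_silent(
    compile_schema('{"$schema": "http://json-schema.org/draft-07/schema#"}'))
})

test_that("malformed custom-keyword blocks fail compilation at their path", {
  b <- disease_example_fixture()$backend
  missing_classes <- '{
    "properties": {"d": {"graph_restriction": {"ontologies": ["minimondo"]}}}
  }'
  err <- tryCatch(compile_schema(missing_classes, backend = b),
                  error = function(e) conditionMessage(e))
  expect_match(err, "graph_restriction")
  expect_match(err, "#/properties/d/graph_restriction", fixed = TRUE)
  unknown_rel <- '{
    "properties": {"d": {"graph_restriction": {
      "ontologies": ["minimondo"], "classes": ["MONDO:0000001"],
      "relations": ["regulates"]}}}
  }'
  expect_error(compile_schema(unknown_rel, backend = b),
               "unknown relation.*regulates")
})

test_that("custom keywords require a backend at compile time", {
  expect_error(
    compile_schema('{"properties": {"x": {"isValidTaxonomy": true}}}'),
    "backend")
  # plain structural schema compiles without one
  expect_silent(compile_schema('{"type": "object"}'))
})

test_that("unresolvable $refs are compile errors naming the reference", {
  expect_error(compile_schema('{"$ref": "#/definitions/missing"}'),
               "#/definitions/missing")
  expect_error(compile_schema('{"$ref": "https://nowhere.example/s.json"}'),
               "https://nowhere.example/s.json")
})

test_that("schema registry: registration, idempotence, conflicts", {
  reg <- schema_registry()
  shared <- read_json_value('{
    "$id": "https://example.org/defs.json",
    "definitions": {"pos": {"type": "integer", "minimum": 1}}
  }')
  register_schema(reg, shared)
  register_schema(reg, shared)  # identical content: idempotent no-op
  conflicting <- shared
  conflicting$definitions$pos$minimum <- 2
  expect_error(register_schema(reg, conflicting), "different content")
  expect_error(register_schema(reg, read_json_value('{"type": "object"}')),
               "\\$id")

  using <- compile_schema('{
    "properties": {"n": {"$ref": "https://example.org/defs.json#/definitions/pos"}}
  }', registry = reg)
  expect_true(validate_document(using, read_json_value('{"n": 3}'))$valid)
  expect_false(validate_document(using, read_json_value('{"n": 0}'))$valid)
})

test_that("reports collect every failure in deterministic document order", {
  b <- miappe_like_fixture()$backend
  schema <- compile_schema('{
    "type": "object",
    "required": ["sample_name", "organism"],
    "properties": {
      "organism": {"isValidTaxonomy": true},
      "trait": {"type": "string",
                "graph_restriction": {"ontologies": ["minitrait"],
                                       "classes": ["TRAIT:0000001"]}}
    }
  }', backend = b)
  doc <- read_json_value(
    '{"organism": "No Such Organism", "trait": "TRAIT:0000999"}')
  report <- validate_document(schema, doc)
  expect_false(report$valid)
  kws <- vapply(report$errors, function(e) e$keyword, character(1))
  # one structural failure plus one per failing semantic value
  expect_identical(kws, c("required", "isValidTaxonomy", "graph_restriction"))
  paths <- vapply(report$errors, function(e) e$instancePath, character(1))
  expect_identical(paths, c("", "/organism", "/trait"))
  # repeated validation yields a byte-identical report
  expect_identical(report_to_json(validate_document(schema, doc)),
                   report_to_json(report))
})

test_that("custom keywords on non-string instances report, never ignore", {
  b <- disease_example_fixture()$backend
  v <- compile_schema(
    '{"properties": {"d": {"isValidTerm": true}}}', backend = b)
  report <- validate_document(v, read_json_value('{"d": 42}'))
  expect_false(report$valid)
  expect_identical(report$errors[[1]]$keyword, "isValidTerm")
  expect_match(report$errors[[1]]$message, "malformed identifier")
})

test_that("error records carry valid JSON pointers and echoed params", {
  fx <- disease_example_fixture()
  v <- compile_schema(fx$schema, backend = fx$backend)
  report <- validate_document(v, fx$invalid_document)
  err <- report$errors[[1]]
  expect_identical(err$instancePath, "/disease_ontology_id")
  expect_identical(unlist(err$params$classes),
                   c("PATO:0000461", "MONDO:0000001"))
  df <- as.data.frame(report)
  expect_identical(nrow(df), 1L)
  expect_identical(df$keyword, "graph_restriction")
})
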