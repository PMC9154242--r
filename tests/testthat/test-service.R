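fixture_state <- function() {
  fx <- disease_example_fixture()
  reg <- schema_registry()
  register_schema(reg, fx$schema)
  list(fx = fx, registry = reg)
}

test_that("single requests return the report with HTTP 200 either way", {
  st <- fixture_state()
  req <- jsonlite::toJSON(list(schema = st$fx$schema,
                               data = st$fx$valid_document),
                          auto_unbox = TRUE)
  res <- handle_validation_request(req, st$fx$backend, st$registry)
  expect_identical(res$status, 200L)
  expect_identical(res$body, '{"valid":true,"errors":[]}')
  req2 <- jsonlite::toJSON(list(schema = st$fx$schema,
                                data = st$fx$invalid_document),
                           auto_unbox = TRUE)
  res2 <- handle_validation_request(req2, st$fx$backend, st$registry)
  expect_identical(res2$status, 200L)  # validity is payload, not status
  expect_false(read_json_value(res2$body)$valid)
})

test_that("schema_id requests resolve against the registry, 404 otherwise", {
  st <- fixture_state()
  req <- jsonlite::toJSON(
    list(schema_id = "https://example.org/schemas/disease-sample.json",
         data = st$fx$valid_document), auto_unbox = TRUE)
  res <- handle_validation_request(req, st$fx$backend, st$registry)
  expect_identical(res$status, 200L)
  miss <- handle_validation_request(
    '{"schema_id": "https://example.org/nope.json", "data": {}}',
    st$fx$backend, st$registry)
  expect_identical(miss$status, 404L)
})

test_that("malformed requests get structured 400 responses", {
  st <- fixture_state()
  b <- st$fx$backend
  cases <- c(
    "not json at all",
    "[1, 2, 3]",
    '{"data": {}}',
    sprintf('{"schema": {}, "schema_id": "x", "data": {}}'),
    '{"schema": {}}',
    '{"schema": {}, "data": {}, "documents": []}',
    '{"schema": {}, "documents": []}')
  for (body in cases) {
    res <- handle_validation_request(body, b, st$registry)
    expect_identical(res$status, 400L, label = body)
    expect_match(res$body, '"error"')
  }
  compile_fail <- '{"schema": {"$schema": "bogus"}, "data": {}}'
  expect_identical(handle_validation_request(compile_fail, b, st$registry)$status,
                   400L)
})

test_that("a batch of three aligns index-for-index with its inputs", {
  st <- fixture_state()
  req <- jsonlite::toJSON(
    list(schema = st$fx$schema,
         documents = list(st$fx$valid_document, st$fx$invalid_document,
                          st$fx$valid_document)),
    auto_unbox = TRUE)
  res <- handle_validation_request(req, st$fx$backend, st$registry)
  expect_identical(res$status, 200L)
  reports <- read_json_value(res$body)
  expect_length(reports, 3L)
  expect_identical(vapply(reports, function(r) r$valid, logical(1)),
                   c(TRUE, FALSE, TRUE))
})

test_that("a batch of n equals n single calls, in order", {
  mf <- miappe_like_fixture()
  docs <- lapply(mf$documents, function(d) d$document)
  batch <- handle_validation_request(
    jsonlite::toJSON(list(schema = mf$schema, documents = docs),
                     auto_unbox = TRUE),
    mf$backend, mf$registry)
  batch_reports <- read_json_value(batch$body)
  singles <- lapply(docs, function(doc)
    read_json_value(handle_validation_request(
      jsonlite::toJSON(list(schema = mf$schema, data = doc),
                       auto_unbox = TRUE),
      mf$backend, mf$registry)$body))
  expect_identical(batch_reports, singles)
})

test_that("the HTTP server answers health checks and validates over sockets", {
  st <- fixture_state()
  base <- start_fixture_server(st$fx$backend, st$registry)
  health <- http_request(paste0(base, "/health"))
  expect_identical(health$status, 200L)
  expect_identical(health$body, '{"status":"ok"}')
  res <- http_request(paste0(base, "/validate"),
                      body = jsonlite::toJSON(list(schema = st$fx$schema,
                                                   data = st$fx$valid_document),
                                              auto_unbox = TRUE))
  expect_identical(res$status, 200L)
  expect_identical(res$body, '{"valid":true,"errors":[]}')
  notfound <- http_request(paste0(base, "/nope"))
  expect_identical(notfound$status, 404L)
})

test_that("the CLI validates with exit status 0/1/2 and prints the report", {
  dir <- withr::local_tempdir()
  man <- write_interface_fixture(dir)
  valid <- run_cli(c("validate", "--schema", "disease-sample.json",
                     "--data", "doc_disease_valid.json",
                     "--config", "config.yaml"), dir = dir)
  expect_identical(valid$status, 0L)
  expect_identical(valid$stdout, '{"valid":true,"errors":[]}')
  invalid <- run_cli(c("validate", "--schema", "disease-sample.json",
                       "--data", "doc_disease_invalid.json",
                       "--config", "config.yaml"), dir = dir)
  expect_identical(invalid$status, 1L)
  expect_false(read_json_value(invalid$stdout)$valid)

  broken <- file.path(dir, "broken.json")
  writeLines("{not json", broken)
  parse_fail <- run_cli(c("validate", "--schema", "disease-sample.json",
                          "--data", "broken.json",
                          "--config", "config.yaml"), dir = dir)
  expect_identical(parse_fail$status, 2L)
  missing <- run_cli(c("validate", "--schema", "disease-sample.json",
                       "--data", "no-such-file.json"), dir = dir)
  expect_identical(missing$status, 2L)
  usage <- run_cli("validate", dir = dir)
  expect_identical(usage$status, 2L)
})
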