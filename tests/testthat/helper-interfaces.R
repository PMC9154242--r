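# Helpers shared by the service tests and the interface-coherence check:
# an in-process HTTP client loop (httpuv service + curl multi in the same R
# process) and an on-disk fixture tree (OBO files, taxonomy dumps, schemas,
# documents, YAML config) for the CLI.

http_request <- function(url, body = NULL, timeout = 20) {
  h <- curl::new_handle(url = url)
  if (!is.null(body)) {
    curl::handle_setopt(h, post = TRUE, postfields = body)
    curl::handle_setheaders(h, "Content-Type" = "application/json")
  }
  state <- new.env(parent = emptyenv())
  pool <- curl::new_pool()
  curl::multi_add(h, done = function(r) state$res <- r,
                  fail = function(e) state$err <- e, pool = pool)
  deadline <- Sys.time() + timeout
  while (is.null(state$res) && is.null(state$err) && Sys.time() < deadline) {
    httpuv::service(25)
    curl::multi_run(timeout = 0.025, pool = pool)
  }
  if (!is.null(state$err)) stop(state$err)
  if (is.null(state$res)) stop("no HTTP response within ", timeout, "s")
  list(status = state$res$status_code,
       body = rawToChar(state$res$content))
}

start_fixture_server <- function(backend, registry, env = parent.frame()) {
  port <- httpuv::randomPort()
  server <- httpuv::startServer("127.0.0.1", port,
                                validator_app(backend, registry))
  withr::defer(server$stop(), envir = env)
  paste0("http://127.0.0.1:", port)
}

json_file <- function(value, path) {
  writeLines(as.character(jsonlite::toJSON(value, auto_unbox = TRUE,
                                           null = "null", digits = NA)),
             path)
  path
}

# Writes every fixture to dir and returns a manifest: config path plus one
# record per (schema file, document file, parsed schema/document, verdict).
write_interface_fixture <- function(dir) {
  fx <- disease_example_fixture()
  mf <- miappe_like_fixture()
  write_obo(fx$ontologies$minimondo, file.path(dir, "minimondo.obo"))
  write_obo(fx$ontologies$minipato, file.path(dir, "minipato.obo"))
  write_obo(mf$backend$ontologies$minitrait, file.path(dir, "minitrait.obo"))
  tax <- mini_taxonomy_dump()
  writeLines(tax$nodes_text, file.path(dir, "nodes.dmp"))
  writeLines(tax$names_text, file.path(dir, "names.dmp"))
  json_file(mf$definitions_schema, file.path(dir, "miappe-defs.json"))
  json_file(mf$schema, file.path(dir, "miappe-sample.json"))
  json_file(fx$schema, file.path(dir, "disease-sample.json"))
  config <- file.path(dir, "config.yaml")
  writeLines(c(
    "ontologies:",
    "  - id: minimondo",
    "    file: minimondo.obo",
    "  - id: minipato",
    "    file: minipato.obo",
    "  - id: minitrait",
    "    file: minitrait.obo",
    "taxonomy:",
    "  nodes: nodes.dmp",
    "  names: names.dmp",
    "schemas:",
    "  - miappe-defs.json"), config)

  cases <- list(
    list(schema_file = "disease-sample.json", schema = fx$schema,
         name = "disease_valid", document = fx$valid_document, valid = TRUE),
    list(schema_file = "disease-sample.json", schema = fx$schema,
         name = "disease_invalid", document = fx$invalid_document,
         valid = FALSE))
  for (d in mf$documents)
    cases[[length(cases) + 1L]] <- list(
      schema_file = "miappe-sample.json", schema = mf$schema,
      name = paste0("miappe_", d$name), document = d$document,
      valid = d$valid)
  for (i in seq_along(cases)) {
    f <- file.path(dir, paste0("doc_", cases[[i]]$name, ".json"))
    json_file(cases[[i]]$document, f)
    cases[[i]]$document_file <- f
  }

  backend <- local_backend(
    list(fx$ontologies$minimondo, fx$ontologies$minipato,
         mf$backend$ontologies$minitrait),
    taxonomy = load_taxonomy(tax$nodes_text, tax$names_text))
  registry <- schema_registry()
  register_schema(registry, mf$definitions_schema)
  register_schema(registry, mf$schema)
  register_schema(registry, fx$schema)

  list(dir = dir, config = config, cases = cases, backend = backend,
       registry = registry)
}

cli_script <- function() {
  system.file("cli", "validator.R", package = "ontovalid")
}

run_cli <- function(args, dir = ".") {
  rscript <- file.path(R.home("bin"), "Rscript")
  errfile <- tempfile()
  out <- withr::with_dir(dir, suppressWarnings(
    system2(rscript, c(cli_script(), args), stdout = TRUE, stderr = errfile)))
  list(status = attr(out, "status") %||% 0L, stdout = as.character(out),
       stderr = readLines(errfile, warn = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
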