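# Two run modes around the engine: a one-shot CLI (validate one document,
# exit 0/1/2) and an HTTP service (POST /validate with single and batch
# payloads, GET /health). Ontology and taxonomy content loads once at
# startup from a config file; validity is payload, not HTTP status.

#' Load backend and schema registry from a YAML config
#'
#' Config keys: `ontologies` — list of `{id, file}` OBO entries; `taxonomy`
#' — `{nodes, names}` dump file pair; `schemas` — optional list of JSON
#' schema files to pre-register (each must carry `$id`); `remote` — optional
#' `{base_url, timeout}` switching to the OLS-style remote backend.
#'
#' @param path Path to the YAML file. Relative file entries resolve against
#'   the config file's directory.
#' @return A list with `backend` and `registry`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)

  if (!is.null(cfg$remote)) {
    backend <- remote_backend(cfg$remote$base_url,
                              timeout = cfg$remote$timeout %||% 10)
  } else {
    graphs <- lapply(cfg$ontologies %||% list(), function(o)
      read_obo(resolve(o$file), ontology_id = o$id))
    taxonomy <- NULL
    if (!is.null(cfg$taxonomy)) {
      taxonomy <- load_taxonomy(
        readLines(resolve(cfg$taxonomy$nodes), warn = FALSE),
        readLines(resolve(cfg$taxonomy$names), warn = FALSE))
    }
    backend <- local_backend(graphs, taxonomy = taxonomy)
  }
  registry <- schema_registry()
  for (s in cfg$schemas %||% list())
    register_schema(registry, read_json_value(path = resolve(s)))
  list(backend = backend, registry = registry)
}

#' One-shot command-line validation
#'
#' Prints the JSON validation report on standard output. Returns exit status
#' 0 when the document is valid, 1 when invalid, 2 on usage or parse errors
#' (message on standard error). The installed script
#' `system.file("cli", "validator.R", package = "ontovalid")` wraps this for
#' shell use.
#'
#' @param schema_path Path to the JSON Schema file.
#' @param data_path Path to the JSON document file.
#' @param config_path Optional YAML config for ontology/taxonomy content and
#'   pre-registered schemas.
#' @return The exit status, invisibly.
#' @export
cli_validate <- function(schema_path, data_path, config_path = NULL) {
  run <- function() {
    state <- if (!is.null(config_path)) load_config(config_path) else
      list(backend = local_backend(), registry = schema_registry())
    schema <- read_json_value(path = schema_path)
    document <- read_json_value(path = data_path)
    v <- compile_schema(schema, registry = state$registry,
                        backend = state$backend)
    validate_document(v, document)
  }
  report <- tryCatch(run(), error = function(e) e)
  if (inherits(report, "error")) {
    message("error: ", conditionMessage(report))
    return(invisible(2L))
  }
  cat(report_to_json(report), "\n", sep = "")
  invisible(if (report$valid) 0L else 1L)
}

json_error_body <- function(message) {
  as.character(jsonlite::toJSON(list(error = message), auto_unbox = TRUE))
}

#' Handle one validation request body
#'
#' The pure request handler behind `POST /validate`. The request carries
#' exactly one of `schema` (inline) or `schema_id` (registry lookup), and
#' exactly one of `data` (single document) or `documents` (non-empty batch
#' array). Batch responses align index-for-index with their inputs.
#'
#' @param body_text Raw JSON request body.
#' @param backend An `ontology_backend`.
#' @param registry A [schema_registry()].
#' @param keywords Custom keyword registry.
#' @return List with `status` (HTTP status code) and `body` (JSON text).
#' @export
handle_validation_request <- function(body_text, backend,
                                      registry = schema_registry(),
                                      keywords = keyword_registry()) {
  req <- tryCatch(read_json_value(text = body_text), error = function(e) e)
  if (inherits(req, "error") || !json_is_object(req))
    return(list(status = 400L,
                body = json_error_body("request body is not a JSON object")))
  has_schema <- json_has(req, "schema")
  has_id <- json_has(req, "schema_id")
  if (has_schema == has_id)
    return(list(status = 400L, body = json_error_body(
      "exactly one of 'schema' and 'schema_id' must be present")))
  schema <- if (has_schema) {
    req[["schema"]]
  } else {
    if (!json_is_string(req[["schema_id"]]))
      return(list(status = 400L,
                  body = json_error_body("'schema_id' must be a string")))
    s <- registry_get(registry, req[["schema_id"]])
    if (is.null(s))
      return(list(status = 404L, body = json_error_body(
        paste0("no schema registered under id '", req[["schema_id"]], "'"))))
    s
  }
  has_data <- json_has(req, "data")
  has_batch <- json_has(req, "documents")
  if (has_data == has_batch)
    return(list(status = 400L, body = json_error_body(
      "exactly one of 'data' and 'documents' must be present")))
  if (has_batch &&
      (!json_is_array(req[["documents"]]) || length(req[["documents"]]) == 0L))
    return(list(status = 400L, body = json_error_body(
      "'documents' must be a non-empty array")))

  v <- tryCatch(compile_schema(schema, registry = registry,
                               keywords = keywords, backend = backend),
                error = function(e) e)
  if (inherits(v, "error"))
    return(list(status = 400L, body = json_error_body(
      paste0("schema compilation failed: ", conditionMessage(v)))))

  if (has_data) {
    report <- validate_document(v, req[["data"]])
    return(list(status = 200L, body = report_to_json(report)))
  }
  reports <- vapply(req[["documents"]], function(doc)
    report_to_json(validate_document(v, doc)), character(1))
  list(status = 200L,
       body = paste0("[", paste(reports, collapse = ","), "]"))
}

#' Build the HTTP application object
#'
#' Routes: `POST /validate` (single and batch validation) and `GET /health`.
#' The returned object plugs into [httpuv::startServer()].
#'
#' @inheritParams handle_validation_request
#' @return A Rook-style application list.
#' @export
validator_app <- function(backend, registry = schema_registry(),
                          keywords = keyword_registry()) {
  respond <- function(status, body) {
    list(status = status,
         headers = list("Content-Type" = "application/json"),
         body = body)
  }
  list(call = function(req) {
    path <- req$PATH_INFO
    method <- req$REQUEST_METHOD
    if (method == "GET" && path == "/health")
      return(respond(200L, '{"status":"ok"}'))
    if (method == "POST" && path == "/validate") {
      body_text <- rawToChar(req$rook.input$read())
      res <- handle_validation_request(body_text, backend, registry, keywords)
      return(respond(res$status, res$body))
    }
    respond(404L, json_error_body(paste0("no route for ", method, " ", path)))
  })
}

#' Run the validation HTTP service (blocking)
#'
#' @param config_path YAML config loaded at startup (see [load_config()]);
#'   ontology and taxonomy content is never loaded per request.
#' @param port TCP port.
#' @param host Bind address.
#' @return Does not return under normal operation.
#' @export
validator_serve <- function(config_path = NULL, port = 3020,
                            host = "127.0.0.1") {
  state <- if (!is.null(config_path)) load_config(config_path) else
    list(backend = local_backend(), registry = schema_registry())
  app <- validator_app(state$backend, state$registry)
  message("ontovalid service listening on http://", host, ":", port)
  httpuv::runServer(host, port, app)
}
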