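# Draft-07 JSON Schema engine: a structural validator core covering the
# draft-07 applicator and assertion vocabulary, plus the plug-in point for
# the custom semantic keywords. Schemas compile once (metaschema checks on
# custom keyword blocks, $ref resolution) and validate many documents,
# collecting every error — no first-failure short-circuit — in a
# deterministic order: instance document order first, then schema path.

DRAFT7_URIS <- c("http://json-schema.org/draft-07/schema#",
                 "http://json-schema.org/draft-07/schema")

#' Create an empty schema registry
#'
#' A registry resolves `$ref` targets across schema documents by their `$id`.
#' Remote (HTTP) resolution is deliberately absent: every reference must
#' resolve against registered content.
#'
#' @return A `schema_registry` object.
#' @export
schema_registry <- function() {
  structure(list(store = new.env(parent = emptyenv())),
            class = "schema_registry")
}

#' Register a schema document under its `$id`
#'
#' Registering the same `$id` with identical content is an idempotent no-op;
#' different content under an existing `$id` is an error.
#'
#' @param registry A [schema_registry()].
#' @param schema Parsed schema document carrying `$id`.
#' @return The registry, invisibly.
#' @export
register_schema <- function(registry, schema) {
  if (!json_has(schema, "$id") || !json_is_string(schema[["$id"]]))
    stop("schema registration requires a string '$id'", call. = FALSE)
  id <- schema[["$id"]]
  if (exists(id, envir = registry$store, inherits = FALSE)) {
    if (!json_equal(get(id, envir = registry$store), schema))
      stop("schema '$id' already registered with different content: ", id,
           call. = FALSE)
    return(invisible(registry))
  }
  assign(id, schema, envir = registry$store)
  invisible(registry)
}

registry_get <- function(registry, id) {
  if (!is.null(registry) &&
      exists(id, envir = registry$store, inherits = FALSE))
    get(id, envir = registry$store) else NULL
}

# ---- $ref resolution ----------------------------------------------------

json_pointer_get <- function(doc, pointer) {
  if (pointer == "") return(doc)
  if (!startsWith(pointer, "/")) return(structure(list(), class = "ptr_miss"))
  segs <- strsplit(substring(pointer, 2L), "/", fixed = TRUE)[[1]]
  segs <- gsub("~0", "~", gsub("~1", "/", segs, fixed = TRUE), fixed = TRUE)
  cur <- doc
  for (s in segs) {
    if (json_is_object(cur) && s %in% names(cur)) {
      cur <- cur[[s]]
    } else if (json_is_array(cur) && grepl("^[0-9]+$", s) &&
               as.integer(s) + 1L <= length(cur)) {
      cur <- cur[[as.integer(s) + 1L]]
    } else {
      return(structure(list(), class = "ptr_miss"))
    }
  }
  cur
}

# Resolve a $ref against the current root document and the registry.
# Supported forms: "#", "#/json/pointer", "<registered-id>",
# "<registered-id>#/json/pointer". Returns list(schema, root) — the resolved
# subschema plus the root document in whose scope further refs resolve — or
# NULL when unresolvable.
resolve_ref <- function(ref, root, registry) {
  split_at <- regexpr("#", ref, fixed = TRUE)
  if (split_at == 1L) {
    target <- json_pointer_get(root, substring(ref, 2L))
    if (inherits(target, "ptr_miss")) return(NULL)
    return(list(schema = target, root = root))
  }
  uri <- if (split_at > 0L) substr(ref, 1L, split_at - 1L) else ref
  frag <- if (split_at > 0L) substring(ref, split_at + 1L) else ""
  doc <- registry_get(registry, uri)
  if (is.null(doc)) doc <- registry_get(registry, paste0(uri, "#"))
  if (is.null(doc) && json_has(root, "$id")) {
    # relative reference against the root document's base
    base <- sub("[^/]*$", "", root[["$id"]])
    doc <- registry_get(registry, paste0(base, uri))
  }
  if (is.null(doc)) return(NULL)
  target <- json_pointer_get(doc, frag)
  if (inherits(target, "ptr_miss")) return(NULL)
  list(schema = target, root = doc)
}

# ---- Compilation --------------------------------------------------------

is_schema_value <- function(x) {
  json_type(x) %in% c("object", "boolean")
}

# Applicator members whose value is one subschema / a map of subschemas / an
# array of subschemas: drives the compile-time walk.
SINGLE_SUBSCHEMA <- c("additionalProperties", "additionalItems", "contains",
                      "propertyNames", "not", "if", "then", "else")
MAP_SUBSCHEMA <- c("properties", "patternProperties", "definitions")
ARRAY_SUBSCHEMA <- c("allOf", "anyOf", "oneOf")

walk_schema <- function(schema, path, fn) {
  fn(schema, path)
  if (!json_is_object(schema)) return(invisible())
  for (k in intersect(SINGLE_SUBSCHEMA, names(schema)))
    walk_schema(schema[[k]], ptr_join(path, k), fn)
  for (k in intersect(MAP_SUBSCHEMA, names(schema))) {
    sub <- schema[[k]]
    if (json_is_object(sub))
      for (p in names(sub))
        walk_schema(sub[[p]], ptr_join(ptr_join(path, k), p), fn)
  }
  for (k in intersect(ARRAY_SUBSCHEMA, names(schema))) {
    sub <- schema[[k]]
    if (json_is_array(sub))
      for (i in seq_along(sub))
        walk_schema(sub[[i]], ptr_join(ptr_join(path, k),
                                       as.character(i - 1L)), fn)
  }
  if (json_has(schema, "items")) {
    it <- schema[["items"]]
    if (json_is_array(it)) {
      for (i in seq_along(it))
        walk_schema(it[[i]], ptr_join(ptr_join(path, "items"),
                                      as.character(i - 1L)), fn)
    } else {
      walk_schema(it, ptr_join(path, "items"), fn)
    }
  }
  if (json_has(schema, "dependencies") && json_is_object(schema[["dependencies"]])) {
    dep <- schema[["dependencies"]]
    for (p in names(dep))
      if (is_schema_candidate(dep[[p]]))
        walk_schema(dep[[p]], ptr_join(ptr_join(path, "dependencies"), p), fn)
  }
  invisible()
}

is_schema_candidate <- function(x) {
  tryCatch(is_schema_value(x), error = function(e) FALSE)
}

#' Compile a JSON Schema against the standard plus custom vocabulary
#'
#' Checks the dialect (draft-07 only), verifies every `$ref` resolves against
#' the document and the registry, and validates every custom-keyword
#' parameter block against its metaschema — all failures are compile errors
#' carrying the schema path. The result validates documents with the full
#' structural vocabulary plus the registered semantic keywords.
#'
#' @param schema Parsed schema document (or JSON text / a file path via
#'   [read_json_value()]).
#' @param registry Optional [schema_registry()] for cross-document `$ref`.
#' @param keywords Custom keyword registry; [keyword_registry()] by default.
#' @param backend An `ontology_backend`; required when the schema uses any
#'   custom keyword.
#' @return A `compiled_validator`.
#' @export
compile_schema <- function(schema, registry = NULL,
                           keywords = keyword_registry(), backend = NULL) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- read_json_value(text = schema)
  if (!is_schema_value(schema))
    stop("schema must be a JSON object or boolean", call. = FALSE)
  if (json_has(schema, "$schema")) {
    dialect <- schema[["$schema"]]
    if (!json_is_string(dialect) || !dialect %in% DRAFT7_URIS)
      stop("unsupported schema dialect '",
           if (json_is_string(dialect)) dialect else json_type(dialect),
           "': only draft-07 is supported", call. = FALSE)
  }

  uses_custom <- FALSE
  walk_schema(schema, "#", function(sub, path) {
    if (!json_is_object(sub)) return()
    if (json_has(sub, "$ref")) {
      ref <- sub[["$ref"]]
      if (!json_is_string(ref) ||
          is.null(resolve_ref(ref, schema, registry)))
        stop("unresolvable $ref '",
             if (json_is_string(ref)) ref else json_type(ref),
             "' at schema path ", path, call. = FALSE)
    }
    for (kw in intersect(names(keywords), names(sub))) {
      uses_custom <<- TRUE
      meta_errors <- validate_core(keywords[[kw]]$metaschema, sub[[kw]],
                                   ipath = "", spath = "#",
                                   ctx = list(root = keywords[[kw]]$metaschema,
                                              registry = NULL,
                                              keywords = list(),
                                              backend = NULL))
      if (length(meta_errors) > 0L)
        stop("invalid '", kw, "' parameter block at schema path ",
             ptr_join(path, kw), ": ", meta_errors[[1]]$message,
             call. = FALSE)
      if (kw == "graph_restriction" && !is.null(backend) &&
          json_has(sub[[kw]], "relations")) {
        rels <- normalize_relation(unlist(sub[[kw]][["relations"]]))
        unknown <- setdiff(rels, backend_relations(backend))
        if (length(unknown) > 0L)
          stop("unknown relation name(s) at schema path ",
               ptr_join(path, kw), ": ", paste(unknown, collapse = ", "),
               call. = FALSE)
      }
    }
  })
  if (uses_custom && is.null(backend))
    stop("schema uses custom semantic keywords but no backend was supplied",
         call. = FALSE)

  structure(list(schema = schema, registry = registry, keywords = keywords,
                 backend = backend),
            class = "compiled_validator")
}

#' @export
print.compiled_validator <- function(x, ...) {
  cat("<compiled_validator",
      if (json_has(x$schema, "$id")) paste0(" '", x$schema[["$id"]], "'"),
      ": draft-07 + {", paste(names(x$keywords), collapse = ", "), "}>\n",
      sep = "")
  invisible(x)
}

#' Validate a document against a compiled schema
#'
#' @param validator A `compiled_validator` from [compile_schema()].
#' @param document Parsed JSON document (see [read_json_value()]).
#' @return A `validation_report`: `valid` flag plus ordered structured
#'   errors.
#' @export
validate_document <- function(validator, document) {
  stopifnot(inherits(validator, "compiled_validator"))
  if (inherits(document, "json"))
    document <- read_json_value(text = unclass(document))
  ctx <- list(root = validator$schema, registry = validator$registry,
              keywords = validator$keywords, backend = validator$backend)
  errors <- validate_core(validator$schema, document, ipath = "",
                          spath = "#", ctx = ctx)
  errors <- order_errors(errors, document)
  validation_report(errors)
}

order_errors <- function(errors, document) {
  if (length(errors) <= 1L) return(errors)
  ranks <- pointer_order(document)
  ipaths <- vapply(errors, function(e) e$instancePath, character(1))
  spaths <- vapply(errors, function(e) e$schemaPath %||% "", character(1))
  r <- match(ipaths, names(ranks))  # names-based [ cannot index the "" root
  r[is.na(r)] <- length(ranks) + 1L
  errors[order(r, spaths)]
}

# ---- The structural core ------------------------------------------------

core_error <- function(keyword, ipath, spath, message, params = NULL) {
  list(keyword = keyword, instancePath = ipath, message = message,
       params = params %||% structure(list(), names = character(0)),
       schemaPath = spath)
}

validate_core <- function(schema, instance, ipath, spath, ctx, depth = 0L) {
  if (depth > 200L)
    stop("schema recursion depth exceeded (circular $ref chain?)", call. = FALSE)
  if (is.logical(schema) && length(schema) == 1L) {
    if (isTRUE(schema)) return(list())
    return(list(core_error("false schema", ipath, spath,
                           "boolean schema 'false' matches nothing")))
  }
  if (!json_is_object(schema)) return(list())

  # draft-07: $ref replaces its sibling keywords
  if (json_has(schema, "$ref")) {
    res <- resolve_ref(schema[["$ref"]], ctx$root, ctx$registry)
    if (is.null(res))
      stop("unresolvable $ref '", schema[["$ref"]], "' at ", spath,
           call. = FALSE)
    sub_ctx <- ctx
    sub_ctx$root <- res$root
    return(validate_core(res$schema, instance, ipath,
                         ptr_join(spath, "$ref"), sub_ctx, depth + 1L))
  }

  errors <- list()
  add <- function(e) errors[[length(errors) + 1L]] <<- e
  addall <- function(es) for (e in es) add(e)
  passes <- function(sub, sp) {
    length(validate_core(sub, instance, ipath, sp, ctx, depth + 1L)) == 0L
  }
  itype <- json_type(instance)

  if (json_has(schema, "type")) {
    want <- schema[["type"]]
    want <- if (json_is_array(want)) unlist(want) else want
    ok <- itype %in% want || (itype == "integer" && "number" %in% want)
    if (!ok)
      add(core_error("type", ipath, ptr_join(spath, "type"),
                     paste0("expected type [", paste(want, collapse = ", "),
                            "], got ", itype),
                     list(type = as.list(want))))
  }

  if (json_has(schema, "enum")) {
    hit <- any(vapply(schema[["enum"]], function(v) json_equal(instance, v),
                      logical(1)))
    if (!hit)
      add(core_error("enum", ipath, ptr_join(spath, "enum"),
                     "value is not one of the enumerated values"))
  }

  if (json_has(schema, "const")) {
    if (!json_equal(instance, schema[["const"]]))
      add(core_error("const", ipath, ptr_join(spath, "const"),
                     "value does not equal the required constant"))
  }

  if (itype %in% c("integer", "number")) {
    x <- as.numeric(instance)
    if (json_has(schema, "multipleOf")) {
      m <- as.numeric(schema[["multipleOf"]])
      q <- x / m
      if (!isTRUE(abs(q - round(q)) < 1e-9))
        add(core_error("multipleOf", ipath, ptr_join(spath, "multipleOf"),
                       paste0(x, " is not a multiple of ", m)))
    }
    if (json_has(schema, "maximum") && !(x <= as.numeric(schema[["maximum"]])))
      add(core_error("maximum", ipath, ptr_join(spath, "maximum"),
                     paste0(x, " exceeds maximum ", schema[["maximum"]])))
    if (json_has(schema, "exclusiveMaximum") &&
        !(x < as.numeric(schema[["exclusiveMaximum"]])))
      add(core_error("exclusiveMaximum", ipath,
                     ptr_join(spath, "exclusiveMaximum"),
                     paste0(x, " is not below exclusive maximum ",
                            schema[["exclusiveMaximum"]])))
    if (json_has(schema, "minimum") && !(x >= as.numeric(schema[["minimum"]])))
      add(core_error("minimum", ipath, ptr_join(spath, "minimum"),
                     paste0(x, " is below minimum ", schema[["minimum"]])))
    if (json_has(schema, "exclusiveMinimum") &&
        !(x > as.numeric(schema[["exclusiveMinimum"]])))
      add(core_error("exclusiveMinimum", ipath,
                     ptr_join(spath, "exclusiveMinimum"),
                     paste0(x, " is not above exclusive minimum ",
                            schema[["exclusiveMinimum"]])))
  }

  if (itype == "string") {
    n <- nchar(instance, type = "chars")
    if (json_has(schema, "maxLength") && n > schema[["maxLength"]])
      add(core_error("maxLength", ipath, ptr_join(spath, "maxLength"),
                     paste0("string longer than ", schema[["maxLength"]],
                            " characters")))
    if (json_has(schema, "minLength") && n < schema[["minLength"]])
      add(core_error("minLength", ipath, ptr_join(spath, "minLength"),
                     paste0("string shorter than ", schema[["minLength"]],
                            " characters")))
    if (json_has(schema, "pattern") &&
        !grepl(schema[["pattern"]], instance, perl = TRUE))
      add(core_error("pattern", ipath, ptr_join(spath, "pattern"),
                     paste0("string does not match pattern '",
                            schema[["pattern"]], "'")))
  }

  if (itype == "array") {
    n <- length(instance)
    if (json_has(schema, "maxItems") && n > schema[["maxItems"]])
      add(core_error("maxItems", ipath, ptr_join(spath, "maxItems"),
                     paste0("array has more than ", schema[["maxItems"]],
                            " items")))
    if (json_has(schema, "minItems") && n < schema[["minItems"]])
      add(core_error("minItems", ipath, ptr_join(spath, "minItems"),
                     paste0("array has fewer than ", schema[["minItems"]],
                            " items")))
    if (isTRUE(json_get(schema, "uniqueItems")) && n > 1L) {
      dup <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          if (json_equal(instance[[i]], instance[[j]])) { dup <- TRUE; break }
        }
        if (dup) break
      }
      if (dup)
        add(core_error("uniqueItems", ipath, ptr_join(spath, "uniqueItems"),
                       "array items are not unique"))
    }
    if (json_has(schema, "items")) {
      it <- schema[["items"]]
      if (json_is_array(it)) {
        for (i in seq_len(min(n, length(it))))
          addall(validate_core(it[[i]], instance[[i]],
                               ptr_join(ipath, as.character(i - 1L)),
                               ptr_join(ptr_join(spath, "items"),
                                        as.character(i - 1L)),
                               ctx, depth + 1L))
        if (n > length(it) && json_has(schema, "additionalItems")) {
          for (i in seq.int(length(it) + 1L, n))
            addall(validate_core(schema[["additionalItems"]], instance[[i]],
                                 ptr_join(ipath, as.character(i - 1L)),
                                 ptr_join(spath, "additionalItems"),
                                 ctx, depth + 1L))
        }
      } else {
        for (i in seq_len(n))
          addall(validate_core(it, instance[[i]],
                               ptr_join(ipath, as.character(i - 1L)),
                               ptr_join(spath, "items"), ctx, depth + 1L))
      }
    }
    if (json_has(schema, "contains")) {
      sp <- ptr_join(spath, "contains")
      hit <- FALSE
      for (i in seq_len(n)) {
        if (length(validate_core(schema[["contains"]], instance[[i]],
                                 ptr_join(ipath, as.character(i - 1L)),
                                 sp, ctx, depth + 1L)) == 0L) {
          hit <- TRUE; break
        }
      }
      if (!hit)
        add(core_error("contains", ipath, sp,
                       "no array item matches the 'contains' schema"))
    }
  }

  if (itype == "object") {
    keys <- names(instance)
    if (json_has(schema, "maxProperties") &&
        length(keys) > schema[["maxProperties"]])
      add(core_error("maxProperties", ipath, ptr_join(spath, "maxProperties"),
                     paste0("object has more than ", schema[["maxProperties"]],
                            " properties")))
    if (json_has(schema, "minProperties") &&
        length(keys) < schema[["minProperties"]])
      add(core_error("minProperties", ipath, ptr_join(spath, "minProperties"),
                     paste0("object has fewer than ", schema[["minProperties"]],
                            " properties")))
    if (json_has(schema, "required")) {
      for (req in unlist(schema[["required"]])) {
        if (!req %in% keys)
          add(core_error("required", ipath, ptr_join(spath, "required"),
                         paste0("required property '", req, "' is missing"),
                         list(missingProperty = req)))
      }
    }
    props <- json_get(schema, "properties")
    patprops <- json_get(schema, "patternProperties")
    for (k in keys) {
      matched <- FALSE
      if (!is.null(props) && k %in% names(props)) {
        matched <- TRUE
        addall(validate_core(props[[k]], instance[[k]], ptr_join(ipath, k),
                             ptr_join(ptr_join(spath, "properties"), k),
                             ctx, depth + 1L))
      }
      if (!is.null(patprops)) {
        for (pat in names(patprops)) {
          if (grepl(pat, k, perl = TRUE)) {
            matched <- TRUE
            addall(validate_core(patprops[[pat]], instance[[k]],
                                 ptr_join(ipath, k),
                                 ptr_join(ptr_join(spath, "patternProperties"),
                                          pat),
                                 ctx, depth + 1L))
          }
        }
      }
      if (!matched && json_has(schema, "additionalProperties")) {
        ap <- schema[["additionalProperties"]]
        if (isFALSE(ap)) {
          add(core_error("additionalProperties", ipath,
                         ptr_join(spath, "additionalProperties"),
                         paste0("additional property '", k,
                                "' is not allowed"),
                         list(additionalProperty = k)))
        } else {
          addall(validate_core(ap, instance[[k]], ptr_join(ipath, k),
                               ptr_join(spath, "additionalProperties"),
                               ctx, depth + 1L))
        }
      }
    }
    if (json_has(schema, "propertyNames")) {
      for (k in keys)
        if (!passes_on(schema[["propertyNames"]], k,
                       ptr_join(spath, "propertyNames"), ctx, depth))
          add(core_error("propertyNames", ipath,
                         ptr_join(spath, "propertyNames"),
                         paste0("property name '", k,
                                "' violates the name schema")))
    }
    if (json_has(schema, "dependencies") &&
        json_is_object(schema[["dependencies"]])) {
      dep <- schema[["dependencies"]]
      for (p in names(dep)) {
        if (!p %in% keys) next
        d <- dep[[p]]
        if (json_is_array(d) || (is.character(d))) {
          for (req in unlist(d))
            if (!req %in% keys)
              add(core_error("dependencies", ipath,
                             ptr_join(ptr_join(spath, "dependencies"), p),
                             paste0("property '", p, "' requires property '",
                                    req, "'")))
        } else {
          addall(validate_core(d, instance, ipath,
                               ptr_join(ptr_join(spath, "dependencies"), p),
                               ctx, depth + 1L))
        }
      }
    }
  }

  if (json_has(schema, "allOf")) {
    sub <- schema[["allOf"]]
    for (i in seq_along(sub))
      addall(validate_core(sub[[i]], instance, ipath,
                           ptr_join(ptr_join(spath, "allOf"),
                                    as.character(i - 1L)),
                           ctx, depth + 1L))
  }
  if (json_has(schema, "anyOf")) {
    sub <- schema[["anyOf"]]
    sp <- ptr_join(spath, "anyOf")
    ok <- any(vapply(seq_along(sub), function(i)
      passes(sub[[i]], ptr_join(sp, as.character(i - 1L))), logical(1)))
    if (!ok)
      add(core_error("anyOf", ipath, sp,
                     "value matches none of the 'anyOf' schemas"))
  }
  if (json_has(schema, "oneOf")) {
    sub <- schema[["oneOf"]]
    sp <- ptr_join(spath, "oneOf")
    hits <- sum(vapply(seq_along(sub), function(i)
      passes(sub[[i]], ptr_join(sp, as.character(i - 1L))), logical(1)))
    if (hits != 1L)
      add(core_error("oneOf", ipath, sp,
                     paste0("value matches ", hits,
                            " of the 'oneOf' schemas instead of exactly 1")))
  }
  if (json_has(schema, "not")) {
    sp <- ptr_join(spath, "not")
    if (passes(schema[["not"]], sp))
      add(core_error("not", ipath, sp,
                     "value matches the schema it must not match"))
  }
  if (json_has(schema, "if")) {
    cond <- passes(schema[["if"]], ptr_join(spath, "if"))
    if (cond && json_has(schema, "then")) {
      addall(validate_core(schema[["then"]], instance, ipath,
                           ptr_join(spath, "then"), ctx, depth + 1L))
    } else if (!cond && json_has(schema, "else")) {
      addall(validate_core(schema[["else"]], instance, ipath,
                           ptr_join(spath, "else"), ctx, depth + 1L))
    }
  }

  # custom semantic keywords
  for (kw in intersect(names(ctx$keywords), names(schema))) {
    def <- ctx$keywords[[kw]]
    sp <- ptr_join(spath, kw)
    if (!json_type(instance) %in% def$value_types) {
      add(core_error(kw, ipath, sp, paste0(
        "malformed identifier: value of JSON type '", json_type(instance),
        "' cannot be validated by '", kw, "'")))
      next
    }
    kw_errors <- def$check(instance, schema[[kw]], ctx$backend)
    for (e in kw_errors) {
      e$instancePath <- ipath
      e$schemaPath <- sp
      e$params <- schema[[kw]]  # echo the keyword block exactly as written
      add(e)
    }
  }

  errors
}

passes_on <- function(schema, instance, spath, ctx, depth) {
  length(validate_core(schema, instance, "", spath, ctx, depth + 1L)) == 0L
}
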