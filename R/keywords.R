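# The four custom JSON Schema keywords for semantic validation:
#   isValidTerm      — the ontology term exists (and is not obsolete)
#   isChildTermOf    — the term is a strict subclass descendant of a parent
#   isValidTaxonomy  — the value resolves to exactly one taxon
#   graph_restriction — the term belongs to one of the listed ontologies and
#                       descends from one of the listed classes via the
#                       listed relations (OR across classes and ontologies)
# Each check takes (value, params, backend) and returns a list of structured
# errors — at most one per failing value, empty iff the value satisfies the
# keyword's predicate. Malformed values produce errors, never exceptions: a
# validator must report on bad data, not fail.

keyword_error <- function(keyword, message, params = NULL,
                          instance_path = "") {
  stopifnot(nzchar(message))
  list(keyword = keyword, instancePath = instance_path, message = message,
       params = params %||% structure(list(), names = character(0)))
}

malformed_value_error <- function(keyword, value, params = NULL) {
  desc <- if (is.character(value) && length(value) == 1L) {
    paste0("'", value, "' is not a CURIE of the form PREFIX:LOCALID")
  } else {
    paste0("value of JSON type '", tryCatch(json_type(value),
                                            error = function(e) "unknown"),
           "' is not an ontology term identifier")
  }
  keyword_error(keyword, paste0("malformed identifier: ", desc), params)
}

#' Check the `isValidTerm` keyword
#'
#' Passes iff the value is a CURIE of a term present (and not obsolete) in
#' the searched ontologies. Obsolete terms fail with the replacement id named
#' when known: deprecated identifiers defeat the quality-control purpose of
#' strict metadata validation.
#'
#' @param value Instance value at the annotated schema location.
#' @param ontologies Optional character vector of ontology ids to search.
#' @param backend An `ontology_backend`.
#' @return List of keyword errors (empty on success).
#' @export
check_is_valid_term <- function(value, ontologies = NULL, backend) {
  kw <- "isValidTerm"
  params <- list(ontologies = ontologies)
  if (!is_curie(value)) return(list(malformed_value_error(kw, value, params)))
  v <- term_exists(backend, value, ontologies)
  if (v$status == "found") return(list())
  if (v$status == "obsolete") {
    msg <- paste0("term '", value, "' is obsolete")
    if (!is.null(v$replaced_by))
      msg <- paste0(msg, "; replaced by '", v$replaced_by, "'")
    return(list(keyword_error(kw, msg, params)))
  }
  list(keyword_error(kw, paste0("term '", value, "' was not found",
                                if (!is.null(ontologies))
                                  paste0(" in ontologies [",
                                         paste(ontologies, collapse = ", "), "]")),
                     params))
}

#' Check the `isChildTermOf` keyword
#'
#' Passes iff the value exists in one of the listed ontologies and is a
#' strict transitive subclass descendant of the parent term (non-reflexive,
#' subclass edges only — the simple keyword stays simple;
#' [check_graph_restriction()] exposes the toggles).
#'
#' @param value Instance value.
#' @param params List with `parent` (CURIE) and `ontologies` (non-empty
#'   character vector).
#' @param backend An `ontology_backend`.
#' @return List of keyword errors (empty on success).
#' @export
check_is_child_term_of <- function(value, params, backend) {
  kw <- "isChildTermOf"
  if (!is_curie(value)) return(list(malformed_value_error(kw, value, params)))
  ex <- term_exists(backend, value, params$ontologies)
  if (ex$status == "not_found")
    return(list(keyword_error(kw, paste0("term '", value,
                                         "' was not found in ontologies [",
                                         paste(params$ontologies, collapse = ", "),
                                         "]"), params)))
  if (ex$status == "obsolete")
    return(list(keyword_error(kw, paste0("term '", value, "' is obsolete",
                                         if (!is.null(ex$replaced_by))
                                           paste0("; replaced by '",
                                                  ex$replaced_by, "'")),
                              params)))
  ok <- is_descendant(backend, value, params$parent, relations = SUBCLASS,
                      include_self = FALSE, direct = FALSE,
                      ontologies = params$ontologies)
  if (ok) return(list())
  list(keyword_error(kw, paste0("term '", value,
                                "' is not a subclass descendant of '",
                                params$parent, "'"), params))
}

#' Check the `isValidTaxonomy` keyword
#'
#' Passes iff the value resolves to exactly one taxon, by taxId or by name.
#' Ambiguous names fail with all candidate taxIds listed.
#'
#' @param value Instance value (text or integer).
#' @param backend An `ontology_backend` with loaded taxonomy.
#' @return List of keyword errors (empty on success).
#' @export
check_is_valid_taxonomy <- function(value, backend) {
  kw <- "isValidTaxonomy"
  ok_type <- json_type(value) %in% c("string", "integer")
  if (!ok_type || (is.character(value) && !nzchar(trimws(value))))
    return(list(keyword_error(kw,
      "malformed identifier: taxonomy value must be a non-empty name or a taxId")))
  v <- taxon_exists(backend, value)
  if (v$status == "found") return(list())
  if (v$status == "ambiguous")
    return(list(keyword_error(kw, paste0("taxon '", value,
                                         "' is ambiguous; candidate taxIds: ",
                                         paste(v$tax_ids, collapse = ", ")))))
  list(keyword_error(kw, paste0("taxon '", value, "' was not found")))
}

#' Check the `graph_restriction` keyword
#'
#' Passes iff (a) the value exists, non-obsolete, in at least one of the
#' listed ontologies, and (b) for at least one listed class the value is a
#' descendant under the listed relations (with the `direct` and
#' `include_self` toggles). OR-semantics across both classes and ontologies:
#' AND is expressed by schema composition (`allOf`). The single error message
#' states which of (a)/(b) failed.
#'
#' @param value Instance value.
#' @param params List with `ontologies`, `classes`, and optional `relations`
#'   (default subclass only), `direct` (default `FALSE`), `include_self`
#'   (default `FALSE`).
#' @param backend An `ontology_backend`.
#' @return List of keyword errors (empty on success).
#' @export
check_graph_restriction <- function(value, params, backend) {
  kw <- "graph_restriction"
  relations <- normalize_relation(params$relations %||% SUBCLASS)
  direct <- isTRUE(params$direct)
  include_self <- isTRUE(params$include_self)
  if (!is_curie(value)) return(list(malformed_value_error(kw, value, params)))

  ex <- term_exists(backend, value, params$ontologies)
  if (ex$status == "not_found")
    return(list(keyword_error(kw, paste0("term '", value,
      "' is not a member of any of the ontologies [",
      paste(params$ontologies, collapse = ", "), "]"), params)))
  if (ex$status == "obsolete")
    return(list(keyword_error(kw, paste0("term '", value, "' is obsolete",
      if (!is.null(ex$replaced_by)) paste0("; replaced by '", ex$replaced_by, "'")),
      params)))
  for (root in params$classes) {
    if (is_descendant(backend, value, root, relations = relations,
                      include_self = include_self, direct = direct,
                      ontologies = params$ontologies))
      return(list())
  }
  list(keyword_error(kw, paste0("term '", value,
    "' does not descend from any of the classes [",
    paste(unlist(params$classes), collapse = ", "), "] via relations [",
    paste(relations, collapse = ", "), "]",
    if (direct) " (direct parents only)"), params))
}

# Parameter metaschemas, written as draft-07 schemas and enforced by the
# package's own structural core at compile time. Every metaschema rejects an
# empty parameter block.
metaschema_is_valid_term <- function() read_json_value('{
  "oneOf": [
    {"const": true},
    {"type": "object",
     "properties": {"ontologies": {"type": "array", "items": {"type": "string"}, "minItems": 1}},
     "required": ["ontologies"], "additionalProperties": false}
  ]
}')

metaschema_is_child_term_of <- function() read_json_value('{
  "type": "object",
  "properties": {
    "parent": {"type": "string", "pattern": "^[^:\\\\s]+:[^:\\\\s]+$"},
    "ontologies": {"type": "array", "items": {"type": "string"}, "minItems": 1}
  },
  "required": ["parent", "ontologies"],
  "additionalProperties": false
}')

metaschema_is_valid_taxonomy <- function() read_json_value('{
  "const": true
}')

metaschema_graph_restriction <- function() read_json_value('{
  "type": "object",
  "properties": {
    "ontologies": {"type": "array", "items": {"type": "string"}, "minItems": 1},
    "classes": {"type": "array",
                "items": {"type": "string", "pattern": "^[^:\\\\s]+:[^:\\\\s]+$"},
                "minItems": 1},
    "relations": {"type": "array", "items": {"type": "string"}, "minItems": 1},
    "direct": {"type": "boolean"},
    "include_self": {"type": "boolean"}
  },
  "required": ["ontologies", "classes"],
  "additionalProperties": false
}')

#' Registry of the four extended keywords
#'
#' Maps each keyword name to its parameter metaschema (a draft-07 schema
#' enforced at compile time), its check function with signature
#' `(value, params, backend)`, and the JSON types of instance values it
#' accepts (anything else is a malformed-identifier validation error, never a
#' silently ignored annotation).
#'
#' @return Named list of four keyword definitions: `isValidTerm`,
#'   `isChildTermOf`, `isValidTaxonomy`, `graph_restriction`.
#' @export
keyword_registry <- function() {
  list(
    isValidTerm = list(
      metaschema = metaschema_is_valid_term(),
      value_types = "string",
      check = function(value, params, backend) {
        onts <- if (json_is_object(params)) {
          vapply(params$ontologies, identity, character(1))
        } else NULL
        check_is_valid_term(value, onts, backend)
      }),
    isChildTermOf = list(
      metaschema = metaschema_is_child_term_of(),
      value_types = "string",
      check = function(value, params, backend) {
        check_is_child_term_of(value,
          list(parent = params$parent,
               ontologies = vapply(params$ontologies, identity, character(1))),
          backend)
      }),
    isValidTaxonomy = list(
      metaschema = metaschema_is_valid_taxonomy(),
      value_types = c("string", "integer"),
      check = function(value, params, backend) {
        check_is_valid_taxonomy(value, backend)
      }),
    graph_restriction = list(
      metaschema = metaschema_graph_restriction(),
      value_types = "string",
      check = function(value, params, backend) {
        check_graph_restriction(value,
          list(ontologies = vapply(params$ontologies, identity, character(1)),
               classes = vapply(params$classes, identity, character(1)),
               relations = if (json_has(params, "relations"))
                 vapply(params$relations, identity, character(1)) else NULL,
               direct = json_get(params, "direct", FALSE),
               include_self = json_get(params, "include_self", FALSE)),
          backend)
      })
  )
}
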