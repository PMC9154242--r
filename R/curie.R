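# Compact URIs (CURIEs) of the form PREFIX:LOCALID identify ontology terms
# throughout the package, e.g. "MONDO:0000001". The prefix matches
# case-insensitively; the local part is case-sensitive.

#' Is a value a well-formed CURIE?
#'
#' A CURIE has exactly one colon separating a non-empty prefix from a
#' non-empty local identifier.
#'
#' @param x A character scalar (anything else returns `FALSE`).
#' @return `TRUE` or `FALSE`.
#' @export
is_curie <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[^:[:space:]]+:[^:[:space:]]+$", x)
}

#' Split a CURIE into prefix and local id
#'
#' @param x A CURIE string.
#' @return A list with elements `prefix` and `local`.
#' @export
parse_curie <- function(x) {
  if (!is_curie(x)) stop("not a well-formed CURIE: ", deparse(x), call. = FALSE)
  i <- regexpr(":", x, fixed = TRUE)
  list(prefix = substr(x, 1L, i - 1L), local = substr(x, i + 1L, nchar(x)))
}

# Canonical comparison key: prefix upper-cased, local untouched. Assumes a
# well-formed CURIE (callers gate on is_curie()); kept lean because it sits
# on the subsumption-query hot path.
curie_key <- function(x) {
  i <- regexpr(":", x, fixed = TRUE)
  if (i < 2L) stop("not a well-formed CURIE: ", deparse(x), call. = FALSE)
  paste0(toupper(substr(x, 1L, i - 1L)), substring(x, i))
}

curie_same <- function(a, b) identical(curie_key(a), curie_key(b))

#' Default CURIE prefix-to-IRI map (OBO PURL conventions)
#'
#' @return A named character vector mapping prefixes to IRI templates. A
#'   prefix absent from the map expands under the generic OBO PURL pattern.
#' @export
default_prefix_map <- function() {
  c(rdfs = "http://www.w3.org/2000/01/rdf-schema#")
}

#' Expand a CURIE to an IRI
#'
#' Uses a configurable prefix map; prefixes not in the map expand under the
#' OBO PURL pattern `http://purl.obolibrary.org/obo/PREFIX_LOCAL`. Only CURIEs
#' appear in validation logic; expansion exists for interoperability output.
#'
#' @param x A CURIE.
#' @param prefix_map Named character vector of prefix -> IRI base.
#' @return The expanded IRI string.
#' @export
curie_to_iri <- function(x, prefix_map = default_prefix_map()) {
  p <- parse_curie(x)
  key <- names(prefix_map)[toupper(names(prefix_map)) == toupper(p$prefix)]
  if (length(key) >= 1L) return(paste0(prefix_map[[key[1L]]], p$local))
  paste0("http://purl.obolibrary.org/obo/", toupper(p$prefix), "_", p$local)
}
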