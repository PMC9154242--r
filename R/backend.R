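# The ontology backend contract: the four query operations the keyword
# checks call — term_exists, find_term, is_descendant, taxon_exists. The
# default implementation is local (OBO graphs + taxonomy dump loaded from
# files); a remote OLS-style client implements the same generics and is
# interchangeable, but is never used in tests and requires network access.

#' Build a local ontology/taxonomy backend
#'
#' @param ontologies List of [ontology_graph()] objects (named or not; the
#'   graph's own `ontology_id` is authoritative).
#' @param taxonomy Optional `taxonomy_table` from [load_taxonomy()].
#' @param cache Cache query answers? Caching is transparent: answers are pure
#'   functions of the loaded content, so cached and uncached backends agree.
#' @return An `ontology_backend` object.
#' @export
local_backend <- function(ontologies = list(), taxonomy = NULL, cache = FALSE) {
  ids <- vapply(ontologies, function(g) g$ontology_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate ontology ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(ontologies) <- ids
  structure(list(ontologies = ontologies, taxonomy = taxonomy,
                 cache = if (isTRUE(cache)) new.env(parent = emptyenv()) else NULL),
            class = c("local_backend", "ontology_backend"))
}

#' @export
print.local_backend <- function(x, ...) {
  cat("<local_backend: ontologies {",
      paste(names(x$ontologies), collapse = ", "), "}",
      if (!is.null(x$taxonomy)) paste0(", taxonomy of ", nrow(x$taxonomy$nodes), " taxa"),
      ">\n", sep = "")
  invisible(x)
}

#' Known relation vocabulary of a backend
#' @param backend An `ontology_backend`.
#' @return Character vector of relation names declared across loaded graphs.
#' @export
backend_relations <- function(backend) {
  sort(unique(c(SUBCLASS, "part_of",
                unlist(lapply(backend$ontologies, function(g) g$relations)))))
}

cached <- function(backend, key, compute) {
  if (is.null(backend$cache)) return(compute())
  if (!exists(key, envir = backend$cache, inherits = FALSE))
    assign(key, compute(), envir = backend$cache)
  get(key, envir = backend$cache)
}

select_graphs <- function(backend, ontologies = NULL) {
  if (is.null(ontologies)) return(backend$ontologies)
  backend$ontologies[intersect(tolower(ontologies), names(backend$ontologies))]
}

#' Does a term exist in the loaded ontologies?
#'
#' Membership means presence in a loaded graph, not prefix matching:
#' ontologies routinely import foreign terms, so presence is the testable
#' criterion. Obsolete terms report as found-but-obsolete, never plain found.
#'
#' @param backend An `ontology_backend`.
#' @param id Term CURIE.
#' @param ontologies Optional character vector of ontology ids to search;
#'   `NULL` searches every loaded ontology.
#' @return A verdict list: `status` (`"found"`, `"obsolete"`, `"not_found"`),
#'   `ontology` (id of a graph containing the term, or `NA`), `replaced_by`
#'   (replacement CURIE or `NULL`).
#' @export
term_exists <- function(backend, id, ontologies = NULL) {
  UseMethod("term_exists")
}

#' @export
term_exists.local_backend <- function(backend, id, ontologies = NULL) {
  compute <- function() {
    verdict <- list(status = "not_found", ontology = NA_character_,
                    replaced_by = NULL)
    if (!is_curie(id)) return(verdict)
    for (g in select_graphs(backend, ontologies)) {
      if (has_term(g, id)) {
        t <- get_term(g, id)
        return(list(status = if (t$obsolete) "obsolete" else "found",
                    ontology = g$ontology_id, replaced_by = t$replaced_by))
      }
    }
    verdict
  }
  if (is.null(backend$cache)) return(compute())
  key <- paste0("te|", if (is_curie(id)) curie_key(id) else id, "|",
                paste(sort(ontologies), collapse = ","))
  cached(backend, key, compute)
}

#' Retrieve a term record from the backend
#' @inheritParams term_exists
#' @return The [ontology_term()] or `NULL` when absent.
#' @export
find_term <- function(backend, id, ontologies = NULL) {
  UseMethod("find_term")
}

#' @export
find_term.local_backend <- function(backend, id, ontologies = NULL) {
  if (!is_curie(id)) return(NULL)
  for (g in select_graphs(backend, ontologies))
    if (has_term(g, id)) return(get_term(g, id))
  NULL
}

#' Is one term a descendant of another?
#'
#' True iff `root` lies in the ancestor set of `id` under the given relations
#' (single hop when `direct`), or `include_self` is set and the two ids are
#' the same term. Absence of either id yields `FALSE`, never an error: the
#' keyword layer reports the specific reason.
#'
#' @param backend An `ontology_backend`.
#' @param id Candidate descendant CURIE.
#' @param root Candidate ancestor CURIE.
#' @param relations Relation names to traverse (default subclass only).
#' @param include_self Does a term count as its own descendant?
#' @param direct Restrict to single-hop parents?
#' @param ontologies Optional ontology ids to search for `id`.
#' @return `TRUE` or `FALSE`.
#' @export
is_descendant <- function(backend, id, root, relations = SUBCLASS,
                          include_self = FALSE, direct = FALSE,
                          ontologies = NULL) {
  UseMethod("is_descendant")
}

#' @export
is_descendant.local_backend <- function(backend, id, root,
                                        relations = SUBCLASS,
                                        include_self = FALSE, direct = FALSE,
                                        ontologies = NULL) {
  if (!all(grepl("^[^:[:space:]]+:[^:[:space:]]+$", c(id, root))))
    return(FALSE)
  id_key <- curie_key(id)
  root_key <- curie_key(root)
  relations <- unique(normalize_relation(relations))
  for (g in select_graphs(backend, ontologies)) {
    if (is.null(g$terms[[id_key]])) next
    if (isTRUE(include_self) && id_key == root_key) return(TRUE)
    anc <- backend_ancestor_keys(backend, g, id_key, relations, direct)
    if (root_key %in% anc) return(TRUE)
  }
  FALSE
}

# Ancestor sets are the cacheable unit: caching them (rather than verdict
# pairs) keeps the cache small and is still answer-transparent.
backend_ancestor_keys <- function(backend, g, id_key, relations, direct) {
  if (is.null(backend$cache))
    return(ancestor_keys(g, id_key, relations, direct))
  key <- paste0("anc|", g$ontology_id, "|", id_key, "|",
                paste(relations, collapse = ","), "|", direct)
  cached(backend, key, function() ancestor_keys(g, id_key, relations, direct))
}

#' Does a taxon exist?
#'
#' @param backend An `ontology_backend` with loaded taxonomy.
#' @param query TaxId (integer or digit string) or taxon name.
#' @return Verdict from [taxon_lookup()]; `"not_found"` when no taxonomy is
#'   loaded.
#' @export
taxon_exists <- function(backend, query) {
  UseMethod("taxon_exists")
}

#' @export
taxon_exists.local_backend <- function(backend, query) {
  if (is.null(backend$taxonomy))
    return(list(status = "not_found", tax_ids = integer(0)))
  taxon_lookup(backend$taxonomy, query)
}

# ---- Remote OLS-style backend -------------------------------------------
# Interchangeable with the local backend behind the same generics. It is a
# thin HTTP client and is exercised only when network access is available;
# every test in this package runs against the local backend.

#' Build a remote OLS-style backend (optional, network-dependent)
#'
#' @param base_url Base URL of an OLS v3-compatible API.
#' @param timeout Request timeout in seconds.
#' @return An `ontology_backend` of class `remote_backend`.
#' @export
remote_backend <- function(base_url, timeout = 10) {
  structure(list(base_url = sub("/+$", "", base_url), timeout = timeout),
            class = c("remote_backend", "ontology_backend"))
}

remote_get_json <- function(backend, path) {
  h <- curl::new_handle(timeout = backend$timeout)
  res <- curl::curl_fetch_memory(paste0(backend$base_url, path), handle = h)
  if (res$status_code != 200L) return(NULL)
  jsonlite::fromJSON(rawToChar(res$content), simplifyVector = FALSE)
}

#' @export
term_exists.remote_backend <- function(backend, id, ontologies = NULL) {
  if (!is_curie(id))
    return(list(status = "not_found", ontology = NA_character_, replaced_by = NULL))
  iri <- curl::curl_escape(curl::curl_escape(curie_to_iri(id)))
  onts <- if (is.null(ontologies)) "" else tolower(ontologies)[1]
  doc <- remote_get_json(backend, paste0("/api/ontologies/", onts,
                                         "/terms/", iri))
  if (is.null(doc))
    return(list(status = "not_found", ontology = NA_character_, replaced_by = NULL))
  obsolete <- isTRUE(doc$is_obsolete)
  list(status = if (obsolete) "obsolete" else "found",
       ontology = doc$ontology_name %||% NA_character_,
       replaced_by = doc$term_replaced_by)
}

#' @export
find_term.remote_backend <- function(backend, id, ontologies = NULL) {
  v <- term_exists(backend, id, ontologies)
  if (v$status == "not_found") return(NULL)
  ontology_term(id, obsolete = v$status == "obsolete",
                replaced_by = v$replaced_by)
}

#' @export
is_descendant.remote_backend <- function(backend, id, root,
                                         relations = SUBCLASS,
                                         include_self = FALSE, direct = FALSE,
                                         ontologies = NULL) {
  if (!is_curie(id) || !is_curie(root)) return(FALSE)
  if (isTRUE(include_self) && curie_same(id, root))
    return(term_exists(backend, id, ontologies)$status != "not_found")
  iri <- curl::curl_escape(curl::curl_escape(curie_to_iri(id)))
  onts <- if (is.null(ontologies)) "" else tolower(ontologies)[1]
  rel <- if (isTRUE(direct)) "parents" else "ancestors"
  doc <- remote_get_json(backend, paste0("/api/ontologies/", onts, "/terms/",
                                         iri, "/", rel, "?size=500"))
  if (is.null(doc)) return(FALSE)
  anc <- doc$`_embedded`$terms
  root_iri <- curie_to_iri(root)
  any(vapply(anc, function(t) identical(t$iri, root_iri), logical(1)))
}

#' @export
taxon_exists.remote_backend <- function(backend, query) {
  stop("remote backend does not implement taxonomy lookup; use a local taxonomy",
       call. = FALSE)
}
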