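# In-memory multi-relation DAG of ontology terms: the substrate for all
# subsumption queries. Terms are keyed by canonical CURIE; edges are
# (child, relation, parent) triples restricted to a declared relation
# vocabulary. "rdfs:subClassOf" and "is_a" are one internal relation.

SUBCLASS <- "is_a"

#' Normalize a relation name
#'
#' `"rdfs:subClassOf"` and `"is_a"` map to the same internal subclass
#' relation; other names pass through unchanged.
#'
#' @param x Character vector of relation names.
#' @return Normalized character vector.
#' @export
normalize_relation <- function(x) {
  hit <- x == "rdfs:subClassOf" | x == "subClassOf"
  if (any(hit)) x[hit] <- SUBCLASS
  x
}

#' Construct an ontology term record
#'
#' @param id Term CURIE.
#' @param label Human-readable label.
#' @param synonyms Character vector of synonyms.
#' @param obsolete Is the term deprecated?
#' @param replaced_by Optional replacement CURIE (obsolete terms only).
#' @return An `ontology_term` list.
#' @export
ontology_term <- function(id, label = "", synonyms = character(0),
                          obsolete = FALSE, replaced_by = NULL) {
  if (!is_curie(id)) stop("term id is not a CURIE: ", deparse(id), call. = FALSE)
  if (!obsolete && !is.null(replaced_by))
    stop("replaced_by is only meaningful on obsolete terms: ", id, call. = FALSE)
  structure(list(id = id, label = label, synonyms = synonyms,
                 obsolete = isTRUE(obsolete), replaced_by = replaced_by),
            class = "ontology_term")
}

#' Construct an ontology graph
#'
#' Validates the container invariants at construction: every edge endpoint is
#' a known term, no duplicate (child, relation, parent) triples, and the edge
#' set is acyclic (checked per relation-restricted subgraph via the full
#' graph, which subsumes every relation subset).
#'
#' @param ontology_id Lowercase short ontology name (e.g. `"mondo"`).
#' @param terms List of [ontology_term()] records.
#' @param edges Data frame with character columns `child`, `relation`,
#'   `parent` (CURIEs and normalized relation names).
#' @return An `ontology_graph` object.
#' @export
ontology_graph <- function(ontology_id, terms = list(),
                           edges = empty_edges()) {
  stopifnot(is.character(ontology_id), length(ontology_id) == 1L)
  ontology_id <- tolower(ontology_id)
  keys <- vapply(terms, function(t) curie_key(t$id), character(1))
  if (anyDuplicated(keys))
    stop("duplicate term ids in ontology '", ontology_id, "': ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  names(terms) <- keys

  edges$relation <- normalize_relation(edges$relation)
  edges$child_key <- vapply(edges$child, curie_key, character(1), USE.NAMES = FALSE)
  edges$parent_key <- vapply(edges$parent, curie_key, character(1), USE.NAMES = FALSE)
  missing <- setdiff(unique(c(edges$child_key, edges$parent_key)), keys)
  if (length(missing) > 0L)
    stop("edge endpoint(s) not declared as terms in '", ontology_id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  trip <- paste(edges$child_key, edges$relation, edges$parent_key)
  if (anyDuplicated(trip))
    stop("duplicate edge triple(s): ",
         paste(unique(trip[duplicated(trip)]), collapse = "; "), call. = FALSE)

  # per-relation child -> parents adjacency, precomputed once so repeated
  # closure queries stay cheap
  adj <- lapply(split(edges[c("child_key", "parent_key")], edges$relation),
                function(e) split(e$parent_key, e$child_key))
  g <- structure(
    list(ontology_id = ontology_id, terms = terms, edges = edges,
         adj = adj,
         relations = sort(unique(c(SUBCLASS, edges$relation)))),
    class = "ontology_graph")
  cyc <- find_cycle(g)
  if (!is.null(cyc))
    stop("cycle detected in ontology '", ontology_id, "': ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  g
}

empty_edges <- function() {
  data.frame(child = character(0), relation = character(0),
             parent = character(0), stringsAsFactors = FALSE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph '", x$ontology_id, "': ", length(x$terms), " terms, ",
      nrow(x$edges), " edges, relations {",
      paste(x$relations, collapse = ", "), "}>\n", sep = "")
  invisible(x)
}

# Kahn's algorithm on the full edge set; returns NULL if acyclic, otherwise
# the term keys left over after peeling (they all lie on/feed a cycle).
find_cycle <- function(g) {
  keys <- names(g$terms)
  if (length(keys) == 0L || nrow(g$edges) == 0L) return(NULL)
  outdeg <- table(factor(g$edges$child_key, levels = keys))  # edges child->parent
  deg <- as.integer(outdeg)
  names(deg) <- keys
  parents_of <- split(g$edges$parent_key, factor(g$edges$child_key, levels = keys))
  children_of <- split(g$edges$child_key, factor(g$edges$parent_key, levels = keys))
  queue <- keys[deg == 0L]  # terms with no parents (roots) peel first
  seen <- 0L
  while (length(queue) > 0L) {
    k <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children_of[[k]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(keys)) return(NULL)
  keys[deg > 0L]
}

has_term <- function(g, id) {
  is_curie(id) && curie_key(id) %in% names(g$terms)
}

get_term <- function(g, id) {
  g$terms[[curie_key(id)]]
}

#' Ancestor set of a term
#'
#' Traverses child-to-parent edges restricted to the given relations. With
#' `direct = TRUE` only single-hop parents are returned; otherwise the full
#' transitive closure. The queried term itself is never included.
#'
#' @param graph An [ontology_graph()].
#' @param id Term CURIE (must exist in the graph).
#' @param relations Character vector of relation names (non-empty); aliases
#'   are normalized.
#' @param direct Single-hop parents only?
#' @return Character vector of ancestor CURIEs (original spellings), sorted.
#' @export
ancestors <- function(graph, id, relations = SUBCLASS, direct = FALSE) {
  stopifnot(length(relations) >= 1L)
  if (!has_term(graph, id))
    stop("term not found: ", if (is.character(id)) id else deparse(id),
         call. = FALSE)
  out <- ancestor_keys(graph, curie_key(id), relations, direct)
  sort(vapply(out, function(k) graph$terms[[k]]$id, character(1),
              USE.NAMES = FALSE))
}

# BFS over the precomputed adjacency; takes and returns canonical keys.
ancestor_keys <- function(graph, start, relations, direct) {
  adjs <- graph$adj[unique(normalize_relation(relations))]
  parents_of <- function(k) {
    unlist(lapply(adjs, function(a) a[[k]]), use.names = FALSE)
  }
  if (direct) return(unique(parents_of(start)))
  out <- character(0)
  frontier <- start
  visited <- start
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, parents_of), use.names = FALSE))
    nxt <- setdiff(nxt, visited)
    out <- c(out, nxt)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  out
}
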