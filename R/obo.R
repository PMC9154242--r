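# Reader and writer for the OBO 1.2 flat-file subset the local backend needs:
# header `ontology:` tag, [Term] stanzas with id, name, is_a, relationship,
# synonym, is_obsolete and replaced_by lines. Trailing comments (`!`) and
# dbxref braces are stripped the way OBO tools do.

strip_obo_comment <- function(x) sub("\\s*!.*$", "", x)

#' Parse OBO 1.2 text into an ontology graph
#'
#' One [ontology_term()] per `[Term]` stanza, one edge per `is_a` /
#' `relationship` line. The ontology id is taken from the header `ontology:`
#' tag (lowercased). Acyclicity is verified at load time.
#'
#' @param obo_text OBO document as a single string or character vector of
#'   lines.
#' @param ontology_id Override for the ontology id when the header lacks an
#'   `ontology:` tag.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(obo_text, ontology_id = NULL) {
  lines <- if (length(obo_text) == 1L && grepl("\n", obo_text)) {
    strsplit(obo_text, "\n", fixed = TRUE)[[1]]
  } else as.character(obo_text)
  lines <- sub("\r$", "", lines)

  terms <- list()
  edges <- list()
  cur <- NULL
  cur_line <- NA_integer_
  in_term <- FALSE

  flush_term <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id))
      stop("OBO parse error: [Term] stanza starting at line ", cur_line,
           " has no id", call. = FALSE)
    terms[[length(terms) + 1L]] <<- ontology_term(
      id = cur$id, label = cur$name %||% "",
      synonyms = cur$synonyms %||% character(0),
      obsolete = isTRUE(cur$obsolete),
      replaced_by = if (isTRUE(cur$obsolete)) cur$replaced_by else NULL)
    for (e in cur$edges)
      edges[[length(edges) + 1L]] <<- c(cur$id, e[[1]], e[[2]])
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush_term()
      in_term <- identical(line, "[Term]")
      if (in_term) { cur <- list(edges = list()); cur_line <- i }
      next
    }
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0) next
    tag <- substr(line, 1L, m - 1L)
    val <- trimws(substr(line, m + 1L, nchar(line)))
    if (!in_term) {
      if (tag == "ontology" && is.null(ontology_id)) ontology_id <- val
      next
    }
    val <- trimws(strip_obo_comment(val))
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "is_a") {
      cur$edges[[length(cur$edges) + 1L]] <- list(SUBCLASS, val)
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L)
        stop("OBO parse error at line ", i, ": malformed relationship line",
             call. = FALSE)
      cur$edges[[length(cur$edges) + 1L]] <-
        list(normalize_relation(parts[[1]]), parts[[2]])
    } else if (tag == "is_obsolete") {
      cur$obsolete <- tolower(val) == "true"
    } else if (tag == "replaced_by") {
      cur$replaced_by <- val
    } else if (tag == "synonym") {
      sm <- regmatches(val, regexpr('^"[^"]*"', val))
      if (length(sm) == 1L)
        cur$synonyms <- c(cur$synonyms, substr(sm, 2L, nchar(sm) - 1L))
    }
  }
  flush_term()

  if (is.null(ontology_id))
    stop("OBO document has no 'ontology:' header tag and no ontology_id was given",
         call. = FALSE)
  ontology_graph(ontology_id, terms = terms, edges = edges_frame(edges))
}

edges_frame <- function(edges) {
  if (length(edges) == 0L) return(empty_edges())
  m <- do.call(rbind, edges)
  data.frame(child = m[, 1], relation = m[, 2], parent = m[, 3],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an ontology graph to OBO text
#'
#' Inverse of [parse_obo()] on the supported subset: terms emit in id order
#' with their labels, synonyms, obsolescence flags and outgoing edges.
#'
#' @param graph An [ontology_graph()].
#' @return A single OBO-format string.
#' @export
serialize_obo <- function(graph) {
  out <- c("format-version: 1.2", paste0("ontology: ", graph$ontology_id))
  ord <- order(vapply(graph$terms, function(t) t$id, character(1)))
  for (t in graph$terms[ord]) {
    out <- c(out, "", "[Term]", paste0("id: ", t$id))
    if (nzchar(t$label)) out <- c(out, paste0("name: ", t$label))
    for (s in t$synonyms)
      out <- c(out, paste0("synonym: \"", s, "\" EXACT []"))
    e <- graph$edges[graph$edges$child_key == curie_key(t$id), , drop = FALSE]
    if (nrow(e) > 0L) {
      e <- e[order(e$relation, e$parent), , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        if (e$relation[[j]] == SUBCLASS) {
          out <- c(out, paste0("is_a: ", e$parent[[j]]))
        } else {
          out <- c(out, paste0("relationship: ", e$relation[[j]], " ",
                               e$parent[[j]]))
        }
      }
    }
    if (t$obsolete) {
      out <- c(out, "is_obsolete: true")
      if (!is.null(t$replaced_by))
        out <- c(out, paste0("replaced_by: ", t$replaced_by))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read an OBO file
#' @param path File path.
#' @inheritParams parse_obo
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path, ontology_id = NULL) {
  parse_obo(readLines(path, warn = FALSE, encoding = "UTF-8"), ontology_id)
}

#' Write an ontology graph to an OBO file
#' @param graph An [ontology_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  writeLines(serialize_obo(graph), path, sep = "")
  invisible(path)
}
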