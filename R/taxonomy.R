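# NCBI-style taxonomy dump subset: nodes table ("tax_id | parent tax_id |
# rank |") and names table ("tax_id | name | unique name | name class |").
# Lookup is by taxId or by name; name keys are case-insensitive with internal
# whitespace collapsed, since dump files mix both freely.

normalize_taxon_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

split_dump_row <- function(line) {
  # rows end with a trailing "|"; fields are trimmed
  trimws(strsplit(sub("\\|\\s*$", "", line), "|", fixed = TRUE)[[1]])
}

#' Load a taxonomy from nodes/names dump text
#'
#' @param nodes_text Nodes table text (string or lines): `tax_id | parent
#'   tax_id | rank |`.
#' @param names_text Names table text: `tax_id | name | unique name | name
#'   class |`. Rows of class `"scientific name"` populate the scientific
#'   name; every class populates the name index.
#' @return A `taxonomy_table` with `nodes` (data frame: tax_id, parent,
#'   rank, scientific_name) and `name_index` (normalized name -> integer
#'   taxIds).
#' @export
load_taxonomy <- function(nodes_text, names_text) {
  as_lines <- function(x) {
    if (length(x) == 1L && grepl("\n", x)) strsplit(x, "\n", fixed = TRUE)[[1]] else as.character(x)
  }
  nl <- Filter(nzchar, trimws(as_lines(nodes_text)))
  ml <- Filter(nzchar, trimws(as_lines(names_text)))

  rows <- lapply(nl, split_dump_row)
  bad <- which(vapply(rows, length, integer(1)) < 3L)
  if (length(bad) > 0L)
    stop("taxonomy nodes row ", bad[[1]], " has fewer than 3 fields", call. = FALSE)
  tax_id <- vapply(rows, function(r) as.integer(r[[1]]), integer(1))
  parent <- vapply(rows, function(r) as.integer(r[[2]]), integer(1))
  rank <- vapply(rows, function(r) r[[3]], character(1))
  if (anyDuplicated(tax_id))
    stop("duplicate tax_id in nodes table: ",
         paste(unique(tax_id[duplicated(tax_id)]), collapse = ", "),
         call. = FALSE)
  missing_parent <- setdiff(parent, tax_id)
  if (length(missing_parent) > 0L)
    stop("node(s) reference missing parent tax_id: ",
         paste(missing_parent, collapse = ", "), call. = FALSE)

  nodes <- data.frame(tax_id = tax_id, parent = parent, rank = rank,
                      scientific_name = NA_character_,
                      stringsAsFactors = FALSE)
  rownames(nodes) <- as.character(tax_id)

  name_index <- new.env(parent = emptyenv())
  for (line in ml) {
    f <- split_dump_row(line)
    if (length(f) < 4L) next
    id <- as.integer(f[[1]]); nm <- f[[2]]; cls <- f[[4]]
    if (!id %in% tax_id)
      stop("names row references unknown tax_id ", id, call. = FALSE)
    if (cls == "scientific name")
      nodes[as.character(id), "scientific_name"] <- nm
    key <- normalize_taxon_name(nm)
    name_index[[key]] <- sort(unique(c(name_index[[key]], id)))
  }
  if (anyNA(nodes$scientific_name))
    for (id in nodes$tax_id[is.na(nodes$scientific_name)])
      nodes[as.character(id), "scientific_name"] <- paste0("taxid:", id)

  structure(list(nodes = nodes, name_index = name_index),
            class = "taxonomy_table")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("<taxonomy_table: ", nrow(x$nodes), " taxa, ",
      length(ls(x$name_index)), " indexed names>\n", sep = "")
  invisible(x)
}

#' Look a taxon up by id or name
#'
#' Integer queries (or all-digit strings) hit the node table; text queries
#' hit the case-insensitive, whitespace-collapsed name index. The result is a
#' verdict, never an error: absence and ambiguity are reportable outcomes.
#'
#' @param taxonomy A `taxonomy_table`.
#' @param query Positive integer taxId or non-empty name text.
#' @return A list with `status` (`"found"`, `"not_found"` or `"ambiguous"`)
#'   and `tax_ids` (integer vector: one id when found, all candidates when
#'   ambiguous, empty otherwise).
#' @export
taxon_lookup <- function(taxonomy, query) {
  verdict <- function(status, ids = integer(0)) list(status = status, tax_ids = ids)
  if (is.numeric(query) && length(query) == 1L && is.finite(query) &&
      query == trunc(query)) {
    id <- as.integer(query)
    if (as.character(id) %in% rownames(taxonomy$nodes))
      return(verdict("found", id))
    return(verdict("not_found"))
  }
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query)))
    return(verdict("not_found"))
  if (grepl("^[0-9]+$", trimws(query)))
    return(taxon_lookup(taxonomy, as.integer(trimws(query))))
  key <- normalize_taxon_name(query)
  ids <- name_index_get(taxonomy, key)
  if (length(ids) == 0L) return(verdict("not_found"))
  if (length(ids) == 1L) return(verdict("found", ids))
  verdict("ambiguous", ids)
}

name_index_get <- function(taxonomy, key) {
  if (exists(key, envir = taxonomy$name_index, inherits = FALSE))
    get(key, envir = taxonomy$name_index) else integer(0)
}
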