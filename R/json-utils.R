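# JSON values are represented as jsonlite::fromJSON(..., simplifyVector = FALSE)
# output: NULL (null), logical (boolean), integer/double (number), character
# (string), unnamed list (array), named list (object). Empty objects keep a
# zero-length names attribute, which is how they are told apart from [].

#' Read a JSON value from text or file without vector simplification
#'
#' Parses JSON keeping the one-to-one mapping between JSON and R values that
#' the validator relies on: objects are named lists, arrays unnamed lists,
#' scalars length-one vectors, null is `NULL`.
#'
#' @param text JSON text (length-one character).
#' @param path Path to a JSON file (used when `text` is missing).
#' @return The parsed JSON value.
#' @export
read_json_value <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  }
  jsonlite::fromJSON(text, simplifyVector = FALSE)
}

#' JSON type of an R value under the validator's representation
#'
#' @param x A parsed JSON value.
#' @return One of "null", "boolean", "integer", "number", "string", "array",
#'   "object". Whole-valued doubles report as "integer", as draft-07 requires
#'   (`1.0` is an integer).
#' @export
json_type <- function(x) {
  if (is.null(x)) return("null")
  if (is.logical(x) && length(x) == 1L) return("boolean")
  if (is.numeric(x) && length(x) == 1L) {
    if (is.integer(x)) return("integer")
    if (is.finite(x) && x == trunc(x)) return("integer")
    return("number")
  }
  if (is.character(x) && length(x) == 1L) return("string")
  if (is.list(x)) {
    if (!is.null(names(x))) return("object") else return("array")
  }
  stop("value is not in JSON representation (class ", class(x)[1], ")")
}

json_is_object <- function(x) is.list(x) && !is.null(names(x))
json_is_array  <- function(x) is.list(x) && is.null(names(x))
json_is_string <- function(x) is.character(x) && length(x) == 1L

# Key presence must be tested on names(), not by NULL-ness of the element,
# because {"a": null} stores an R NULL under name "a".
json_has <- function(obj, key) json_is_object(obj) && key %in% names(obj)

json_get <- function(obj, key, default = NULL) {
  if (json_has(obj, key)) obj[[key]] else default
}

#' Deep equality of two JSON values
#'
#' Numbers compare by value regardless of integer/double storage; booleans are
#' never equal to numbers; objects compare key-set plus per-key values; arrays
#' compare element-wise in order.
#'
#' @param a,b Parsed JSON values.
#' @return `TRUE` or `FALSE`.
#' @export
json_equal <- function(a, b) {
  ta <- json_type(a); tb <- json_type(b)
  num <- c("integer", "number")
  if (ta %in% num && tb %in% num) return(isTRUE(a == b))
  if (ta != tb) return(FALSE)
  switch(ta,
    null = TRUE,
    boolean = ,
    string = identical(as.vector(a), as.vector(b)),
    array = {
      if (length(a) != length(b)) return(FALSE)
      for (i in seq_along(a)) if (!json_equal(a[[i]], b[[i]])) return(FALSE)
      TRUE
    },
    object = {
      na <- sort(names(a)); nb <- sort(names(b))
      if (!identical(na, nb)) return(FALSE)
      for (k in na) if (!json_equal(a[[k]], b[[k]])) return(FALSE)
      TRUE
    }
  )
}

# JSON Pointer (RFC 6901) segment escaping.
ptr_escape <- function(seg) gsub("/", "~1", gsub("~", "~0", seg))

ptr_join <- function(base, seg) paste0(base, "/", ptr_escape(seg))

# Document-order ranks of every JSON Pointer location in a document. Used to
# sort validation errors deterministically: errors on earlier instance
# locations come first.
pointer_order <- function(document) {
  ranks <- character(0)
  walk <- function(x, ptr) {
    ranks[[length(ranks) + 1L]] <<- ptr
    if (json_is_object(x)) {
      for (k in names(x)) walk(x[[k]], ptr_join(ptr, k))
    } else if (json_is_array(x)) {
      for (i in seq_along(x)) walk(x[[i]], ptr_join(ptr, as.character(i - 1L)))
    }
  }
  walk(document, "")
  stats::setNames(seq_along(ranks), ranks)
}
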