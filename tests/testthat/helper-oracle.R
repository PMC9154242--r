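# Independent reachability oracle: boolean adjacency matrix closed by
# repeated multiplication. Deliberately shares no code with ancestors() /
# is_descendant(), which it cross-checks.

oracle_adjacency <- function(graph, relations = c("is_a", "part_of")) {
  keys <- names(graph$terms)
  n <- length(keys)
  A <- matrix(0, n, n, dimnames = list(keys, keys))
  rel <- normalize_relation(relations)
  e <- graph$edges[graph$edges$relation %in% rel, , drop = FALSE]
  if (nrow(e) > 0L)
    A[cbind(match(e$child_key, keys), match(e$parent_key, keys))] <- 1
  A
}

oracle_closure <- function(A) {
  R <- A
  repeat {
    R2 <- ((R + R %*% A) > 0) * 1
    if (all(R2 == R)) return(R)
    R <- R2
  }
}

# named list: term key -> sorted ancestor keys (transitive or direct)
oracle_ancestor_sets <- function(graph, relations = c("is_a", "part_of"),
                                 direct = FALSE) {
  A <- oracle_adjacency(graph, relations)
  M <- if (direct) A else oracle_closure(A)
  keys <- rownames(M)
  stats::setNames(lapply(seq_along(keys), function(i) sort(keys[M[i, ] > 0])),
                  keys)
}

expect_same_set <- function(got, want) {
  expect_setequal(got, want)
  expect_equal(length(got), length(unique(got)))
}

# terms are keyed by canonical CURIE (uppercase prefix), which equals the id
# itself for all fixture prefixes used in these tests
get_in_graph <- function(g, id) g$terms[[id]]

graph_triples <- function(g) {
  sort(paste(g$edges$child_key, g$edges$relation, g$edges$parent_key))
}
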