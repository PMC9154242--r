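fixture_backend <- function(cache = FALSE) {
  fx <- disease_example_fixture()
  local_backend(fx$ontologies, cache = cache)
}

test_that("term_exists distinguishes found, obsolete, and not-found", {
  g <- ontology_graph("toy", list(
    ontology_term("TOY:1"),
    ontology_term("TOY:2", obsolete = TRUE, replaced_by = "TOY:1")))
  b <- local_backend(list(g))
  expect_identical(term_exists(b, "TOY:1")$status, "found")
  v <- term_exists(b, "TOY:2")
  expect_identical(v$status, "obsolete")
  expect_identical(v$replaced_by, "TOY:1")
  expect_identical(term_exists(b, "NOPE:0000001")$status, "not_found")
})

test_that("membership is graph presence, not prefix matching", {
  b <- fixture_backend()
  # MINI-prefixed terms live inside minimondo: found by membership
  expect_identical(term_exists(b, "MINI:0000010", "minimondo")$status, "found")
  # a MONDO-prefixed id absent from the loaded graph is not found
  expect_identical(term_exists(b, "MONDO:9999999")$status, "not_found")
  # restricting to the wrong ontology hides the term
  expect_identical(term_exists(b, "MINI:0000010", "minipato")$status,
                   "not_found")
})

test_that("is_descendant equals include_self exactly on reflexive queries", {
  b <- fixture_backend()
  for (g in b$ontologies) {
    for (t in names(g$terms)) {
      expect_true(is_descendant(b, t, t, include_self = TRUE))
      expect_false(is_descendant(b, t, t, include_self = FALSE))
      expect_true(is_descendant(b, t, t, include_self = TRUE, direct = TRUE))
      expect_false(is_descendant(b, t, t, include_self = FALSE, direct = TRUE))
    }
  }
})

test_that("direct single hops differ from transitive closure on a chain", {
  b <- fixture_backend()
  # MINI:0000011 is_a MINI:0000010 is_a MONDO:0000001
  expect_false(is_descendant(b, "MINI:0000011", "MONDO:0000001", direct = TRUE))
  expect_true(is_descendant(b, "MINI:0000011", "MONDO:0000001"))
  expect_true(is_descendant(b, "MINI:0000011", "MINI:0000010", direct = TRUE))
})

test_that("absent ids and malformed ids yield FALSE, never an error", {
  b <- fixture_backend()
  expect_false(is_descendant(b, "NOPE:1", "MONDO:0000001"))
  expect_false(is_descendant(b, "MINI:0000010", "NOPE:1"))
  expect_false(is_descendant(b, "not a curie", "MONDO:0000001"))
  expect_false(is_descendant(b, "NOPE:1", "NOPE:1", include_self = TRUE))
})

test_that("is_descendant agrees with the reachability oracle on all pairs", {
  g <- generate_dag_ontology(30, max_parents = 3, part_of_fraction = 0.25,
                             seed = 11)
  b <- local_backend(list(g))
  relset <- c("is_a", "part_of")
  closure <- oracle_ancestor_sets(g, relset)
  direct <- oracle_ancestor_sets(g, relset, direct = TRUE)
  for (x in names(g$terms)) {
    for (y in names(g$terms)) {
      expect_identical(is_descendant(b, x, y, relations = relset),
                       y %in% closure[[x]])
      expect_identical(is_descendant(b, x, y, relations = relset,
                                     direct = TRUE),
                       y %in% direct[[x]])
    }
  }
})

test_that("query caching is transparent", {
  g <- generate_dag_ontology(20, seed = 13, obsolete_fraction = 0.2)
  plain <- local_backend(list(g))
  caching <- local_backend(list(g), cache = TRUE)
  ids <- sort(names(g$terms))
  for (x in ids) {
    expect_identical(term_exists(caching, x), term_exists(plain, x))
    for (y in ids[1:5]) {
      expect_identical(is_descendant(caching, x, y),
                       is_descendant(plain, x, y))
      # second pass hits the cache and must not change the answer
      expect_identical(is_descendant(caching, x, y),
                       is_descendant(plain, x, y))
    }
  }
})

test_that("taxon_exists routes through the loaded taxonomy", {
  mf <- miappe_like_fixture()
  b <- mf$backend
  expect_identical(taxon_exists(b, "Zea mays")$status, "found")
  expect_equal(taxon_exists(b, "maize")$tax_ids, 4577L)
  expect_identical(taxon_exists(b, "cress")$status, "ambiguous")
  expect_identical(taxon_exists(local_backend(), "Zea mays")$status,
                   "not_found")
})
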