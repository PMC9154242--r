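disease_backend <- function() disease_example_fixture()$backend

test_that("the registry holds exactly the four extended keywords", {
  reg <- keyword_registry()
  expect_length(reg, 4L)
  expect_setequal(names(reg), c("isValidTerm", "isChildTermOf",
                                "isValidTaxonomy", "graph_restriction"))
  for (def in reg) {
    expect_true(is.function(def$check))
    expect_false(is.null(def$metaschema))
  }
})

test_that("every keyword's metaschema rejects an empty parameter block", {
  b <- disease_backend()
  for (kw in names(keyword_registry())) {
    schema <- read_json_value(sprintf(
      '{"type": "object", "properties": {"x": {"%s": {}}}}', kw))
    expect_error(compile_schema(schema, backend = b),
                 paste0("invalid '", kw, "'"))
  }
})

test_that("isValidTerm: existing term passes, unknown id fails naming the id", {
  b <- disease_backend()
  expect_length(check_is_valid_term("MINI:0000010", NULL, b), 0L)
  errs <- check_is_valid_term("NOPE:0000001", NULL, b)
  expect_length(errs, 1L)
  expect_match(errs[[1]]$message, "NOPE:0000001")
})

test_that("isValidTerm: obsolete terms fail mentioning the replacement", {
  g <- ontology_graph("toy", list(
    ontology_term("TOY:1"),
    ontology_term("TOY:2", obsolete = TRUE, replaced_by = "TOY:1")))
  errs <- check_is_valid_term("TOY:2", NULL, local_backend(list(g)))
  expect_length(errs, 1L)
  expect_match(errs[[1]]$message, "obsolete")
  expect_match(errs[[1]]$message, "TOY:1")
})

test_that("malformed values produce one structured error, never a crash", {
  b <- disease_backend()
  for (bad in list("no-colon", "", "a:b:c", 42L, list(1, 2))) {
    errs <- check_is_valid_term(bad, NULL, b)
    expect_length(errs, 1L)
    expect_match(errs[[1]]$message, "malformed identifier")
  }
  errs <- check_graph_restriction(
    "not a curie", list(ontologies = "minimondo", classes = "MONDO:0000001"), b)
  expect_length(errs, 1L)
  expect_match(errs[[1]]$message, "malformed identifier")
})

test_that("isChildTermOf: child passes, inverted and reflexive queries fail", {
  b <- disease_backend()
  p <- list(parent = "MONDO:0000001", ontologies = "minimondo")
  expect_length(check_is_child_term_of("MINI:0000010", p, b), 0L)
  expect_length(check_is_child_term_of("MINI:0000011", p, b), 0L)  # transitive
  inverted <- list(parent = "MINI:0000010", ontologies = "minimondo")
  expect_length(check_is_child_term_of("MONDO:0000001", inverted, b), 1L)
  expect_length(check_is_child_term_of("MONDO:0000001", p, b), 1L)  # self
})

test_that("isValidTaxonomy: found, unknown and ambiguous verdicts", {
  b <- miappe_like_fixture()$backend
  expect_length(check_is_valid_taxonomy("Zea mays", b), 0L)
  expect_length(check_is_valid_taxonomy(4577L, b), 0L)
  errs <- check_is_valid_taxonomy("No Such Organism", b)
  expect_length(errs, 1L)
  amb <- check_is_valid_taxonomy("cress", b)
  expect_length(amb, 1L)
  expect_match(amb[[1]]$message, "3701")
  expect_match(amb[[1]]$message, "3702")
  empty <- check_is_valid_taxonomy("  ", b)
  expect_match(empty[[1]]$message, "malformed identifier")
})

test_that("graph_restriction: subclass passes, include_self gates the root", {
  b <- disease_backend()
  p <- list(ontologies = c("minimondo", "minipato"),
            classes = c("PATO:0000461", "MONDO:0000001"))
  expect_length(check_graph_restriction("MINI:0000010", p, b), 0L)
  expect_length(check_graph_restriction("MINI:0000020", p, b), 0L)  # PATO side
  expect_length(check_graph_restriction("MONDO:0000001", p, b), 1L)
  p$include_self <- TRUE
  expect_length(check_graph_restriction("MONDO:0000001", p, b), 0L)
})

test_that("graph_restriction error message states which condition failed", {
  b <- disease_backend()
  p <- list(ontologies = "minimondo", classes = "MONDO:0000001")
  membership <- check_graph_restriction("NOPE:0000001", p, b)
  expect_match(membership[[1]]$message, "not a member")
  hierarchy <- check_graph_restriction("MINI:0000099", p, b)
  expect_match(hierarchy[[1]]$message, "does not descend")
})

test_that("graph_restriction with one class equals isChildTermOf", {
  g <- generate_dag_ontology(25, seed = 17, part_of_fraction = 0.2)
  b <- local_backend(list(g))
  ids <- names(g$terms)
  roots <- ids[c(1, 5, 12)]
  for (v in ids) {
    for (r in roots) {
      gr <- check_graph_restriction(
        v, list(ontologies = g$ontology_id, classes = r), b)
      ct <- check_is_child_term_of(
        v, list(parent = r, ontologies = g$ontology_id), b)
      expect_identical(length(gr) == 0L, length(ct) == 0L)
    }
  }
})

test_that("adding a class never turns a passing value into a failing one", {
  g <- generate_dag_ontology(25, seed = 19)
  b <- local_backend(list(g))
  ids <- names(g$terms)
  for (v in ids[seq(1, 25, by = 3)]) {
    base <- list(ontologies = g$ontology_id, classes = ids[[1]])
    widened <- list(ontologies = g$ontology_id,
                    classes = c(ids[[1]], ids[[7]], ids[[13]]))
    if (length(check_graph_restriction(v, base, b)) == 0L)
      expect_length(check_graph_restriction(v, widened, b), 0L)
  }
})

test_that("keyword verdicts match the reachability oracle with membership", {
  g <- generate_dag_ontology(30, max_parents = 3, seed = 23)
  b <- local_backend(list(g))
  closure <- oracle_ancestor_sets(g, "is_a")
  ids <- names(g$terms)
  for (v in ids) {
    for (r in ids) {
      got <- length(check_graph_restriction(
        v, list(ontologies = g$ontology_id, classes = r), b)) == 0L
      expect_identical(got, r %in% closure[[v]])
    }
  }
})
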