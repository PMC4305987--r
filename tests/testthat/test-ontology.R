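test_that("parse_obo reads a minimal aspect-filtered DAG", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: molecular_function",
    "alt_id: GO:0000099",
    "is_a: GO:0000001 ! a", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: molecular_function",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: gone",
    "namespace: molecular_function", "is_obsolete: true",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000010", "name: bp-root",
    "namespace: biological_process"), obo)
  dag <- parse_obo(obo, "MF")
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(nrow(dag$edges), 2L)
  expect_equal(dag$root, "GO:0000001")
  expect_equal(unname(dag$alt_id["GO:0000099"]), "GO:0000002")
  expect_false("GO:0000004" %in% dag$terms)
})

test_that("parse_obo rejects cycles and multiple roots", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "namespace: molecular_function", "is_a: B", "",
    "[Term]", "id: B", "namespace: molecular_function", "is_a: A"), obo)
  expect_error(parse_obo(obo, "MF"), "cycle|root")
  obo2 <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "namespace: molecular_function", "",
    "[Term]", "id: B", "namespace: molecular_function"), obo2)
  expect_error(parse_obo(obo2, "MF"), "root")
})

test_that("ancestors is the reflexive transitive closure", {
  dag <- tiny_dag()
  expect_equal(ancestors(dag, "A"), "A")
  expect_equal(ancestors(dag, "B"), c("A", "B"))
  # diamond: D below both B and C
  dia <- new_ontology_dag(
    c("A", "B", "C", "D"),
    data.frame(child = c("B", "C", "D", "D"),
               parent = c("A", "A", "B", "C"),
               relation = "is_a", stringsAsFactors = FALSE), "MF")
  expect_equal(ancestors(dia, "D"), c("A", "B", "C", "D"))
  expect_equal(ancestors(dia, "D"), oracle_ancestors(dia$edges, "D"))
  expect_error(ancestors(dia, "Z"), "unknown term")
})

test_that("ancestor closure is idempotent and matches enumeration on random DAGs", {
  for (s in 1:5) {
    dag <- random_small_dag(8L, seed = 100 + s)
    for (t in dag$terms) {
      a <- ancestors(dag, t)
      expect_equal(a, oracle_ancestors(dag$edges, t))
      closed_again <- sort(unique(unlist(lapply(a, ancestors, dag = dag))))
      expect_equal(closed_again, a)
    }
  }
})

test_that("parse_gaf applies aspect, NOT and closure rules", {
  dag <- tiny_dag()
  gaf <- tempfile(fileext = ".gaf")
  row <- function(gene, term, qual = "enables", aspect = "F") {
    paste(c("DB", gene, gene, qual, term, "REF", "IEA", "", aspect,
            gene, "", "protein", "taxon:0", "20140101", "DB", "", ""),
          collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               row("g1", "B"), row("g1", "C"),
               row("g2", "B", qual = "NOT|enables"),
               row("g3", "B", aspect = "P")), gaf)
  corp <- parse_gaf(gaf, dag)
  expect_equal(corp$genes, "g1")
  expect_equal(corp$direct$g1, c("B", "C"))
  expect_equal(corp$closed$g1, c("A", "B", "C"))
})

test_that("parse_gaf skips or rejects unknown terms as configured", {
  dag <- tiny_dag()
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c(
    paste(c("DB", "g1", "g1", "", "B", "REF", "IEA", "", "F", rep("", 8)),
          collapse = "\t"),
    paste(c("DB", "g1", "g1", "", "ZZZ", "REF", "IEA", "", "F", rep("", 8)),
          collapse = "\t")), gaf)
  expect_warning(corp <- parse_gaf(gaf, dag), "unknown term")
  expect_equal(corp$direct$g1, "B")
  expect_error(suppressWarnings(parse_gaf(gaf, dag, unknown_term = "error")),
               "unknown term")
})

test_that("information content follows annotation frequency", {
  dag <- new_ontology_dag(
    c("A", "B", "C"),
    data.frame(child = c("B", "C"), parent = c("A", "A"),
               relation = "is_a", stringsAsFactors = FALSE), "MF")
  corp <- annotation_corpus(
    list(g1 = "B", g2 = "B", g3 = "C", g4 = "C"), dag)
  ic <- compute_ic(dag, corp)
  expect_equal(unname(ic$p["A"]), 1)
  expect_equal(unname(ic$ic["A"]), 0)
  expect_equal(unname(ic$p["B"]), 0.5)
  expect_equal(unname(ic$ic["B"]), log(2), tolerance = 1e-12)
  # unannotated term: undefined IC sentinel
  dag2 <- new_ontology_dag(
    c("A", "B", "C"),
    data.frame(child = c("B", "C"), parent = c("A", "A"),
               relation = "is_a", stringsAsFactors = FALSE), "MF")
  corp2 <- annotation_corpus(list(g1 = "B"), dag2)
  ic2 <- compute_ic(dag2, corp2)
  expect_true(is.na(ic2$ic["C"]))
})

test_that("IC is monotone along edges of random annotated DAGs", {
  for (s in 1:5) {
    dag <- random_small_dag(8L, seed = 200 + s)
    corp <- random_corpus(dag, 10L, seed = 300 + s)
    ic <- compute_ic(dag, corp)
    for (k in seq_len(nrow(dag$edges))) {
      pc <- ic$p[[dag$edges$child[k]]]
      pp <- ic$p[[dag$edges$parent[k]]]
      expect_gte(pp, pc)
    }
  }
})

test_that("OBO write/parse round trip reproduces the DAG", {
  spec <- fixture_spec(depth = 3L, branching = 2L, seed = 11L)
  dag <- make_toy_ontology(spec)
  obo <- tempfile(fileext = ".obo")
  write_obo(dag, obo)
  dag2 <- parse_obo(obo, "MF")
  expect_equal(dag2$terms, dag$terms)
  expect_equal(dag2$edges, dag$edges)
  expect_equal(dag2$root, dag$root)
})
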