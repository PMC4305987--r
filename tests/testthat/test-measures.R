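# shared micro-fixture: root A with leaf children B, C, D
abcd_setup <- function() {
  dag <- new_ontology_dag(
    c("A", "B", "C", "D"),
    data.frame(child = c("B", "C", "D"), parent = "A",
               relation = "is_a", stringsAsFactors = FALSE), "MF")
  corp <- annotation_corpus(
    list(g1 = c("B", "C"), g2 = c("B", "D"), g3 = "B", g4 = "C"), dag)
  list(dag = dag, corp = corp, ic = compute_ic(dag, corp))
}

test_that("term-level measures reproduce hand-computed values", {
  fx <- abcd_setup()
  # only common ancestor of two siblings is the root -> resnik 0
  expect_equal(term_similarity(fx$dag, fx$ic, "C", "D", "resnik"), 0)
  # schlicker self-similarity with p(t) = 0.25
  expect_equal(unname(fx$ic$p["D"]), 0.25)
  expect_equal(term_similarity(fx$dag, fx$ic, "D", "D", "schlicker"), 0.75)
  # wang on B is_a A: (0.8 + 1) / (1.8 + 1)
  expect_equal(term_similarity(fx$dag, fx$ic, "B", "A", "wang"),
               1.8 / 2.8, tolerance = 1e-12)
  # hrss leaf self-similarity: gamma = beta = 0
  expect_gt(unname(fx$ic$ic["D"]), 0)
  expect_equal(term_similarity(fx$dag, fx$ic, "D", "D", "hrss"), 1)
  # hrss degenerate root case pinned to 0
  expect_equal(term_similarity(fx$dag, fx$ic, "C", "D", "hrss"), 0)
})

test_that("set-based gene measures follow their set arithmetic", {
  fx <- abcd_setup()
  # closed sets {A,B,C} vs {A,B,D}
  expect_equal(gene_similarity(fx$corp, fx$dag, fx$ic, "g1", "g2", "simui"),
               0.5)
  expect_equal(gene_similarity(fx$corp, fx$dag, fx$ic, "g1", "g2", "to"),
               2 / 3)
  # identical annotations
  corp2 <- annotation_corpus(list(a = c("B", "C"), b = c("B", "C")), fx$dag)
  for (m in c("simui", "to", "simgic")) {
    expect_equal(gene_similarity(corp2, fx$dag, fx$ic, "a", "b", m), 1)
  }
  # genes sharing only the root: every IC-based lifted measure is 0
  for (m in c("resnik", "schlicker", "hrss")) {
    expect_equal(gene_similarity(fx$corp, fx$dag, fx$ic, "g3", "g4", m), 0)
  }
  expect_error(gene_similarity(fx$corp, fx$dag, fx$ic, "g1", "zz", "simui"),
               "zz")
})

test_that("SimUI equals a brute-force Jaccard on random corpora", {
  for (s in 1:3) {
    dag <- random_small_dag(8L, seed = 400 + s)
    corp <- random_corpus(dag, 6L, seed = 410 + s)
    ic <- compute_ic(dag, corp)
    for (pair in list(c(1, 2), c(3, 4), c(5, 6))) {
      g1 <- corp$genes[pair[1]]; g2 <- corp$genes[pair[2]]
      c1 <- sort(unique(unlist(lapply(corp$direct[[g1]],
                                      oracle_ancestors, edges = dag$edges))))
      c2 <- sort(unique(unlist(lapply(corp$direct[[g2]],
                                      oracle_ancestors, edges = dag$edges))))
      expect_equal(gene_similarity(corp, dag, ic, g1, g2, "simui"),
                   length(intersect(c1, c2)) / length(union(c1, c2)))
    }
  }
})

test_that("Wang S-values and MICA match exhaustive enumeration on small DAGs", {
  for (s in 1:5) {
    dag <- random_small_dag(8L, seed = 500 + s)
    corp <- random_corpus(dag, 8L, seed = 510 + s)
    ic <- compute_ic(dag, corp)
    terms <- dag$terms
    for (t in terms) {
      S <- integosim:::.wang_svalues(dag, t)
      for (a in names(S)) {
        expect_equal(unname(S[a]), oracle_wang_svalue(dag$edges, t, a),
                     tolerance = 1e-12)
      }
    }
    annotated <- terms[!is.na(ic$ic[terms])]
    for (i in 1:4) {
      t1 <- annotated[1 + (i %% length(annotated))]
      t2 <- annotated[1 + ((i * 3) %% length(annotated))]
      expect_equal(integosim:::.mica(dag, ic, t1, t2),
                   oracle_mica(dag$edges, ic$ic, t1, t2))
    }
  }
})

test_that("all measures are symmetric and [0,1]-bounded where promised", {
  dag <- random_small_dag(8L, seed = 600)
  corp <- random_corpus(dag, 6L, seed = 601)
  ic <- compute_ic(dag, corp)
  bounded <- c("simui", "to", "simgic", "schlicker", "wang", "hrss")
  for (m in candidate_measures()) {
    for (pair in list(c(1, 3), c(2, 5), c(4, 6))) {
      g1 <- corp$genes[pair[1]]; g2 <- corp$genes[pair[2]]
      v12 <- gene_similarity(corp, dag, ic, g1, g2, m)
      v21 <- gene_similarity(corp, dag, ic, g2, g1, m)
      expect_equal(v12, v21)
      expect_gte(v12, 0)
      if (m %in% bounded) expect_lte(v12, 1 + 1e-12)
    }
  }
})

test_that("similarity_matrices matches pairwise gene_similarity calls", {
  fx <- planted_fixture(seed = 7L)
  genes <- fx$corpus$genes[c(1, 2, 8, 14, 20, 27)]
  mats <- similarity_matrices(fx$corpus, fx$dag, fx$ic, genes)
  expect_length(mats, 7L)
  for (m in names(mats)) {
    df <- as.data.frame(mats[[m]])
    expect_equal(nrow(df), choose(length(genes), 2L))
    for (k in seq_len(nrow(df))) {
      expect_equal(df$score[k],
                   gene_similarity(fx$corpus, fx$dag, fx$ic,
                                   df$gene1[k], df$gene2[k], m),
                   tolerance = 1e-12)
    }
  }
  # permutation of the input gene order leaves results unchanged
  mats2 <- similarity_matrices(fx$corpus, fx$dag, fx$ic, rev(genes),
                               measures = "simui")
  expect_equal(as.data.frame(mats2$simui), as.data.frame(mats$simui))
})

test_that("fake measure copies half the pairs and reverses the rest", {
  fx <- planted_fixture(seed = 7L)
  res <- fx$matrices$resnik
  fake1 <- fake_measure(res, fx$grouping, seed = 3L)
  fake2 <- fake_measure(res, fx$grouping, seed = 3L)
  expect_identical(fake1, fake2)
  df <- as.data.frame(fake1)
  raw <- as.data.frame(res)
  copied <- df$score == raw$score & !(df$score %in% c(0, 1))
  zero_one <- df$score %in% c(0, 1) & df$score != raw$score
  expect_gte(sum(copied | df$score == raw$score), ceiling(nrow(df) / 2))
  # on the reversed half, same-group pairs are 0 and cross-group pairs 1
  grp_of <- function(g) sub("^(G\\d+)\\..*$", "\\1", g)
  same <- grp_of(df$gene1) == grp_of(df$gene2)
  expect_true(all(df$score[zero_one & same] == 0))
  expect_true(all(df$score[zero_one & !same] == 1))
})
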