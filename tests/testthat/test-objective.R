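two_group_fixture <- function() {
  grouping <- ec_grouping(list(e1 = c("g", "a"), e2 = "b"), min_size = 1L)
  sim <- sim_from_table(data.frame(
    gene1 = c("b", "a", "a"), gene2 = c("g", "g", "b"),
    sim = c(0.1, 0.9, 0.2)))
  list(grouping = grouping, sim = sim)
}

test_that("diff_gene reproduces the hand-computed log ratio", {
  fx <- two_group_fixture()
  d <- diff_gene("g", "e1", "e2", fx$sim, fx$grouping, c_smooth = 0.01)
  expect_equal(d, log(0.91 / 0.11), tolerance = 1e-6)
  expect_equal(d, 2.112956, tolerance = 1e-5)
})

test_that("logfc sums per-gene diffs over disjoint groups", {
  fx <- two_group_fixture()
  v <- logfc("e1", fx$grouping, fx$sim, c_smooth = 0.01)
  expect_equal(v, log(0.91 / 0.11) + log(0.81 / 0.11), tolerance = 1e-6)
  expect_equal(v, 4.109574, tolerance = 1e-4)
})

test_that("uniform similarity gives exactly zero LogFC", {
  grouping <- ec_grouping(list(e1 = c("a", "b", "c"), e2 = c("d", "e", "f"),
                               e3 = c("h", "i", "j")), min_size = 3L)
  genes <- grouping_genes(grouping)
  pairs <- integosim:::.canonical_pairs(genes)
  for (s in c(0, 0.37, 1)) {
    sim <- sim_from_table(cbind(pairs, sim = s))
    for (ei in names(grouping$groups)) {
      expect_equal(logfc(ei, grouping, sim), 0, tolerance = 1e-12)
    }
    expect_equal(optf(grouping, sim), 0, tolerance = 1e-12)
  }
})

test_that("diff sign tracks the inter/intra separation direction", {
  grouping <- ec_grouping(list(e1 = c("a", "b"), e2 = c("c", "d")),
                          min_size = 2L)
  good <- sim_from_table(data.frame(
    gene1 = c("a", "a", "a", "b", "b", "c"),
    gene2 = c("b", "c", "d", "c", "d", "d"),
    sim = c(0.9, 0.1, 0.1, 0.1, 0.1, 0.9)))
  bad <- sim_from_table(data.frame(
    gene1 = c("a", "a", "a", "b", "b", "c"),
    gene2 = c("b", "c", "d", "c", "d", "d"),
    sim = c(0.1, 0.9, 0.9, 0.9, 0.9, 0.1)))
  expect_gt(diff_gene("a", "e1", "e2", good, grouping), 0)
  expect_lt(diff_gene("a", "e1", "e2", bad, grouping), 0)
  # smoothing constant changes diff smoothly without flipping the sign
  for (cs in c(0.001, 0.01, 0.1)) {
    expect_gt(diff_gene("a", "e1", "e2", good, grouping, c_smooth = cs), 0)
  }
})

test_that("invalid diff_gene inputs are rejected", {
  grouping <- ec_grouping(list(e1 = c("a", "b"), e2 = c("b", "c"),
                               e3 = "z"), min_size = 1L)
  sim <- function(g1, g2) 0.5
  expect_error(diff_gene("a", "e1", "e2", sim, grouping), "share genes")
  expect_error(diff_gene("z", "e3", "e1", sim, grouping), "no gene other")
  expect_error(diff_gene("c", "e1", "e2", sim, grouping), "not in group")
})

test_that("a group overlapping every other group yields NA with a message", {
  grouping <- ec_grouping(list(e1 = c("a", "b"), e2 = c("b", "c")),
                          min_size = 2L)
  sim <- function(g1, g2) 0.5
  expect_message(v <- logfc("e1", grouping, sim), "undefined")
  expect_true(is.na(v))
  expect_error(optf(grouping, sim), "undefined for every group")
})

test_that("optf is invariant under relabeling of groups and genes", {
  set.seed(77)
  groups <- list(A = c("g1", "g2", "g3", "g4"),
                 B = c("g5", "g6", "g7", "g8"),
                 C = c("g9", "g10", "g11", "g12"))
  grouping <- ec_grouping(groups, min_size = 3L)
  genes <- grouping_genes(grouping)
  pairs <- integosim:::.canonical_pairs(genes)
  tab <- cbind(pairs, sim = runif(nrow(pairs)))
  v1 <- optf(grouping, sim_from_table(tab))
  # relabel genes g* -> x* and groups A/B/C -> Z1/Z2/Z3
  rl <- function(g) sub("^g", "x", g)
  tab2 <- data.frame(gene1 = rl(tab$gene1), gene2 = rl(tab$gene2),
                     sim = tab$sim)
  grouping2 <- ec_grouping(setNames(lapply(groups, rl),
                                    c("Z3", "Z1", "Z2")), min_size = 3L)
  v2 <- optf(grouping2, sim_from_table(tab2))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("vectorized objective equals naive triple-loop recomputation", {
  fx <- planted_fixture(seed = 7L)
  rm_ <- build_rank_matrix(fx$matrices)
  sg <- seed_groups(rm_)
  ps <- mean_parameter_set(rm_$measures)
  ctx <- build_objective_context(rm_, sg, fx$grouping, c_smooth = 0.01)
  simfun <- sim_from_model(rm_, sg, ps)
  # naive re-evaluation straight from the printed definitions
  gids <- names(fx$grouping$groups)
  cs <- 0.01
  lf <- vapply(gids, function(ei) {
    Gi <- fx$grouping$groups[[ei]]
    others <- gids[gids != ei]
    acc <- 0
    for (ej in others) {
      Gj <- fx$grouping$groups[[ej]]
      for (g in Gi) {
        I <- setdiff(Gi, g)
        num <- length(I) * sum(sapply(Gj, function(x) 1 - simfun(g, x) + cs))
        den <- length(Gj) * sum(sapply(I, function(x) 1 - simfun(g, x) + cs))
        acc <- acc + (log(num) - log(den)) / length(Gj)
      }
    }
    acc / length(others)
  }, 0)
  expect_equal(context_optf(ctx, ps), mean(lf), tolerance = 1e-10)
  expect_equal(optf(fx$grouping, simfun), mean(lf), tolerance = 1e-10)
})

test_that("the ei-divisor variant rescales the inner sum", {
  fx <- two_group_fixture()
  v_ej <- logfc("e1", fx$grouping, fx$sim, divisor = "ej")
  v_ei <- logfc("e1", fx$grouping, fx$sim, divisor = "ei")
  expect_equal(v_ei, v_ej / 2, tolerance = 1e-12)  # |ei|=2, |ej|=1
})
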