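#' Specification for a synthetic ontology/annotation fixture
#'
#' Defines the shape of a toy GO-like DAG and of an annotation corpus with
#' planted functional signal: genes are organized in functional groups,
#' each group owns a disjoint pool of leaf terms, and a gene draws each
#' term of its own pool with probability `p_in` and each off-pool leaf
#' with probability `p_out`. With `p_in > p_out`, genes within a group
#' share annotations more often than genes across groups, which is the
#' signal the separation objective rewards.
#'
#' @param depth tree depth below the root (root is depth 0).
#' @param branching children per internal term.
#' @param n_groups number of functional gene groups.
#' @param genes_per_group genes in each group.
#' @param p_in probability of drawing each term of the group's pool.
#' @param p_out background probability of drawing each off-pool leaf.
#' @param p_cross fraction of terms receiving an extra random `part_of`
#'   edge to a shallower term.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `fixture_spec` list (with derived field `n_terms`).
#' @export
fixture_spec <- function(depth = 4L, branching = 3L, n_groups = 5L,
                         genes_per_group = 6L, p_in = 0.8, p_out = 0.1,
                         p_cross = 0.1, seed = 1L) {
  stopifnot(depth >= 1L, branching >= 1L, n_groups >= 1L,
            genes_per_group >= 1L, p_out >= 0, p_in <= 1, p_out < p_in,
            p_cross >= 0, p_cross <= 1)
  structure(list(depth = depth, branching = branching,
                 n_groups = n_groups, genes_per_group = genes_per_group,
                 p_in = p_in, p_out = p_out, p_cross = p_cross,
                 seed = as.integer(seed),
                 n_terms = sum(branching^(0:depth))),
            class = "fixture_spec")
}

#' Generate a toy ontology DAG
#'
#' Builds a complete `is_a` tree of the requested depth and branching,
#' then adds roughly `p_cross * n_terms` random `part_of` edges from
#' deeper terms to strictly shallower non-parent terms (edges always point
#' to a shallower level, so the graph stays acyclic). Deterministic given
#' the spec's seed; the optional OBO serialization is byte-identical
#' across runs.
#'
#' @param spec a [fixture_spec()].
#' @param path optional path: write the DAG as an OBO file.
#' @param aspect ontology aspect of the generated DAG.
#' @return an `ontology_dag`.
#' @export
make_toy_ontology <- function(spec, path = NULL, aspect = "MF") {
  set.seed(spec$seed)
  n <- spec$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  level <- integer(n)
  parent <- integer(n)  # tree parent index, 0 for root
  for (d in seq_len(spec$depth)) {
    n_level <- spec$branching^d
    prev_start <- sum(spec$branching^(0:(d - 1L))) - spec$branching^(d - 1L) + 1L
    this_start <- sum(spec$branching^(0:(d - 1L))) + 1L
    idx <- this_start:(this_start + n_level - 1L)
    level[idx] <- d
    parent[idx] <- prev_start + (seq_len(n_level) - 1L) %/% spec$branching
  }
  e_child <- ids[level > 0]
  e_parent <- ids[parent[level > 0]]
  edges <- data.frame(child = e_child, parent = e_parent,
                      relation = "is_a", stringsAsFactors = FALSE)
  n_cross <- round(spec$p_cross * n)
  deep <- which(level >= 2L)
  if (n_cross > 0L && length(deep)) {
    added <- 0L
    guard <- 0L
    while (added < n_cross && guard < 50L * n_cross) {
      guard <- guard + 1L
      u <- deep[sample.int(length(deep), 1L)]
      shallow <- which(level < level[u])
      v <- shallow[sample.int(length(shallow), 1L)]
      if (v == parent[u]) next
      if (any(edges$child == ids[u] & edges$parent == ids[v])) next
      edges <- rbind(edges,
                     data.frame(child = ids[u], parent = ids[v],
                                relation = "part_of",
                                stringsAsFactors = FALSE))
      added <- added + 1L
    }
  }
  dag <- new_ontology_dag(ids, edges, aspect)
  if (!is.null(path)) write_obo(dag, path)
  dag
}

#' Generate annotated gene groups with planted signal
#'
#' Partitions the DAG's leaf terms into one disjoint pool per functional
#' group and draws each gene's direct annotations from its group's pool
#' (probability `p_in` per pool term) and from all remaining leaves
#' (probability `p_out` per leaf). Genes drawing no term are redrawn (up
#' to 50 attempts). Group memberships are disjoint unless
#' `overlap = TRUE`, which additionally places each group's first gene in
#' the following group to exercise the disjointness filter of the
#' objective.
#'
#' @param dag an `ontology_dag` from [make_toy_ontology()].
#' @param spec the same [fixture_spec()].
#' @param gaf_path optional path: write annotations as GAF 2.2.
#' @param grouping_path optional path: write the grouping as 2-column TSV.
#' @param overlap create overlapping group memberships (default FALSE).
#' @return list with `corpus` (an `annotation_corpus`), `grouping` (an
#'   `ec_grouping`) and `pools` (term pool per group).
#' @export
make_annotated_groups <- function(dag, spec, gaf_path = NULL,
                                  grouping_path = NULL, overlap = FALSE) {
  set.seed(spec$seed + 1L)
  leaves <- leaf_terms(dag)
  if (length(leaves) < spec$n_groups) {
    stop("DAG has ", length(leaves), " leaves; need at least one per group")
  }
  pool_size <- length(leaves) %/% spec$n_groups
  pools <- lapply(seq_len(spec$n_groups), function(g) {
    leaves[((g - 1L) * pool_size + 1L):(g * pool_size)]
  })
  names(pools) <- sprintf("EC%02d", seq_len(spec$n_groups))
  direct <- list()
  members <- list()
  for (g in seq_len(spec$n_groups)) {
    own <- pools[[g]]
    off <- setdiff(leaves, own)
    for (k in seq_len(spec$genes_per_group)) {
      gene <- sprintf("G%02d.%02d", g, k)
      terms <- character()
      for (try in seq_len(50L)) {
        terms <- c(own[runif(length(own)) < spec$p_in],
                   off[runif(length(off)) < spec$p_out])
        if (length(terms)) break
      }
      if (!length(terms)) stop("gene ", gene, " drew no terms in 50 attempts")
      direct[[gene]] <- sort(terms)
      members[[names(pools)[g]]] <- c(members[[names(pools)[g]]], gene)
    }
  }
  if (overlap) {
    for (g in seq_len(spec$n_groups - 1L)) {
      members[[g + 1L]] <- c(members[[g + 1L]], members[[g]][1L])
    }
  }
  corpus <- annotation_corpus(direct, dag)
  grouping <- ec_grouping(members,
                          min_size = min(3L, spec$genes_per_group))
  if (!is.null(gaf_path)) write_gaf(direct, gaf_path, dag$aspect)
  if (!is.null(grouping_path)) write_grouping(grouping, grouping_path)
  list(corpus = corpus, grouping = grouping, pools = pools)
}
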