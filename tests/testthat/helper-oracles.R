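# Independent reference implementations used to cross-check the package.
# Deliberately written as naive enumerations, not as calls into the code
# paths they verify.

# average-tie ranking: for each element, the mean of the sorted positions
# holding its value
oracle_rank_average <- function(x) {
  s <- sort(x)
  vapply(x, function(v) mean(which(s == v)), 0)
}

# all ancestors of `t` by exhaustive upward path enumeration over an edge
# data frame (child, parent, relation); includes t itself
oracle_ancestors <- function(edges, t) {
  found <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, found)
    found <- c(found, nxt)
    frontier <- nxt
  }
  sort(found)
}

# Wang S-value of ancestor `a` w.r.t. term `t`: maximum over all directed
# paths t -> ... -> a of the product of edge weights
oracle_wang_svalue <- function(edges, t, a, w = c(is_a = 0.8, part_of = 0.6)) {
  if (a == t) return(1)
  best <- -Inf
  walk <- function(node, prod) {
    if (node == a) {
      best <<- max(best, prod)
      return()
    }
    up <- which(edges$child == node)
    for (i in up) walk(edges$parent[i], prod * w[[edges$relation[i]]])
  }
  walk(t, 1)
  if (is.finite(best)) best else 0
}

# MICA by brute force: intersect enumerated ancestor sets, take the term
# with maximal defined IC (ties: first in sorted order)
oracle_mica <- function(edges, ic, t1, t2) {
  common <- intersect(oracle_ancestors(edges, t1), oracle_ancestors(edges, t2))
  common <- common[!is.na(ic[common])]
  common[which.max(ic[common])]
}

# best contiguous run by explicit enumeration of all sorted subranges,
# scored with the documented tie rules (size, diameter, median, position)
oracle_seed_group <- function(values, min_size, d_prime) {
  ord <- order(values, names(values))
  v <- unname(values[ord])
  nm <- names(values)[ord]
  n <- length(v)
  med <- median(v)
  cand <- expand.grid(i = seq_len(n), j = seq_len(n))
  cand <- cand[cand$i <= cand$j, ]
  cand$diam <- v[cand$j] - v[cand$i]
  cand <- cand[cand$diam <= d_prime + 1e-12, ]
  cand$size <- cand$j - cand$i + 1L
  cand$has_med <- v[cand$i] <= med & med <= v[cand$j]
  cand <- cand[order(-cand$size, cand$diam, -cand$has_med, cand$i), ]
  top <- cand[1L, ]
  if (top$size < min_size) {
    list(members = nm, fallback = TRUE, removed_low = 0L, removed_high = 0L)
  } else {
    list(members = nm[top$i:top$j], fallback = FALSE,
         removed_low = top$i - 1L, removed_high = n - top$j)
  }
}

# random small DAG fixture: a chain/tree hybrid on <= n terms with both
# relation types, always rooted at "R"
random_small_dag <- function(n, seed) {
  set.seed(seed)
  terms <- c("R", paste0("T", seq_len(n - 1L)))
  child <- character(); parent <- character(); rel <- character()
  for (k in 2:n) {
    n_par <- sample(1:min(2L, k - 1L), 1L)
    pars <- sample(terms[seq_len(k - 1L)], n_par)
    child <- c(child, rep(terms[k], n_par))
    parent <- c(parent, pars)
    rel <- c(rel, sample(c("is_a", "part_of"), n_par, replace = TRUE))
  }
  new_ontology_dag(terms,
                   data.frame(child = child, parent = parent, relation = rel,
                              stringsAsFactors = FALSE),
                   "MF")
}

# random annotation corpus over a DAG's leaves
random_corpus <- function(dag, n_genes, seed) {
  set.seed(seed)
  leaves <- leaf_terms(dag)
  direct <- lapply(seq_len(n_genes), function(i) {
    sample(leaves, sample(1:min(3L, length(leaves)), 1L))
  })
  names(direct) <- sprintf("g%02d", seq_len(n_genes))
  annotation_corpus(direct, dag)
}

# tiny 3-term DAG (B is_a A, C part_of A) used across files
tiny_dag <- function() {
  new_ontology_dag(c("A", "B", "C"),
                   data.frame(child = c("B", "C"), parent = c("A", "A"),
                              relation = c("is_a", "part_of"),
                              stringsAsFactors = FALSE),
                   "MF")
}

# shared planted-signal fixture (cached per session to keep tests fast)
planted_fixture <- local({
  cache <- list()
  function(seed = 7L, ...) {
    key <- paste(seed, ..., sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- fixture_spec(seed = seed, ...)
    dag <- make_toy_ontology(spec)
    fx <- make_annotated_groups(dag, spec)
    ic <- compute_ic(dag, fx$corpus)
    mats <- similarity_matrices(fx$corpus, dag, ic)
    out <- list(spec = spec, dag = dag, corpus = fx$corpus,
                grouping = fx$grouping, ic = ic, matrices = mats)
    cache[[key]] <<- out
    out
  }
})
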