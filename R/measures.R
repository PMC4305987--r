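.TERM_MEASURES <- c("resnik", "schlicker", "wang", "hrss")
.SET_MEASURES <- c("simui", "to", "simgic")

#' Candidate similarity measure names
#'
#' The seven gene-pair similarity measures integrated by the package:
#' `resnik`, `schlicker`, `wang`, `hrss` (term-level measures lifted to
#' genes by best-match average) and `simui`, `to`, `simgic` (annotation-set
#' measures).
#'
#' @return character vector of measure names.
#' @export
candidate_measures <- function() c(.TERM_MEASURES, .SET_MEASURES)

#' Similarity matrix over unordered gene pairs
#'
#' @param pairs data frame with columns `gene1`, `gene2`, `score`; each row
#'   an unordered gene pair, stored with `gene1 < gene2`.
#' @param measure measure name.
#' @param genes the covered gene set.
#' @return a `sim_matrix` (a data frame with attributes `measure`, `genes`).
#' @keywords internal
new_sim_matrix <- function(pairs, measure, genes) {
  stopifnot(all(c("gene1", "gene2", "score") %in% names(pairs)))
  swap <- pairs$gene1 > pairs$gene2
  if (any(swap)) {
    tmp <- pairs$gene1[swap]
    pairs$gene1[swap] <- pairs$gene2[swap]
    pairs$gene2[swap] <- tmp
  }
  pairs <- pairs[order(pairs$gene1, pairs$gene2), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, measure = measure, genes = sort(genes),
            class = c("sim_matrix", "data.frame"))
}

.canonical_pairs <- function(genes) {
  genes <- sort(genes)
  if (length(genes) < 2L) stop("need at least 2 genes")
  cmb <- utils::combn(genes, 2L)
  data.frame(gene1 = cmb[1L, ], gene2 = cmb[2L, ], stringsAsFactors = FALSE)
}

.mica <- function(dag, ic_tab, t1, t2) {
  common <- intersect(ancestors(dag, t1), ancestors(dag, t2))
  vals <- ic_tab$ic[common]
  common <- common[!is.na(vals)]
  if (!length(common)) stop("no IC-defined common ancestor for ", t1, ", ", t2)
  vals <- ic_tab$ic[common]
  common[which.max(vals)]  # ties: first in sorted ancestor order
}

.wang_svalues <- function(dag, t, w = c(is_a = 0.8, part_of = 0.6)) {
  anc <- ancestors(dag, t)
  S <- setNames(numeric(length(anc)), anc)
  S[t] <- 1
  repeat {  # DAG relaxation to fixpoint; bounded by |anc| passes
    changed <- FALSE
    for (a in anc) {
      if (a == t) next
      idx <- dag$child_idx[[a]]
      if (!length(idx)) next
      ch <- dag$edges$child[idx]
      rel <- dag$edges$relation[idx]
      keep <- ch %in% anc
      if (!any(keep)) next
      val <- max(w[rel[keep]] * S[ch[keep]])
      if (val > S[a] + 1e-15) {
        S[a] <- val
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  S
}

# IC of the most informative leaf descendant of t (t itself when t is a
# leaf; falls back to ic(t) when no leaf descendant has defined IC).
.mil_ic <- function(dag, ic_tab, t) {
  desc <- descendants(dag, t)
  leaves <- desc[vapply(dag$child_idx[desc], length, 1L) == 0L]
  vals <- ic_tab$ic[leaves]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(ic_tab$ic[[t]])
  max(vals)
}

#' Term-to-term semantic similarity
#'
#' Implements four term-level measures:
#' \describe{
#'   \item{resnik}{IC of the most informative common ancestor (MICA);
#'     unbounded above, 0 when only the root is shared.}
#'   \item{schlicker}{relevance similarity
#'     `2 ic(MICA) / (ic(t1) + ic(t2)) * (1 - p(MICA))`; defined as 0 when
#'     both terms are the root.}
#'   \item{wang}{topology-only S-value similarity with contribution weights
#'     0.8 (`is_a`) and 0.6 (`part_of`).}
#'   \item{hrss}{hybrid relative specificity similarity
#'     `1/(1 + gamma) * alpha/(alpha + beta)` with `alpha = ic(MICA)`,
#'     `gamma` the summed IC distance of the terms to the MICA and `beta`
#'     the mean IC distance to their most informative leaf descendants;
#'     the degenerate `alpha = beta = 0` case is defined as 0.}
#' }
#'
#' @param dag an `ontology_dag`.
#' @param ic_tab an `ic_table` from [compute_ic()].
#' @param t1,t2 term identifiers.
#' @param measure one of `"resnik"`, `"schlicker"`, `"wang"`, `"hrss"`.
#' @param wang_weights named numeric contribution weights per relation.
#' @return a single numeric similarity.
#' @export
term_similarity <- function(dag, ic_tab, t1, t2,
                            measure = c("resnik", "schlicker", "wang", "hrss"),
                            wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  if (measure != "wang") {
    if (is.na(ic_tab$ic[[t1]]) || is.na(ic_tab$ic[[t2]])) {
      stop("term without defined IC for measure ", measure, ": ",
           paste(c(t1, t2)[is.na(ic_tab$ic[c(t1, t2)])], collapse = ", "))
    }
  }
  switch(measure,
    resnik = {
      ic_tab$ic[[.mica(dag, ic_tab, t1, t2)]]
    },
    schlicker = {
      ic1 <- ic_tab$ic[[t1]]; ic2 <- ic_tab$ic[[t2]]
      if (ic1 + ic2 == 0) return(0)
      m <- .mica(dag, ic_tab, t1, t2)
      2 * ic_tab$ic[[m]] / (ic1 + ic2) * (1 - ic_tab$p[[m]])
    },
    wang = {
      S1 <- .wang_svalues(dag, t1, wang_weights)
      S2 <- .wang_svalues(dag, t2, wang_weights)
      common <- intersect(names(S1), names(S2))
      (sum(S1[common]) + sum(S2[common])) / (sum(S1) + sum(S2))
    },
    hrss = {
      ic1 <- ic_tab$ic[[t1]]; ic2 <- ic_tab$ic[[t2]]
      alpha <- ic_tab$ic[[.mica(dag, ic_tab, t1, t2)]]
      gamma <- (ic1 - alpha) + (ic2 - alpha)
      beta <- ((.mil_ic(dag, ic_tab, t1) - ic1) +
                 (.mil_ic(dag, ic_tab, t2) - ic2)) / 2
      if (alpha == 0 && beta == 0) return(0)
      (1 / (1 + gamma)) * (alpha / (alpha + beta))
    })
}

.bma <- function(sim_mat) {
  (sum(apply(sim_mat, 1L, max)) + sum(apply(sim_mat, 2L, max))) /
    (nrow(sim_mat) + ncol(sim_mat))
}

#' Gene-to-gene similarity under one candidate measure
#'
#' Annotation-set measures compare the ancestor-closed annotation sets:
#' `simui` is the Jaccard index, `to` the closure overlap normalized by the
#' smaller closed set, and `simgic` the IC-weighted Jaccard. Term-level
#' measures (`resnik`, `schlicker`, `wang`, `hrss`) are lifted to gene
#' pairs by the best-match average over the genes' direct term sets.
#'
#' @inheritParams term_similarity
#' @param corpus an `annotation_corpus`.
#' @param g1,g2 annotated gene identifiers.
#' @param measure one of [candidate_measures()].
#' @return a single numeric similarity.
#' @export
gene_similarity <- function(corpus, dag, ic_tab, g1, g2,
                            measure = candidate_measures()) {
  measure <- match.arg(measure)
  for (g in c(g1, g2)) {
    if (!g %in% corpus$genes) stop("gene not annotated: ", g)
  }
  if (measure %in% .SET_MEASURES) {
    c1 <- corpus$closed[[g1]]; c2 <- corpus$closed[[g2]]
    inter <- intersect(c1, c2); uni <- union(c1, c2)
    switch(measure,
      simui = length(inter) / length(uni),
      to = length(inter) / min(length(c1), length(c2)),
      simgic = {
        den <- sum(ic_tab$ic[uni])
        if (den == 0) return(as.numeric(setequal(c1, c2)))
        sum(ic_tab$ic[inter]) / den
      })
  } else {
    T1 <- corpus$direct[[g1]]; T2 <- corpus$direct[[g2]]
    sims <- outer(seq_along(T1), seq_along(T2),
                  Vectorize(function(i, j) {
                    term_similarity(dag, ic_tab, T1[i], T2[j], measure)
                  }))
    .bma(matrix(sims, nrow = length(T1)))
  }
}

# Term-similarity lookup matrices over a fixed term universe; computed once
# per call of similarity_matrices() so that gene-pair scoring is indexing.
.term_sim_cache <- function(dag, ic_tab, terms, measures) {
  terms <- sort(unique(terms))
  n <- length(terms)
  out <- list()
  need_anc <- any(measures %in% c("resnik", "schlicker", "hrss"))
  anc <- if (need_anc) lapply(setNames(terms, terms), ancestors, dag = dag)
  mil <- if ("hrss" %in% measures)
    vapply(setNames(terms, terms), .mil_ic, 0, dag = dag, ic_tab = ic_tab)
  sv <- if ("wang" %in% measures)
    lapply(setNames(terms, terms), .wang_svalues, dag = dag)
  for (m in measures) {
    M <- matrix(0, n, n, dimnames = list(terms, terms))
    for (i in seq_len(n)) {
      for (j in i:n) {
        t1 <- terms[i]; t2 <- terms[j]
        v <- switch(m,
          resnik = , schlicker = , hrss = {
            common <- intersect(anc[[t1]], anc[[t2]])
            vals <- ic_tab$ic[common]
            common <- common[!is.na(vals)]
            micaic <- max(ic_tab$ic[common], 0)
            if (m == "resnik") micaic
            else if (m == "schlicker") {
              s <- ic_tab$ic[[t1]] + ic_tab$ic[[t2]]
              if (s == 0) 0
              else 2 * micaic / s * (1 - exp(-micaic))
            } else {
              ic1 <- ic_tab$ic[[t1]]; ic2 <- ic_tab$ic[[t2]]
              gamma <- (ic1 - micaic) + (ic2 - micaic)
              beta <- ((mil[[t1]] - ic1) + (mil[[t2]] - ic2)) / 2
              if (micaic == 0 && beta == 0) 0
              else (1 / (1 + gamma)) * (micaic / (micaic + beta))
            }
          },
          wang = {
            common <- intersect(names(sv[[t1]]), names(sv[[t2]]))
            (sum(sv[[t1]][common]) + sum(sv[[t2]][common])) /
              (sum(sv[[t1]]) + sum(sv[[t2]]))
          })
        M[i, j] <- v
        M[j, i] <- v
      }
    }
    out[[m]] <- M
  }
  out
}

#' Raw similarity matrices for a gene set under several measures
#'
#' Computes one [new_sim_matrix()] per requested measure over all
#' `choose(n, 2)` unordered pairs of `gene_set`. Results are identical to
#' calling [gene_similarity()] pair by pair, but term-level similarities
#' are cached over the union of direct annotation terms.
#'
#' @inheritParams gene_similarity
#' @param gene_set genes to score (all must be annotated); at least 2.
#' @param measures subset of [candidate_measures()].
#' @return named list of `sim_matrix` objects, one per measure.
#' @export
similarity_matrices <- function(corpus, dag, ic_tab,
                                gene_set = corpus$genes,
                                measures = candidate_measures()) {
  measures <- match.arg(measures, candidate_measures(), several.ok = TRUE)
  if (length(gene_set) < 2L) stop("need at least 2 genes")
  missing <- setdiff(gene_set, corpus$genes)
  if (length(missing)) {
    stop("unannotated gene(s): ", paste(head(missing, 5), collapse = ", "))
  }
  gene_set <- sort(gene_set)
  pairs <- .canonical_pairs(gene_set)
  term_measures <- intersect(measures, .TERM_MEASURES)
  cache <- NULL
  if (length(term_measures)) {
    universe <- sort(unique(unlist(corpus$direct[gene_set])))
    bad <- universe[is.na(ic_tab$ic[universe])]
    if (length(bad)) {
      stop("direct annotation term(s) without defined IC: ",
           paste(head(bad, 5), collapse = ", "))
    }
    cache <- .term_sim_cache(dag, ic_tab, universe, term_measures)
  }
  out <- list()
  for (m in measures) {
    score <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
      if (m %in% .SET_MEASURES) {
        score[k] <- gene_similarity(corpus, dag, ic_tab, g1, g2, m)
      } else {
        sub <- cache[[m]][corpus$direct[[g1]], corpus$direct[[g2]],
                          drop = FALSE]
        score[k] <- .bma(sub)
      }
    }
    out[[m]] <- new_sim_matrix(cbind(pairs, score = score), m, gene_set)
  }
  out
}

#' Fake low-quality measure for robustness experiments
#'
#' Emulates the inclusion of a wrong measure: a uniformly sampled half of
#' the gene pairs keep their Resnik scores, while the remaining half get
#' deliberately reversed values — 0 when the pair shares a functional group
#' (so truly similar genes look dissimilar) and 1 otherwise. Pairs without
#' any group assignment on the reversed half are treated as
#' different-group (score 1).
#'
#' @param resnik_matrix a `sim_matrix` of Resnik scores.
#' @param grouping an `ec_grouping` covering the matrix's gene set.
#' @param seed integer seed controlling which half keeps Resnik scores.
#' @return a `sim_matrix` named `"fake"`.
#' @export
fake_measure <- function(resnik_matrix, grouping, seed = 1L) {
  pairs <- as.data.frame(resnik_matrix)
  P <- nrow(pairs)
  gene2groups <- list()
  for (gid in names(grouping$groups)) {
    for (g in grouping$groups[[gid]]) {
      gene2groups[[g]] <- c(gene2groups[[g]], gid)
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  keep_idx <- sample.int(P, ceiling(P / 2))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  score <- numeric(P)
  score[keep_idx] <- pairs$score[keep_idx]
  flip <- setdiff(seq_len(P), keep_idx)
  n_unassigned <- 0L
  for (k in flip) {
    gr1 <- gene2groups[[pairs$gene1[k]]]
    gr2 <- gene2groups[[pairs$gene2[k]]]
    if (!length(gr1) || !length(gr2)) n_unassigned <- n_unassigned + 1L
    score[k] <- if (length(gr1) && length(gr2) && length(intersect(gr1, gr2)))
      0 else 1
  }
  if (n_unassigned) {
    message(n_unassigned, " reversed pair(s) without group assignment ",
            "treated as different-group")
  }
  new_sim_matrix(data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
                            score = score),
                 "fake", attr(resnik_matrix, "genes"))
}

#' Write / read a similarity matrix as TSV
#'
#' Columns `gene1`, `gene2`, `score`; the measure name travels in a header
#' comment line.
#'
#' @param x a `sim_matrix`.
#' @param path file path.
#' @return `path` invisibly, or a `sim_matrix` for the reader.
#' @export
write_sim_matrix <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# measure: ", attr(x, "measure")), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_matrix
#' @export
read_sim_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  measure <- sub("^# measure: ", "", first)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  new_sim_matrix(df, measure, sort(unique(c(df$gene1, df$gene2))))
}
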