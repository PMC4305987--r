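#' Functional grouping of genes (EC numbers or pathways)
#'
#' Groups genes by independent biological evidence — Enzyme Commission
#' numbers for molecular function, pathway membership for biological
#' process. Groups smaller than `min_size` are dropped (defaults used in
#' practice: 3 for EC groups, 2 for pathways).
#'
#' @param groups named list: group id -> character vector of gene ids.
#' @param min_size minimum retained group size.
#' @return an `ec_grouping`: list with `groups` (filtered, genes sorted)
#'   and `min_size`.
#' @export
ec_grouping <- function(groups, min_size = 3L) {
  stopifnot(is.list(groups), length(groups) > 0L, min_size >= 1L)
  if (is.null(names(groups))) stop("groups must be named")
  groups <- lapply(groups, function(g) sort(unique(as.character(g))))
  groups <- groups[lengths(groups) >= min_size]
  if (!length(groups)) stop("no group of size >= ", min_size)
  structure(list(groups = groups[order(names(groups))], min_size = min_size),
            class = "ec_grouping")
}

#' @export
print.ec_grouping <- function(x, ...) {
  cat(sprintf("<ec_grouping> groups=%d genes=%d (min size %d)\n",
              length(x$groups), length(unique(unlist(x$groups))),
              x$min_size))
  invisible(x)
}

#' All genes covered by a grouping
#' @param grouping an `ec_grouping`.
#' @return sorted character vector of gene ids.
#' @export
grouping_genes <- function(grouping) sort(unique(unlist(grouping$groups)))

#' Read / write a two-column grouping TSV
#'
#' One membership row per line: `group_id <tab> gene`.
#'
#' @param path file path.
#' @param min_size passed to [ec_grouping()].
#' @return an `ec_grouping`.
#' @export
read_grouping <- function(path, min_size = 3L) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("group", "gene"))
  ec_grouping(split(df$gene, df$group), min_size)
}

#' @rdname read_grouping
#' @param grouping an `ec_grouping` to write.
#' @export
write_grouping <- function(grouping, path) {
  rows <- data.frame(
    group = rep(names(grouping$groups), lengths(grouping$groups)),
    gene = unlist(grouping$groups, use.names = FALSE))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Similarity-function adapters
#'
#' The separation objective evaluates any symmetric pair-similarity
#' function. These adapters wrap the package's tabular objects into the
#' `function(g1, g2) -> numeric` contract: a raw pair-score table, one
#' measure's RankSim column, or the trained addition model.
#'
#' @param table data frame with columns `gene1`, `gene2` and a score
#'   column.
#' @param score_col name of the score column in `table`.
#' @return a function of two gene ids returning a numeric similarity.
#' @export
sim_from_table <- function(table, score_col = "sim") {
  env <- new.env(parent = emptyenv(), size = 2L * nrow(table))
  for (k in seq_len(nrow(table))) {
    g1 <- table$gene1[k]; g2 <- table$gene2[k]
    key <- if (g1 < g2) paste0(g1, "\r", g2) else paste0(g2, "\r", g1)
    assign(key, table[[score_col]][k], envir = env)
  }
  function(g1, g2) {
    key <- if (g1 < g2) paste0(g1, "\r", g2) else paste0(g2, "\r", g1)
    v <- env[[key]]
    if (is.null(v)) stop("no similarity stored for pair ", g1, ", ", g2)
    v
  }
}

#' @rdname sim_from_table
#' @param rank_matrix a `rank_matrix`.
#' @param measure measure whose RankSim column to use.
#' @export
sim_from_measure <- function(rank_matrix, measure) {
  if (!measure %in% rank_matrix$measures) stop("unknown measure: ", measure)
  tab <- cbind(rank_matrix$pairs, sim = rank_matrix$ranksim[, measure])
  sim_from_table(tab)
}

#' @rdname sim_from_table
#' @param groups seed groups aligned with `rank_matrix$pairs`.
#' @param ps a `parameter_set`.
#' @export
sim_from_model <- function(rank_matrix, groups, ps) {
  tab <- cbind(rank_matrix$pairs,
               sim = integrate_all(rank_matrix, groups, ps))
  sim_from_table(tab)
}

#' Per-gene inter/intra group separation (log ratio)
#'
#' For a gene `g` in group `ei` and a disjoint group `ej`, compares the
#' summed smoothed distances `1 - sim + c_smooth` from `g` to the genes of
#' `ej` (inter) against those to the other genes of `ei` (intra):
#' `diff = ln[|I| * sum_inter] - ln[|J| * sum_intra]`, with
#' `I = ei \ {g}` and `J = ej`. Positive values mean `g` is closer to its
#' own group than to the other group.
#'
#' @param g a gene in `grouping$groups[[ei]]`.
#' @param ei,ej group ids; the groups must be disjoint and `ei` must have
#'   at least 2 genes.
#' @param sim a similarity function (see [sim_from_table()]).
#' @param grouping an `ec_grouping`.
#' @param c_smooth Laplacian smoothing constant (> 0, default 0.01).
#' @return a single numeric log fold change.
#' @export
diff_gene <- function(g, ei, ej, sim, grouping, c_smooth = 0.01) {
  stopifnot(c_smooth > 0)
  Gi <- grouping$groups[[ei]]; Gj <- grouping$groups[[ej]]
  if (is.null(Gi) || is.null(Gj)) stop("unknown group id")
  if (!g %in% Gi) stop("gene ", g, " not in group ", ei)
  if (length(intersect(Gi, Gj))) stop("groups ", ei, " and ", ej,
                                      " share genes")
  I <- setdiff(Gi, g)
  if (!length(I)) stop("group ", ei, " has no gene other than ", g)
  inter <- sum(vapply(Gj, function(gp) 1 - sim(g, gp) + c_smooth, 0))
  intra <- sum(vapply(I, function(gs) 1 - sim(g, gs) + c_smooth, 0))
  log(length(I) * inter) - log(length(Gj) * intra)
}

#' Log fold change of one group against all disjoint groups
#'
#' `LogFC(ei)` averages [diff_gene()] over every gene of `ei` and every
#' group `ej` sharing no gene with `ei`, scaling each term by the inner
#' divisor (the size of `ej` by default; a `divisor = "ei"` variant is
#' provided) and normalizing by the number of disjoint groups.
#'
#' @inheritParams diff_gene
#' @param divisor which group size scales the inner sum (`"ej"`, the
#'   literal definition, or `"ei"`).
#' @return numeric LogFC, or `NA` (with a message) when no disjoint group
#'   exists.
#' @export
logfc <- function(ei, grouping, sim, c_smooth = 0.01,
                  divisor = c("ej", "ei")) {
  divisor <- match.arg(divisor)
  Gi <- grouping$groups[[ei]]
  if (is.null(Gi)) stop("unknown group id: ", ei)
  others <- setdiff(names(grouping$groups), ei)
  disjoint <- others[vapply(others, function(ej) {
    !length(intersect(Gi, grouping$groups[[ej]]))
  }, TRUE)]
  if (!length(disjoint)) {
    message("group ", ei, " overlaps every other group; LogFC undefined")
    return(NA_real_)
  }
  total <- 0
  for (ej in disjoint) {
    d <- if (divisor == "ej") length(grouping$groups[[ej]]) else length(Gi)
    for (g in Gi) {
      total <- total + diff_gene(g, ei, ej, sim, grouping, c_smooth) / d
    }
  }
  total / length(disjoint)
}

#' Mean LogFC over all groups (the training objective)
#'
#' @inheritParams logfc
#' @return mean of [logfc()] over all groups with a defined value.
#' @export
optf <- function(grouping, sim, c_smooth = 0.01, divisor = c("ej", "ei")) {
  divisor <- match.arg(divisor)
  vals <- vapply(names(grouping$groups), logfc, 0, grouping = grouping,
                 sim = sim, c_smooth = c_smooth, divisor = divisor)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("LogFC undefined for every group")
  mean(vals)
}

#' Per-group LogFC report with summary quartiles
#'
#' @inheritParams logfc
#' @return data frame with columns `group`, `logfc`; the attribute
#'   `summary` carries the 25th, 50th and 75th percentiles over groups.
#' @export
logfc_report <- function(grouping, sim, c_smooth = 0.01,
                         divisor = c("ej", "ei")) {
  divisor <- match.arg(divisor)
  vals <- vapply(names(grouping$groups), logfc, 0, grouping = grouping,
                 sim = sim, c_smooth = c_smooth, divisor = divisor)
  df <- data.frame(group = names(grouping$groups), logfc = unname(vals))
  attr(df, "summary") <- quantile(vals, c(0.25, 0.5, 0.75), na.rm = TRUE)
  df
}
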