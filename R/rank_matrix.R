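#' Rank-normalize raw similarity matrices
#'
#' For each measure the gene pairs are sorted in increasing order of raw
#' score and assigned 1-based ranks (ties get the average of the tied
#' positions). The rank of pair `(g1, g2)` under measure `m` is rescaled to
#' `RankSim(g1 g2, m) = 2 rank / |GS|^2`, where `|GS|` is the number of
#' genes in the set — so ranked scores from measures on arbitrary raw
#' scales become comparable. Note the divisor is the squared gene count,
#' not the pair count, so the maximum attainable value is
#' `(|GS| - 1) / |GS| < 1`.
#'
#' @param matrices named list of `sim_matrix` objects over the same gene
#'   set (as from [similarity_matrices()]).
#' @return a `rank_matrix`: list with `pairs` (data frame `gene1`,
#'   `gene2`), `measures`, `rank` and `ranksim` (pair-by-measure numeric
#'   matrices), `genes`, and `gs_size`.
#' @export
build_rank_matrix <- function(matrices) {
  if (!length(matrices)) stop("need at least one similarity matrix")
  genes <- attr(matrices[[1L]], "genes")
  for (m in matrices) {
    if (!identical(attr(m, "genes"), genes)) {
      d <- c(setdiff(attr(m, "genes"), genes), setdiff(genes, attr(m, "genes")))
      stop("matrices cover different gene sets; difference: ",
           paste(head(d, 5), collapse = ", "))
    }
  }
  measure_names <- vapply(matrices, attr, "", "measure")
  if (is.null(names(matrices))) names(matrices) <- measure_names
  pairs <- as.data.frame(matrices[[1L]])[, c("gene1", "gene2")]
  P <- nrow(pairs)
  n <- length(genes)
  rk <- matrix(NA_real_, P, length(matrices),
               dimnames = list(NULL, measure_names))
  for (j in seq_along(matrices)) {
    df <- as.data.frame(matrices[[j]])
    if (!identical(df$gene1, pairs$gene1) ||
        !identical(df$gene2, pairs$gene2)) {
      stop("pair ordering mismatch between matrices")
    }
    rk[, j] <- rank(df$score, ties.method = "average")
  }
  structure(list(pairs = pairs, measures = unname(measure_names),
                 rank = rk, ranksim = 2 * rk / n^2,
                 genes = genes, gs_size = n),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> genes=%d pairs=%d measures=%s\n",
              x$gs_size, nrow(x$pairs), paste(x$measures, collapse = ",")))
  invisible(x)
}

#' Write a rank matrix as TSV
#'
#' Columns `gene1`, `gene2`, then one RankSim column per measure.
#'
#' @param x a `rank_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rank_matrix <- function(x, path) {
  df <- cbind(x$pairs, as.data.frame(x$ranksim))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
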