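#' Select the seed measure group for one gene pair
#'
#' Given the RankSim values of all candidate measures for a single gene
#' pair, finds the largest set of measures that agree: among all contiguous
#' runs of the values sorted on the number axis whose diameter (max minus
#' min) is at most `d_prime`, the run with the most members is selected
#' (ties broken by smaller diameter, then by containing the median value,
#' then by the lower run). On a line this exhaustive window search selects
#' the same core as agglomerative single-linkage grouping with a gradually
#' reduced distance threshold, but is deterministic and order-free. If the
#' best run has fewer than `min_size` members, no qualifying group exists
#' and all measures are kept (`fallback = TRUE`, type `"mix"`).
#'
#' @param values named numeric vector of RankSim values in `[0, 1]`, one
#'   per candidate measure.
#' @param min_size minimum seed group size (default 3).
#' @param d_prime maximum within-group spread (default 0.10).
#' @return a `seed_group`: list with `members` (measure names, in
#'   ascending RankSim order), `group_type` (`"high"`, `"low"` or
#'   `"mix"`), `fallback`, `removed_low`, `removed_high`.
#' @export
select_seed_group <- function(values, min_size = 3L, d_prime = 0.10) {
  if (!length(values)) stop("empty RankSim vector")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by measure")
  }
  stopifnot(min_size >= 1L, d_prime > 0, d_prime < 1)
  ord <- order(values, names(values))
  v <- unname(values[ord])
  nm <- names(values)[ord]
  n <- length(v)
  med <- stats::median(v)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      diam <- v[j] - v[i]
      if (diam > d_prime + 1e-12) break
      cand <- list(size = j - i + 1L, diam = diam,
                   has_med = v[i] <= med && med <= v[j], i = i, j = j)
      if (is.null(best) ||
          cand$size > best$size ||
          (cand$size == best$size && cand$diam < best$diam) ||
          (cand$size == best$size && cand$diam == best$diam &&
             cand$has_med > best$has_med) ||
          (cand$size == best$size && cand$diam == best$diam &&
             cand$has_med == best$has_med && cand$i < best$i)) {
        best <- cand
      }
    }
  }
  if (best$size < min_size) {
    grp <- structure(list(members = nm, fallback = TRUE,
                          removed_low = 0L, removed_high = 0L),
                     class = "seed_group")
  } else {
    grp <- structure(list(members = nm[best$i:best$j],
                          fallback = FALSE,
                          removed_low = best$i - 1L,
                          removed_high = n - best$j),
                     class = "seed_group")
  }
  grp$group_type <- label_group_type(grp)
  grp
}

#' Label a seed group as high, low or mix
#'
#' The label records where the isolated (non-seed) measures sit on the
#' number axis: more isolated measures below the group than above it means
#' the group itself occupies the high end (`"high"`), and vice versa;
#' equal counts — including fallback groups with no isolated measures —
#' give `"mix"`.
#'
#' @param group a `seed_group` (the `group_type` field may be absent).
#' @return `"high"`, `"low"` or `"mix"`.
#' @export
label_group_type <- function(group) {
  if (group$removed_low > group$removed_high) "high"
  else if (group$removed_high > group$removed_low) "low"
  else "mix"
}

#' Seed groups for every pair of a rank matrix
#'
#' @param rank_matrix a `rank_matrix`.
#' @param min_size,d_prime see [select_seed_group()].
#' @return list of `seed_group` objects, aligned with `rank_matrix$pairs`.
#' @export
seed_groups <- function(rank_matrix, min_size = 3L, d_prime = 0.10) {
  lapply(seq_len(nrow(rank_matrix$pairs)), function(k) {
    select_seed_group(rank_matrix$ranksim[k, ], min_size, d_prime)
  })
}

#' Write per-pair seed groups as TSV (audit dump)
#'
#' @param rank_matrix the `rank_matrix` the groups were derived from.
#' @param groups list of `seed_group` objects from [seed_groups()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_seed_groups <- function(rank_matrix, groups, path) {
  df <- data.frame(
    gene1 = rank_matrix$pairs$gene1,
    gene2 = rank_matrix$pairs$gene2,
    type = vapply(groups, `[[`, "", "group_type"),
    fallback = vapply(groups, `[[`, TRUE, "fallback"),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"), ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
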