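# synthetic rank matrix with ranksim values set directly; bypasses the
# measure pipeline so search behaviour can be controlled precisely
mk_rank_matrix <- function(genes, measures, ranksim) {
  pairs <- integosim:::.canonical_pairs(genes)
  structure(list(pairs = pairs, measures = measures,
                 rank = ranksim * length(genes)^2 / 2, ranksim = ranksim,
                 genes = sort(genes), gs_size = length(genes)),
            class = "rank_matrix")
}

# two groups of 3; one informative measure (separates the groups), the
# rest uniform noise
informative_fixture <- function(n_noise = 3L, seed = 1L) {
  set.seed(seed)
  genes <- c(paste0("A", 1:3), paste0("B", 1:3))
  pairs <- integosim:::.canonical_pairs(genes)
  intra <- substr(pairs$gene1, 1, 1) == substr(pairs$gene2, 1, 1)
  measures <- c("inf", paste0("noise", seq_len(n_noise)))
  rs <- matrix(runif(nrow(pairs) * length(measures), 0.05, 0.95),
               ncol = length(measures), dimnames = list(NULL, measures))
  rs[, "inf"] <- ifelse(intra, runif(sum(intra), 0.75, 0.9),
                        runif(sum(!intra), 0.1, 0.25))
  grouping <- ec_grouping(list(EA = paste0("A", 1:3), EB = paste0("B", 1:3)),
                          min_size = 3L)
  rm_ <- mk_rank_matrix(genes, measures, rs)
  list(rm = rm_, sg = seed_groups(rm_), grouping = grouping)
}
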