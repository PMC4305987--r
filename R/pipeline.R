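#' Train the integrative similarity model on a grouped gene set
#'
#' Runs the full training path: raw similarity matrices for every
#' candidate measure over the genes of the training grouping, rank
#' normalization within that gene set, per-pair seed-group selection and
#' tabu-search estimation of the addition-model parameters against the
#' LogFC separation objective.
#'
#' @param dag an `ontology_dag`.
#' @param corpus an `annotation_corpus` over `dag`.
#' @param grouping an `ec_grouping` (EC numbers or pathways) whose genes
#'   are the training set.
#' @param measures candidate measures to integrate.
#' @param include_fake add the low-quality fake measure (requires
#'   `"resnik"` among `measures`).
#' @param seed_min_size,d_prime seed-group selection thresholds.
#' @param config a [train_config()].
#' @param out_dir optional directory; when given, persists
#'   `parameters.json`, `logfc_report.tsv`, `seed_groups.tsv` and
#'   `training_log.tsv`.
#' @return list with `params` (trained `parameter_set`), `optf` (its
#'   objective on the training set), `report` (per-group LogFC of the
#'   trained model), `rank_matrix`, `seed_groups`, `matrices`, `ic`.
#' @export
run_train <- function(dag, corpus, grouping,
                      measures = candidate_measures(),
                      include_fake = FALSE, seed_min_size = 3L,
                      d_prime = 0.10, config = train_config(),
                      out_dir = NULL) {
  gs <- grouping_genes(grouping)
  ic_tab <- compute_ic(dag, corpus)
  mats <- similarity_matrices(corpus, dag, ic_tab, gs, measures)
  if (include_fake) {
    if (!"resnik" %in% names(mats)) stop("fake measure needs resnik scores")
    mats$fake <- fake_measure(mats$resnik, grouping, seed = config$seed)
  }
  rm_ <- build_rank_matrix(mats)
  sg <- seed_groups(rm_, seed_min_size, d_prime)
  ps <- tabu_train(rm_, sg, grouping, config)
  simfun <- sim_from_model(rm_, sg, ps)
  report <- logfc_report(grouping, simfun, config$c_smooth, config$divisor)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parameter_set(ps, file.path(out_dir, "parameters.json"))
    write.table(report, file.path(out_dir, "logfc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_seed_groups(rm_, sg, file.path(out_dir, "seed_groups.tsv"))
    write.table(attr(ps, "trace"), file.path(out_dir, "training_log.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(params = ps, optf = attr(ps, "best_optf"), report = report,
       rank_matrix = rm_, seed_groups = sg, matrices = mats, ic = ic_tab)
}

#' Score a gene set with a trained model
#'
#' RankSim values are computed within the input gene set (scores are
#' relative to the query set, mirroring the training protocol), seed
#' groups are selected per pair and the trained addition model is applied.
#'
#' @inheritParams run_train
#' @param ps a trained `parameter_set`.
#' @param gene_set genes to score.
#' @param missing_gene `"skip"` (drop unannotated genes with a message) or
#'   `"error"`.
#' @return data frame with columns `gene1`, `gene2`, `sim`, `group_type`.
#' @export
run_score <- function(dag, corpus, ps, gene_set,
                      measures = candidate_measures(),
                      seed_min_size = 3L, d_prime = 0.10,
                      missing_gene = c("skip", "error")) {
  missing_gene <- match.arg(missing_gene)
  absent <- setdiff(gene_set, corpus$genes)
  if (length(absent)) {
    msg <- paste0("unannotated gene(s): ", paste(absent, collapse = ", "))
    if (missing_gene == "error") stop(msg)
    message(msg, " (skipped)")
    gene_set <- setdiff(gene_set, absent)
  }
  if (length(gene_set) < 2L) stop("fewer than 2 scorable genes")
  ic_tab <- compute_ic(dag, corpus)
  mats <- similarity_matrices(corpus, dag, ic_tab, gene_set, measures)
  rm_ <- build_rank_matrix(mats)
  sg <- seed_groups(rm_, seed_min_size, d_prime)
  data.frame(rm_$pairs,
             sim = integrate_all(rm_, sg, ps),
             group_type = vapply(sg, `[[`, "", "group_type"))
}

#' Robustness of the integration to measure removal
#'
#' Retrains and re-evaluates the model after removing candidate measures,
#' either cumulatively in the given order or one at a time
#' (leave-one-out). Stops early (with a partial report) once fewer than
#' `seed_min_size` measures remain.
#'
#' @param matrices named list of `sim_matrix` objects (all candidate
#'   measures over the training gene set).
#' @param grouping the training `ec_grouping`.
#' @param removal_order measures to remove, in order (cumulative mode);
#'   defaults to all measures for leave-one-out.
#' @param mode `"cumulative"` or `"leave_one_out"`.
#' @param seed_min_size,d_prime seed-group selection thresholds.
#' @param config a [train_config()].
#' @return data frame with one row per step: `step`, `removed`,
#'   `n_measures`, `optf`, `logfc_q25`, `logfc_median`, `logfc_q75`.
#' @export
run_robustness <- function(matrices, grouping, removal_order = NULL,
                           mode = c("cumulative", "leave_one_out"),
                           seed_min_size = 3L, d_prime = 0.10,
                           config = train_config()) {
  mode <- match.arg(mode)
  all_measures <- names(matrices)
  if (is.null(removal_order)) removal_order <- all_measures
  stopifnot(all(removal_order %in% all_measures))
  eval_subset <- function(remaining) {
    rm_ <- build_rank_matrix(matrices[remaining])
    sg <- seed_groups(rm_, seed_min_size, d_prime)
    ps <- tabu_train(rm_, sg, grouping, config)
    rep_ <- logfc_report(grouping, sim_from_model(rm_, sg, ps),
                         config$c_smooth, config$divisor)
    q <- attr(rep_, "summary")
    data.frame(n_measures = length(remaining),
               optf = attr(ps, "best_optf"),
               logfc_q25 = q[[1L]], logfc_median = q[[2L]],
               logfc_q75 = q[[3L]])
  }
  rows <- list()
  if (mode == "cumulative") {
    removed <- character()
    for (s in 0:length(removal_order)) {
      if (s > 0L) removed <- c(removed, removal_order[s])
      remaining <- setdiff(all_measures, removed)
      if (length(remaining) < max(2L, seed_min_size)) {
        message("stopping at step ", s, ": only ", length(remaining),
                " measure(s) left")
        break
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(step = s,
                         removed = paste(removed, collapse = ";")),
              eval_subset(remaining))
    }
  } else {
    for (m in removal_order) {
      remaining <- setdiff(all_measures, m)
      if (length(remaining) < max(2L, seed_min_size)) {
        message("skipping leave-one-out of ", m, ": too few measures left")
        next
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(step = m, removed = m), eval_subset(remaining))
    }
  }
  do.call(rbind, rows)
}

#' Export a functional association network
#'
#' Keeps the gene pairs whose integrated similarity reaches the
#' threshold; the edge list is the input for association-map construction.
#'
#' @param scores data frame from [run_score()] (columns `gene1`, `gene2`,
#'   `sim`).
#' @param threshold similarity cutoff in `[0, 1]`.
#' @param path optional TSV output path.
#' @return data frame of edges `gene1`, `gene2`, `sim`.
#' @export
export_network <- function(scores, threshold, path = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  edges <- scores[scores$sim >= threshold, c("gene1", "gene2", "sim")]
  rownames(edges) <- NULL
  message(length(unique(c(edges$gene1, edges$gene2))), " nodes, ",
          nrow(edges), " edges at threshold ", threshold)
  if (!is.null(path)) {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  edges
}

#' Split a grouping into training and test groupings
#'
#' Randomly assigns a fraction of the groups to the test set (at least
#' one group on each side).
#'
#' @param grouping an `ec_grouping`.
#' @param test_fraction fraction of groups held out.
#' @param seed integer seed.
#' @return list with `train` and `test` `ec_grouping`s.
#' @export
cv_split <- function(grouping, test_fraction = 0.2, seed = 1L) {
  ids <- names(grouping$groups)
  n_test <- max(1L, round(test_fraction * length(ids)))
  if (n_test >= length(ids)) stop("test fraction leaves no training group")
  set.seed(seed)
  test_ids <- sort(sample(ids, n_test))
  list(train = ec_grouping(grouping$groups[setdiff(ids, test_ids)],
                           grouping$min_size),
       test = ec_grouping(grouping$groups[test_ids], grouping$min_size))
}

#' Cross-validated comparison against the averaging baseline
#'
#' Trains the addition model on the training split and evaluates both the
#' trained model and the plain averaging baseline — the unweighted mean of
#' all candidate measures' RankSim values, with no seed selection — on the
#' held-out split, scoring each within the test gene set as [run_score()]
#' does.
#'
#' @inheritParams run_train
#' @param test_fraction fraction of groups held out.
#' @param cv_seed seed for the group split.
#' @return list with `trained_optf`, `baseline_optf` (test-set objective
#'   values), `train_optf` and the `split`.
#' @export
run_cv <- function(dag, corpus, grouping,
                   measures = candidate_measures(),
                   include_fake = FALSE, seed_min_size = 3L, d_prime = 0.10,
                   config = train_config(), test_fraction = 0.2,
                   cv_seed = 1L) {
  split <- cv_split(grouping, test_fraction, cv_seed)
  fit <- run_train(dag, corpus, split$train, measures = measures,
                   include_fake = include_fake,
                   seed_min_size = seed_min_size, d_prime = d_prime,
                   config = config)
  ic_tab <- fit$ic
  test_genes <- grouping_genes(split$test)
  mats <- similarity_matrices(corpus, dag, ic_tab, test_genes, measures)
  if (include_fake) {
    mats$fake <- fake_measure(mats$resnik, split$test, seed = config$seed)
  }
  rm_ <- build_rank_matrix(mats)
  sg <- seed_groups(rm_, seed_min_size, d_prime)
  trained <- optf(split$test, sim_from_model(rm_, sg, fit$params),
                  config$c_smooth, config$divisor)
  avg_tab <- cbind(rm_$pairs, sim = rowMeans(rm_$ranksim))
  baseline <- optf(split$test, sim_from_table(avg_tab),
                   config$c_smooth, config$divisor)
  list(trained_optf = trained, baseline_optf = baseline,
       train_optf = fit$optf, split = split)
}
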