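#' Tabu search configuration
#'
#' @param step_sizes positive step sizes for the simplex mass transfers
#'   that generate neighborhood solutions.
#' @param tabu_capacity maximum number of solution fingerprints retained
#'   in the tabu list.
#' @param stability_patience stop optimizing a parameter block after this
#'   many consecutive moves without improving the best solution.
#' @param restarts number of independent random restarts; the best result
#'   over all restarts is returned.
#' @param max_cycles safety cap on outer high/low/mix cycles per restart.
#' @param c_smooth Laplacian smoothing constant of the objective.
#' @param divisor inner LogFC divisor, see [logfc()].
#' @param seed integer seed for the random initial solutions.
#' @return a `train_config` list.
#' @export
train_config <- function(step_sizes = c(0.05, 0.01), tabu_capacity = 50L,
                         stability_patience = 25L, restarts = 5L,
                         max_cycles = 10L, c_smooth = 0.01,
                         divisor = c("ej", "ei"), seed = 1L) {
  divisor <- match.arg(divisor)
  stopifnot(all(step_sizes > 0), restarts >= 1L, tabu_capacity >= 1L,
            stability_patience >= 0L, c_smooth > 0)
  structure(list(step_sizes = step_sizes, tabu_capacity = tabu_capacity,
                 stability_patience = stability_patience,
                 restarts = restarts, max_cycles = max_cycles,
                 c_smooth = c_smooth, divisor = divisor, seed = seed),
            class = "train_config")
}

.theta_fingerprint <- function(theta) {
  paste(sprintf("%.4f", unlist(theta, use.names = FALSE)), collapse = ",")
}

# Neighborhood on one simplex block: every ordered (donor, receiver) pair
# and step size, transferring min(step, donor mass); empty donors skipped.
.neighborhood_theta <- function(v, step_sizes) {
  K <- length(v)
  cols <- list()
  for (d in seq_len(K)) {
    if (v[d] <= 0) next
    for (r in seq_len(K)) {
      if (r == d) next
      for (s in step_sizes) {
        amt <- min(s, v[d])
        nv <- v
        nv[d] <- nv[d] - amt
        nv[r] <- nv[r] + amt
        cols[[length(cols) + 1L]] <- nv
      }
    }
  }
  if (!length(cols)) return(matrix(numeric(), nrow = K, ncol = 0))
  M <- do.call(cbind, cols)
  M[, !duplicated(apply(round(M, 10), 2, paste, collapse = ",")),
    drop = FALSE]
}

#' Neighborhood of a parameter set for one group type
#'
#' Generates every solution obtainable by moving probability mass of size
#' `min(step, donor)` from one parameter of the given type to another;
#' parameters of the other types are held fixed, so every neighbor still
#' satisfies the per-type sum-to-one constraint.
#'
#' @param ps a `parameter_set`.
#' @param type `"high"`, `"low"` or `"mix"`.
#' @param step_sizes positive transfer sizes.
#' @return list of `parameter_set` neighbors.
#' @export
neighborhood <- function(ps, type = c("high", "low", "mix"),
                         step_sizes = c(0.05, 0.01)) {
  type <- match.arg(type)
  measures <- names(ps$high$weights)
  theta <- .ps_to_theta(ps, measures)
  M <- .neighborhood_theta(theta[[type]], step_sizes)
  lapply(seq_len(ncol(M)), function(j) {
    th <- theta
    th[[type]] <- M[, j]
    .theta_to_ps(th, measures)
  })
}

#' Precompute the LogFC objective over a fixed training set
#'
#' Freezes everything that does not change during training — RankSim
#' values, per-pair seed groups, the addition-model design matrix and the
#' sparse gene-pair aggregation maps of the grouping — so that the
#' objective of a candidate parameter set (or of a whole batch of
#' neighbors) is a handful of matrix products.
#'
#' @param rank_matrix a `rank_matrix` covering all grouping genes.
#' @param groups seed groups aligned with the rank matrix pairs.
#' @param grouping an `ec_grouping`; needs at least one disjoint group
#'   pair.
#' @param c_smooth smoothing constant.
#' @param divisor inner LogFC divisor, see [logfc()].
#' @return an `objective_context`.
#' @export
build_objective_context <- function(rank_matrix, groups, grouping,
                                    c_smooth = 0.01,
                                    divisor = c("ej", "ei")) {
  divisor <- match.arg(divisor)
  missing <- setdiff(grouping_genes(grouping), rank_matrix$genes)
  if (length(missing)) {
    stop("grouping gene(s) absent from rank matrix: ",
         paste(head(missing, 5), collapse = ", "))
  }
  measures <- rank_matrix$measures
  M <- length(measures)
  P <- nrow(rank_matrix$pairs)
  pair_key <- function(a, b) ifelse(a < b, paste0(a, "\r", b),
                                    paste0(b, "\r", a))
  pair_index <- setNames(seq_len(P),
                         pair_key(rank_matrix$pairs$gene1,
                                  rank_matrix$pairs$gene2))
  # design matrix: masked member RankSims plus max/min/mean of members
  D <- matrix(0, P, M + 3L)
  type <- character(P)
  for (k in seq_len(P)) {
    g <- groups[[k]]
    V <- rank_matrix$ranksim[k, g$members]
    D[k, match(g$members, measures)] <- V
    D[k, M + 1L] <- max(V)
    D[k, M + 2L] <- min(V)
    D[k, M + 3L] <- mean(V)
    type[k] <- g$group_type
  }
  gids <- names(grouping$groups)
  disjoint <- lapply(gids, function(ei) {
    Gi <- grouping$groups[[ei]]
    gids[vapply(gids, function(ej) {
      ej != ei && !length(intersect(Gi, grouping$groups[[ej]]))
    }, TRUE)]
  })
  names(disjoint) <- gids
  retained <- gids[lengths(disjoint) > 0L]
  if (length(retained) < length(gids)) {
    message(length(gids) - length(retained),
            " group(s) overlap all others; excluded from the objective")
  }
  if (!length(retained)) stop("no disjoint pair of groups in the grouping")
  # intra rows: one per (ei, g); inter rows: one per (ei, g, ej)
  intra_i <- integer(); intra_j <- integer()
  inter_i <- integer(); inter_j <- integer()
  n_intra <- 0L
  inter_nI <- numeric(); inter_nJ <- numeric(); inter_coef <- numeric()
  inter_map <- integer()
  intra_key <- character()
  for (ei in retained) {
    Gi <- grouping$groups[[ei]]
    if (length(Gi) < 2L) stop("retained group ", ei, " has fewer than 2 genes")
    nEC <- length(disjoint[[ei]])
    for (g in Gi) {
      n_intra <- n_intra + 1L
      others <- setdiff(Gi, g)
      intra_i <- c(intra_i, rep(n_intra, length(others)))
      intra_j <- c(intra_j, unname(pair_index[pair_key(g, others)]))
      intra_key <- c(intra_key, paste0(ei, "\r", g))
      for (ej in disjoint[[ei]]) {
        Gj <- grouping$groups[[ej]]
        r <- length(inter_nI) + 1L
        inter_i <- c(inter_i, rep(r, length(Gj)))
        inter_j <- c(inter_j, unname(pair_index[pair_key(g, Gj)]))
        inter_nI <- c(inter_nI, length(others))
        inter_nJ <- c(inter_nJ, length(Gj))
        div <- if (divisor == "ej") length(Gj) else length(Gi)
        inter_coef <- c(inter_coef,
                        1 / (length(retained) * nEC * div))
        inter_map <- c(inter_map, n_intra)
      }
    }
  }
  Mintra <- Matrix::sparseMatrix(i = intra_i, j = intra_j, x = 1,
                                 dims = c(n_intra, P))
  Minter <- Matrix::sparseMatrix(i = inter_i, j = inter_j, x = 1,
                                 dims = c(length(inter_nI), P))
  type_idx <- lapply(setNames(.GROUP_TYPES, .GROUP_TYPES),
                     function(t) which(type == t))
  structure(list(D = D, type_idx = type_idx, measures = measures,
                 Mintra = Mintra, Minter = Minter,
                 inter_nI = inter_nI, inter_nJ = inter_nJ,
                 inter_coef = inter_coef, inter_map = inter_map,
                 c_smooth = c_smooth, n_pairs = P,
                 n_groups = length(retained)),
            class = "objective_context")
}

# integrated similarity vector for flat per-type theta vectors
.ctx_sim <- function(ctx, theta) {
  sim <- numeric(ctx$n_pairs)
  for (t in .GROUP_TYPES) {
    idx <- ctx$type_idx[[t]]
    if (length(idx)) sim[idx] <- ctx$D[idx, , drop = FALSE] %*% theta[[t]]
  }
  sim
}

.ctx_optf_sim <- function(ctx, sim) {
  d <- 1 - sim + ctx$c_smooth
  Si <- as.numeric(ctx$Minter %*% d)
  St <- as.numeric(ctx$Mintra %*% d)
  sum(ctx$inter_coef *
        (log(ctx$inter_nI * Si) - log(ctx$inter_nJ * St[ctx$inter_map])))
}

#' Objective value of a parameter set under a precomputed context
#'
#' Equals [optf()] evaluated on the integrated similarity of the same
#' rank matrix, seed groups and grouping the context was built from.
#'
#' @param ctx an `objective_context`.
#' @param ps a `parameter_set` over the context's measures.
#' @return a single numeric objective value (mean LogFC).
#' @export
context_optf <- function(ctx, ps) {
  validate_parameter_set(ps)
  .ctx_optf_sim(ctx, .ctx_sim(ctx, .ps_to_theta(ps, ctx$measures)))
}

# Batched objective for all columns of Theta replacing block `t`;
# the other blocks' contribution to the distance vector is fixed.
.ctx_optf_many <- function(ctx, theta, t, Theta) {
  sim_base <- .ctx_sim(ctx, theta)
  d_base <- 1 - sim_base + ctx$c_smooth
  idx <- ctx$type_idx[[t]]
  if (!length(idx)) {
    v <- .ctx_optf_sim(ctx, sim_base)
    return(rep(v, ncol(Theta)))
  }
  d_other <- d_base
  d_other[idx] <- 0
  Si_other <- as.numeric(ctx$Minter %*% d_other)
  St_other <- as.numeric(ctx$Mintra %*% d_other)
  SimT <- ctx$D[idx, , drop = FALSE] %*% Theta            # |idx| x N
  Dt <- 1 - SimT + ctx$c_smooth
  Si <- as.matrix(ctx$Minter[, idx, drop = FALSE] %*% Dt) + Si_other
  St <- as.matrix(ctx$Mintra[, idx, drop = FALSE] %*% Dt) + St_other
  diffs <- log(ctx$inter_nI * Si) -
    log(ctx$inter_nJ * St[ctx$inter_map, , drop = FALSE])
  as.numeric(crossprod(ctx$inter_coef, diffs))
}

#' Fit the addition model by tabu search
#'
#' Maximizes the mean LogFC separation objective over the per-type simplex
#' parameters of the addition model. Each restart draws a random initial
#' point on every type's simplex (symmetric Dirichlet), then optimizes one
#' type block at a time (high, then low, then mix, cycling while any block
#' still improves). Moves transfer mass between two parameters; the best
#' neighbor is accepted when it improves the best-so-far solution
#' (aspiration), otherwise the best non-tabu neighbor is taken and the
#' move recorded in the bounded tabu list. A block stops after
#' `stability_patience` consecutive moves without a new best. The best
#' solution over all restarts is returned.
#'
#' @param rank_matrix a `rank_matrix` covering all grouping genes.
#' @param groups seed groups aligned with the rank matrix pairs.
#' @param grouping an `ec_grouping` with at least two disjoint groups.
#' @param config a [train_config()].
#' @return the best `parameter_set` found, with attributes `best_optf`
#'   (its objective value) and `trace` (one row per move: restart, cycle,
#'   type, iteration, objective of the accepted move and of the best
#'   solution, aspiration/tabu flags).
#' @export
tabu_train <- function(rank_matrix, groups, grouping,
                       config = train_config()) {
  ctx <- build_objective_context(rank_matrix, groups, grouping,
                                 c_smooth = config$c_smooth,
                                 divisor = config$divisor)
  measures <- ctx$measures
  K <- length(measures) + 3L
  set.seed(config$seed)
  overall_best <- NULL
  overall_val <- -Inf
  trace <- list()
  for (r in seq_len(config$restarts)) {
    theta <- lapply(setNames(.GROUP_TYPES, .GROUP_TYPES), function(t) {
      x <- rgamma(K, 1)
      x / sum(x)
    })
    bs <- theta
    bs_val <- .ctx_optf_sim(ctx, .ctx_sim(ctx, theta))
    TL <- character()
    push_tl <- function(fp) {
      TL <<- c(TL, fp)
      if (length(TL) > config$tabu_capacity) {
        TL <<- TL[-seq_len(length(TL) - config$tabu_capacity)]
      }
    }
    push_tl(.theta_fingerprint(theta))
    iter <- 0L
    for (cycle in seq_len(config$max_cycles)) {
      cycle_start_val <- bs_val
      for (t in .GROUP_TYPES) {
        if (!length(ctx$type_idx[[t]])) next
        no_improve <- 0L
        repeat {
          if (no_improve >= config$stability_patience) break
          NB <- .neighborhood_theta(theta[[t]], config$step_sizes)
          if (!ncol(NB)) break
          vals <- .ctx_optf_many(ctx, theta, t, NB)
          fps <- vapply(seq_len(ncol(NB)), function(j) {
            th <- theta
            th[[t]] <- NB[, j]
            .theta_fingerprint(th)
          }, "")
          ord <- order(-vals, fps)
          accepted <- FALSE
          for (j in ord) {
            fp <- fps[j]
            if (vals[j] > bs_val) {        # aspiration: always accept
              theta[[t]] <- NB[, j]
              bs <- theta
              bs_val <- vals[j]
              push_tl(fp)
              no_improve <- 0L
              accepted <- TRUE
            } else if (!fp %in% TL) {      # non-improving, non-tabu move
              theta[[t]] <- NB[, j]
              push_tl(fp)
              no_improve <- no_improve + 1L
              accepted <- TRUE
            } else {
              next                          # tabu: delete from neighborhood
            }
            iter <- iter + 1L
            trace[[length(trace) + 1L]] <- data.frame(
              restart = r, cycle = cycle, type = t, iteration = iter,
              optf_move = vals[j], optf_best = bs_val,
              tabu_hit = fp %in% head(TL, -1L))
            break
          }
          if (!accepted) break
        }
      }
      if (bs_val <= cycle_start_val) break
      theta <- bs   # continue each new cycle from the best solution
    }
    if (bs_val > overall_val) {
      overall_val <- bs_val
      overall_best <- bs
    }
  }
  ps <- .theta_to_ps(overall_best, measures)
  attr(ps, "best_optf") <- overall_val
  attr(ps, "trace") <- do.call(rbind, trace)
  ps
}
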