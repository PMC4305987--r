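.GROUP_TYPES <- c("high", "low", "mix")

#' Construct and validate a parameter set for the addition model
#'
#' One parameter block per seed-group type (`high`, `low`, `mix`). Each
#' block carries one weight per candidate measure plus the coefficients
#' `alpha`, `beta`, `gamma` of the maximum, minimum and average of the
#' seed RankSim values. All parameters are non-negative and each block
#' sums to 1, so the integrated score is a sub-convex combination of
#' values in `[0, 1]`.
#'
#' @param high,low,mix lists with fields `weights` (named numeric over the
#'   candidate measures), `alpha`, `beta`, `gamma`.
#' @return a `parameter_set`.
#' @export
parameter_set <- function(high, low, mix) {
  ps <- structure(list(high = high, low = low, mix = mix),
                  class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' @rdname parameter_set
#' @param ps a `parameter_set` to validate.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  ref <- sort(names(ps$high$weights))
  for (t in .GROUP_TYPES) {
    b <- ps[[t]]
    vals <- c(b$weights, b$alpha, b$beta, b$gamma)
    if (any(!is.finite(vals))) stop("non-finite parameter in type ", t)
    if (any(vals < -1e-12)) stop("negative parameter in type ", t)
    if (abs(sum(vals) - 1) > 1e-9) {
      stop("parameters of type ", t, " sum to ", format(sum(vals)),
           ", expected 1")
    }
    if (!identical(sort(names(b$weights)), ref)) {
      stop("measure weight names differ across types")
    }
  }
  invisible(ps)
}

.flat_block <- function(weights, alpha, beta, gamma) {
  list(weights = weights, alpha = alpha, beta = beta, gamma = gamma)
}

#' Degenerate parameter sets (baselines)
#'
#' `mean_parameter_set()` puts all mass on the average of the seed
#' RankSims for every type (the plain averaging baseline);
#' `max_parameter_set()` and `min_parameter_set()` analogously.
#'
#' @param measures character vector of candidate measure names.
#' @return a `parameter_set`.
#' @export
mean_parameter_set <- function(measures) {
  w <- setNames(numeric(length(measures)), measures)
  b <- .flat_block(w, 0, 0, 1)
  parameter_set(b, b, b)
}

#' @rdname mean_parameter_set
#' @export
max_parameter_set <- function(measures) {
  w <- setNames(numeric(length(measures)), measures)
  b <- .flat_block(w, 1, 0, 0)
  parameter_set(b, b, b)
}

#' @rdname mean_parameter_set
#' @export
min_parameter_set <- function(measures) {
  w <- setNames(numeric(length(measures)), measures)
  b <- .flat_block(w, 0, 1, 0)
  parameter_set(b, b, b)
}

#' Integrate seed RankSim values into the final similarity
#'
#' Applies the type-conditional addition model: with `t` the pair's seed
#' group type and `V` the RankSim values of its seed measures,
#' `Sim = sum_i w[t][i] V_i + alpha[t] max(V) + beta[t] min(V) +
#' gamma[t] mean(V)`. Weights of candidate measures outside the pair's
#' seed group contribute nothing.
#'
#' @param pair_values named numeric vector: RankSim per candidate measure
#'   for one gene pair.
#' @param group the pair's `seed_group`.
#' @param ps a `parameter_set`.
#' @return a single numeric similarity in `[0, 1]`.
#' @export
integrate_pair <- function(pair_values, group, ps) {
  validate_parameter_set(ps)
  if (!all(group$members %in% names(pair_values))) {
    stop("pair_values missing seed member value(s)")
  }
  b <- ps[[group$group_type]]
  V <- pair_values[group$members]
  sum(b$weights[group$members] * V) +
    b$alpha * max(V) + b$beta * min(V) + b$gamma * mean(V)
}

#' Integrated similarity for every pair of a rank matrix
#'
#' @param rank_matrix a `rank_matrix`.
#' @param groups seed groups from [seed_groups()], aligned with the pairs.
#' @param ps a `parameter_set`.
#' @return numeric vector of similarities, one per pair.
#' @export
integrate_all <- function(rank_matrix, groups, ps) {
  validate_parameter_set(ps)
  vapply(seq_along(groups), function(k) {
    integrate_pair(rank_matrix$ranksim[k, ], groups[[k]], ps)
  }, 0)
}

#' Read / write a parameter set as JSON
#'
#' Layout: `{type: {measure_weights: {...}, alpha, beta, gamma}}`.
#'
#' @param ps a `parameter_set`.
#' @param path file path.
#' @return `path` invisibly, or the loaded `parameter_set`.
#' @export
write_parameter_set <- function(ps, path) {
  validate_parameter_set(ps)
  out <- lapply(ps[.GROUP_TYPES], function(b) {
    list(measure_weights = as.list(b$weights),
         alpha = b$alpha, beta = b$beta, gamma = b$gamma)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  raw <- jsonlite::read_json(path)
  blocks <- lapply(raw[.GROUP_TYPES], function(b) {
    .flat_block(unlist(b$measure_weights), b$alpha, b$beta, b$gamma)
  })
  parameter_set(blocks$high, blocks$low, blocks$mix)
}

# parameter_set <-> per-type flat theta vectors (weights..., alpha, beta,
# gamma) in a fixed measure order; internal plumbing for the tabu search.
.ps_to_theta <- function(ps, measures) {
  lapply(ps[.GROUP_TYPES], function(b) {
    unname(c(b$weights[measures], b$alpha, b$beta, b$gamma))
  })
}

.theta_to_ps <- function(theta, measures) {
  M <- length(measures)
  blocks <- lapply(theta, function(v) {
    .flat_block(setNames(v[seq_len(M)], measures),
                v[M + 1L], v[M + 2L], v[M + 3L])
  })
  parameter_set(blocks$high, blocks$low, blocks$mix)
}
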