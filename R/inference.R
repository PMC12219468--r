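#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties). If either
#' variable has zero rank variance the value is defined as 0 and flagged via
#' the `"degenerate"` attribute.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(rx, ry)
}

#' Partial Spearman correlation controlling for a covariate
#'
#' All three variables are midrank-transformed; the ranked `x` and `y` are
#' residualized on the ranked control by least squares and the Pearson
#' correlation of the residuals is returned. Used to test whether the
#' universality/brain-similarity association survives controlling for PC
#' rank. A constant control falls back to the plain Spearman correlation
#' (flagged).
#'
#' @param x,y,control numeric vectors of equal length >= 4.
#' @return partial rho in [-1, 1].
#' @export
partial_spearman <- function(x, y, control) {
  n <- length(x)
  stopifnot(length(y) == n, length(control) == n, n >= 4L)
  rz <- rank(control, ties.method = "average")
  if (stats::sd(rz) == 0) {
    return(structure(as.numeric(spearman_rho(x, y)), constant_control = TRUE))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  Z <- cbind(1, rz)
  ex <- stats::lm.fit(Z, rx)$residuals
  ey <- stats::lm.fit(Z, ry)$residuals
  # residuals that are numerically zero (variable identical to the control)
  # are degenerate, not correlatable floating-point noise
  tol <- 1e-8
  if (stats::sd(ex) <= tol * stats::sd(rx) ||
      stats::sd(ey) <= tol * stats::sd(ry)) {
    return(structure(0, degenerate = TRUE))
  }
  safe_pearson(ex, ey)
}

# recompute every dimension's universality with each target network's
# evaluation rows permuted by `perms[[t]]` (predictors untouched).
permuted_universality <- function(study, engines, grid, perms,
                                  method = "ridge") {
  nn <- study$config$n_networks
  out <- vector("list", nn)
  for (t in seq_len(nn)) {
    Yp <- study$targets[[t]]$Y[perms[[t]], , drop = FALSE]
    others <- setdiff(seq_len(nn), t)
    R <- vapply(others, function(p) {
      engine_score(engines$network[[p]], Yp, grid, method = method)$mean_r
    }, numeric(ncol(Yp)))
    R <- matrix(R, nrow = ncol(Yp))
    out[[t]] <- apply(R, 1L, stats::median)
  }
  unlist(out)
}

#' Image-label permutation test for the universality/brain-similarity link
#'
#' Each iteration draws one permutation of evaluation-stimulus indices per
#' target network and applies it to all of that network's dimension score
#' series (preserving within-network feature dependence), recomputes
#' universality for every dimension, and correlates the permuted
#' universality with the observed (unpermuted) brain similarity. The
#' one-sided p-value is add-one corrected:
#' `p = (1 + #{null rho >= observed rho}) / (n_perm + 1)`.
#'
#' @param study a `unidim_study`.
#' @param table the observed `score_table` from [score_dimensions()].
#' @param plan the [fold_plan()] used for scoring.
#' @param grid a [penalty_grid()].
#' @param n_perm number of permutations (>= 19; desk-scale default 199, the
#'   full-scale convention is 5000).
#' @param seed integer seed for the permutation stream.
#' @param engines optional precomputed [study_engines()] (reused across
#'   iterations — the predictor factorizations do not depend on the target).
#' @return a `permutation_result`: `p_value`, `observed_rho`, `null_rho`
#'   (length `n_perm`), `n_perm`, `seed`.
#' @export
permutation_test <- function(study, table, plan, grid = penalty_grid(),
                             n_perm = 199L, seed = 1L, engines = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 19L) {
    stop("n_perm must be >= 19 (p-value floor would exceed 0.05)",
         call. = FALSE)
  }
  stopifnot(inherits(study, "unidim_study"))
  if (is.null(engines)) engines <- study_engines(study, plan)
  obs <- as.numeric(spearman_rho(table$universality, table$brain_similarity))
  n_eval <- study$config$n_stim_eval
  nn <- study$config$n_networks
  null_rho <- with_component_seed(seed, "perm", {
    vapply(seq_len(n_perm), function(k) {
      perms <- lapply(seq_len(nn), function(t) sample.int(n_eval))
      u <- permuted_universality(study, engines, grid, perms)
      as.numeric(spearman_rho(u, table$brain_similarity))
    }, numeric(1))
  })
  p <- (1 + sum(null_rho >= obs)) / (n_perm + 1)
  structure(list(p_value = p, observed_rho = obs, null_rho = null_rho,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' Full inference on a scored study
#'
#' Spearman correlation between universality and brain similarity, the
#' partial Spearman controlling for PC rank, and the image-label permutation
#' p-value.
#'
#' @inheritParams permutation_test
#' @return an `inference_result`: `rho`, `rho_partial`, `p_value`,
#'   `null_rho`, `n_permutations`, `seed`.
#' @export
run_inference <- function(study, table, plan, grid = penalty_grid(),
                          n_perm = 199L, seed = 1L, engines = NULL) {
  rho <- as.numeric(spearman_rho(table$universality, table$brain_similarity))
  rho_partial <- as.numeric(partial_spearman(table$universality,
                                             table$brain_similarity,
                                             table$pc_rank))
  perm <- permutation_test(study, table, plan, grid, n_perm, seed, engines)
  structure(list(rho = rho, rho_partial = rho_partial,
                 p_value = perm$p_value, null_rho = perm$null_rho,
                 n_permutations = perm$n_perm, seed = seed),
            class = "inference_result")
}
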