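#' Assemble a scored-study object from a latent world
#'
#' Runs the feature-extraction stage for every network: global max pooling,
#' PC basis fitted on the fit split, evaluation-split projection, and the
#' raw pooled evaluation activations concatenated across layers (the
#' predictor representation — PCA is applied to target features only).
#' Subjects' standardized voxel matrices are generated on the evaluation
#' split.
#'
#' @param world a `latent_world`.
#' @return a `unidim_study`: per-network `bases` and `scores` (per layer),
#'   per-network `predictors` (eval stimuli x concatenated channels),
#'   `targets` (per network: eval stimuli x dims matrix of PC scores with an
#'   index data.frame of layer_id / pc_rank), `brains`, and the config.
#' @export
build_study <- function(world) {
  stopifnot(inherits(world, "latent_world"))
  config <- world$config
  idx <- split_indices(config)
  bases <- vector("list", config$n_networks)
  scores <- vector("list", config$n_networks)
  predictors <- vector("list", config$n_networks)
  targets <- vector("list", config$n_networks)
  for (i in seq_len(config$n_networks)) {
    aset <- pool_activation_set(make_network(world, i, "all"))
    bases[[i]] <- vector("list", config$n_layers)
    scores[[i]] <- vector("list", config$n_layers)
    ycols <- list()
    index <- list()
    eval_layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      Xl <- aset$layers[[l]]
      b <- fit_pc_basis(Xl[idx$fit, , drop = FALSE])
      sc <- project_scores(b, Xl[idx$eval, , drop = FALSE])
      bases[[i]][[l]] <- b
      scores[[i]][[l]] <- sc
      eval_layers[[l]] <- Xl[idx$eval, , drop = FALSE]
      if (b$rank > 0) {
        ycols[[l]] <- sc$scores
        index[[l]] <- data.frame(layer_id = l, pc_rank = sc$pc_rank)
      }
    }
    targets[[i]] <- list(Y = do.call(cbind, ycols),
                         index = do.call(rbind, index))
    predictors[[i]] <- do.call(cbind, eval_layers)
  }
  brains <- lapply(seq_len(config$n_subjects), function(s) {
    make_brain(world, s)
  })
  structure(list(config = config, world = world, bases = bases,
                 scores = scores, predictors = predictors, targets = targets,
                 brains = brains),
            class = "unidim_study")
}

#' Precompute cross-validation engines for a study
#'
#' Engines (per-fold SVDs) for every network's concatenated predictor matrix
#' and every subject's voxel matrix. They depend only on predictors and the
#' fold plan, so they are shared across all target dimensions and across
#' permutation-test iterations.
#'
#' @param study a `unidim_study`, `plan` a [fold_plan()].
#' @return list with `network` and `subject` engine lists.
#' @export
study_engines <- function(study, plan) {
  stopifnot(inherits(study, "unidim_study"))
  list(network = lapply(study$predictors, cv_engine, plan = plan),
       subject = lapply(study$brains, cv_engine, plan = plan))
}

#' Universality of one target dimension
#'
#' The median, over all predictor networks, of the nested cross-validated
#' prediction accuracy (mean Pearson r over outer folds) of the target
#' dimension from each predictor's concatenated pooled layers. The median —
#' not the mean — keeps the summary from being driven by a few predictors
#' with exceptionally high or low scores.
#'
#' @param target numeric vector: one PC-score column on the evaluation set.
#' @param predictors list of pooled `activation_set`s (the target network
#'   excluded by the caller).
#' @param plan a [fold_plan()], `grid` a [penalty_grid()].
#' @return list with `per_predictor_r` and `universality`.
#' @export
universality_score <- function(target, predictors, plan,
                               grid = penalty_grid()) {
  if (length(predictors) == 0L) {
    stop("configuration error: empty predictor list", call. = FALSE)
  }
  r <- vapply(predictors, function(p) {
    X <- if (inherits(p, "activation_set")) concat_predictor_layers(p)
         else as.matrix(p)
    nested_cv_score(X, target, plan, grid)$mean_r
  }, numeric(1))
  list(per_predictor_r = r, universality = stats::median(r))
}

#' Brain similarity of one target dimension
#'
#' The mean, over subjects, of the nested cross-validated prediction
#' accuracy of the target dimension from each subject's voxel responses.
#'
#' @param target numeric vector (evaluation-set PC scores).
#' @param subjects list of stimuli x voxels matrices, row-aligned with the
#'   target.
#' @param plan a [fold_plan()], `grid` a [penalty_grid()].
#' @return list with `per_subject_r` and `brain_similarity`.
#' @export
brain_similarity_score <- function(target, subjects, plan,
                                   grid = penalty_grid()) {
  stopifnot(length(subjects) >= 1L)
  for (S in subjects) {
    if (nrow(S) != length(target)) {
      stop("shape error: subject rows not aligned with target", call. = FALSE)
    }
  }
  r <- vapply(subjects, function(S) {
    nested_cv_score(S, target, plan, grid)$mean_r
  }, numeric(1))
  list(per_subject_r = r, brain_similarity = mean(r))
}

#' Between-subject reliability of a target dimension
#'
#' For each subject, the cross-validated predicted series for the target
#' dimension (held-out predictions assembled in stimulus order); reliability
#' is the mean over subject pairs of the Pearson correlation between their
#' predicted series, clamped to [0, 1]. Brain similarity of a dimension can
#' only be as high as the consistency of the brain data that predicts it, so
#' this acts as a noise ceiling.
#'
#' @inheritParams brain_similarity_score
#' @return scalar reliability in [0, 1], or `NA` with a single subject.
#' @export
between_subject_reliability <- function(target, subjects, plan,
                                        grid = penalty_grid()) {
  if (length(subjects) < 2L) return(NA_real_)
  preds <- lapply(subjects, function(S) {
    eng <- cv_engine(S, plan)
    engine_score(eng, target, grid, return_predictions = TRUE)$predictions[, 1]
  })
  pairs <- utils::combn(length(subjects), 2L)
  r <- apply(pairs, 2L, function(ij) {
    safe_pearson(preds[[ij[1]]], preds[[ij[2]]])
  })
  min(1, max(0, mean(r)))
}

#' Adjust brain similarity for between-subject reliability
#'
#' Attenuation correction: `brain_similarity / sqrt(reliability)`.
#' Dimensions whose reliability falls below the floor are excluded (NA)
#' rather than divided, since the correction is unstable there.
#'
#' @param brain_similarity,reliability numeric vectors (recycled).
#' @param floor reliability floor below which no adjustment is made.
#' @param divisor `"sqrt"` (attenuation-correction convention, default) or
#'   `"raw"` (divide by reliability itself).
#' @return adjusted brain similarity, NA where reliability is missing or
#'   below the floor.
#' @export
reliability_adjust <- function(brain_similarity, reliability, floor = 0.1,
                               divisor = c("sqrt", "raw")) {
  divisor <- match.arg(divisor)
  den <- if (divisor == "sqrt") sqrt(reliability) else reliability
  out <- brain_similarity / den
  out[is.na(reliability) | reliability <= floor] <- NA_real_
  out
}

#' Score every dimension of a study
#'
#' Computes universality (median predictability from the other networks) and
#' brain similarity (mean predictability from each subject) for every
#' retained PC of every layer of every network, sharing per-predictor
#' engines across target dimensions.
#'
#' @param study a `unidim_study`.
#' @param plan a [fold_plan()] over the evaluation stimuli.
#' @param grid a [penalty_grid()].
#' @param engines optional precomputed [study_engines()].
#' @param reliability if TRUE, also compute between-subject reliability and
#'   adjusted brain similarity per dimension.
#' @param method mapping method passed to the scorer.
#' @return a `score_table` data.frame with columns `network_id`, `layer_id`,
#'   `pc_rank`, `universality`, `brain_similarity` (plus `reliability` and
#'   `adjusted_brain_similarity` when requested); the per-predictor and
#'   per-subject correlation matrices are kept in attributes
#'   `per_predictor_r` and `per_subject_r`, row-aligned with the table.
#' @export
score_dimensions <- function(study, plan, grid = penalty_grid(),
                             engines = NULL, reliability = FALSE,
                             method = "ridge") {
  stopifnot(inherits(study, "unidim_study"))
  if (is.null(engines)) engines <- study_engines(study, plan)
  nn <- study$config$n_networks
  rows <- list()
  pred_r <- list()
  subj_r <- list()
  rel <- list()
  for (t in seq_len(nn)) {
    Y <- study$targets[[t]]$Y
    index <- study$targets[[t]]$index
    others <- setdiff(seq_len(nn), t)
    R <- vapply(others, function(p) {
      engine_score(engines$network[[p]], Y, grid, method = method)$mean_r
    }, numeric(ncol(Y)))
    R <- matrix(R, nrow = ncol(Y))
    B <- vapply(seq_along(study$brains), function(s) {
      engine_score(engines$subject[[s]], Y, grid, method = method)$mean_r
    }, numeric(ncol(Y)))
    B <- matrix(B, nrow = ncol(Y))
    rows[[t]] <- data.frame(network_id = t,
                            layer_id = index$layer_id,
                            pc_rank = index$pc_rank,
                            universality = apply(R, 1L, stats::median),
                            brain_similarity = rowMeans(B))
    pred_r[[t]] <- R
    subj_r[[t]] <- B
    if (reliability) {
      preds <- lapply(engines$subject, function(e) {
        engine_score(e, Y, grid, method = method,
                     return_predictions = TRUE)$predictions
      })
      pairs <- utils::combn(length(preds), 2L)
      rel[[t]] <- vapply(seq_len(ncol(Y)), function(j) {
        r <- apply(pairs, 2L, function(ij) {
          safe_pearson(preds[[ij[1]]][, j], preds[[ij[2]]][, j])
        })
        min(1, max(0, mean(r)))
      }, numeric(1))
    }
  }
  tbl <- do.call(rbind, rows)
  if (reliability) {
    tbl$reliability <- unlist(rel)
    tbl$adjusted_brain_similarity <-
      reliability_adjust(tbl$brain_similarity, tbl$reliability)
  }
  attr(tbl, "per_predictor_r") <- do.call(rbind, pred_r)
  attr(tbl, "per_subject_r") <- do.call(rbind, subj_r)
  class(tbl) <- c("score_table", "data.frame")
  tbl
}

#' Quantile-bin means of universality and brain similarity
#'
#' Records are sorted by universality (ascending) and grouped into
#' consecutive bins of `bin_size`; a final partial bin is dropped so all
#' quantiles are equally sized. Per-bin means of both metrics trace the
#' trend curve.
#'
#' @param table a `score_table` (any data.frame with `universality` and
#'   `brain_similarity` columns).
#' @param bin_size dimensions per quantile bin (default 100).
#' @return data.frame with `bin`, `mean_universality`,
#'   `mean_brain_similarity`.
#' @export
quantile_bin_means <- function(table, bin_size = 100L) {
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) stop("bin_size must be >= 1", call. = FALSE)
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  ord <- order(table$universality)
  u <- table$universality[ord]
  b <- table$brain_similarity[ord]
  n_bins <- nrow(table) %/% bin_size
  if (n_bins == 0L) {
    return(data.frame(bin = integer(0), mean_universality = numeric(0),
                      mean_brain_similarity = numeric(0)))
  }
  keep <- seq_len(n_bins * bin_size)
  g <- rep(seq_len(n_bins), each = bin_size)
  data.frame(bin = seq_len(n_bins),
             mean_universality = as.numeric(tapply(u[keep], g, mean)),
             mean_brain_similarity = as.numeric(tapply(b[keep], g, mean)))
}
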