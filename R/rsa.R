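#' Split evaluation stimuli into RSA train and test halves
#'
#' Random disjoint halves with a recorded seed; with an odd count the extra
#' stimulus goes to the training half.
#'
#' @param n_eval number of evaluation stimuli (>= 8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n_eval, seed = 1L) {
  n_eval <- as.integer(n_eval)
  if (n_eval < 8L) stop("need at least 8 stimuli to split", call. = FALSE)
  n_train <- ceiling(n_eval / 2)
  perm <- with_component_seed(seed, "rsa_split", sample.int(n_eval))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n_eval]))
}

#' Representational dissimilarity matrix
#'
#' Pairwise Pearson correlation distances between condition rows:
#' `D(i, j) = 1 - cor(row i, row j)`. Zero-variance rows get distance 1 to
#' every other condition (flagged via the `"degenerate_rows"` attribute).
#'
#' @param X conditions x features matrix with >= 2 features.
#' @param labels optional condition labels (default row indices).
#' @return an `rdm`: list with `labels` and the symmetric distance matrix
#'   `D` (zero diagonal, entries in [0, 2]).
#' @export
compute_rdm <- function(X, labels = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) {
    stop("correlation distance undefined with a single feature",
         call. = FALSE)
  }
  labels <- labels %||% seq_len(nrow(X))
  C <- suppressWarnings(stats::cor(t(X)))
  deg <- which(apply(X, 1L, stats::sd) == 0)
  D <- 1 - C
  if (length(deg) > 0) {
    D[deg, ] <- 1
    D[, deg] <- 1
  }
  diag(D) <- 0
  D <- pmin(pmax((D + t(D)) / 2, 0), 2)  # symmetrize fp noise, clamp range
  structure(list(labels = labels, D = D,
                 degenerate_rows = if (length(deg)) deg else NULL),
            class = "rdm")
}

#' Spearman similarity between two RDMs
#'
#' Spearman correlation over the strictly-lower-triangle entries of two
#' RDMs over the same conditions in the same order.
#'
#' @param a,b `rdm` objects with identical labels.
#' @return scalar in [-1, 1].
#' @export
rdm_similarity <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (!identical(a$labels, b$labels)) {
    stop("label mismatch between RDMs", call. = FALSE)
  }
  lt <- lower.tri(a$D)
  as.numeric(spearman_rho(a$D[lt], b$D[lt]))
}

#' Representational similarity analysis with universal-subspace reduction
#'
#' Conventional RSA with a train/test split: per layer, the train-half RDM
#' of the pooled activations is compared (Spearman) with each subject's
#' train-half RDM and averaged over subjects; the best-performing layer is
#' selected on the training half (ties toward the shallower layer) and the
#' final similarity is computed on the held-out test half. The selected
#' layer is then reduced to the subspace of its `k` most universal
#' dimensions — test-half activations reconstructed from those components
#' only — and the test similarity is recomputed for each `k`.
#'
#' @param study a `unidim_study`.
#' @param network_id 1-based network index.
#' @param table a `score_table` holding universality for this network's
#'   dimensions.
#' @param split a [split_train_test()] result over the evaluation stimuli.
#' @param ks component counts for the reduced analysis (default 10 and 5;
#'   clamped to the selected layer's rank, flagged when clamped).
#' @param scope `"layer"` (default): rank dimensions by universality within
#'   the selected layer; `"network"`: keep only the selected layer's
#'   dimensions that fall in the network-wide top k.
#' @return an `rsa_result`: `per_layer_train_similarity`, `selected_layer`,
#'   `test_similarity_full`, `test_similarity_reduced` (named by k),
#'   `subject_level` scores, and `clamped` flags.
#' @export
run_rsa <- function(study, network_id, table, split, ks = c(10L, 5L),
                    scope = c("layer", "network")) {
  scope <- match.arg(scope)
  stopifnot(inherits(study, "unidim_study"))
  config <- study$config
  nl <- config$n_layers
  # pooled evaluation activations per layer
  aset <- pool_activation_set(make_network(study$world, network_id, "eval"))
  subj_rdm_train <- lapply(study$brains, function(S) {
    compute_rdm(S[split$train, , drop = FALSE], labels = split$train)
  })
  subj_rdm_test <- lapply(study$brains, function(S) {
    compute_rdm(S[split$test, , drop = FALSE], labels = split$test)
  })
  avg_similarity <- function(r, subj_rdms) {
    mean(vapply(subj_rdms, function(s) rdm_similarity(r, s), numeric(1)))
  }
  train_sim <- vapply(seq_len(nl), function(l) {
    r <- compute_rdm(aset$layers[[l]][split$train, , drop = FALSE],
                     labels = split$train)
    avg_similarity(r, subj_rdm_train)
  }, numeric(1))
  sel <- which.max(train_sim)  # which.max takes the first max: shallower layer
  Xsel <- aset$layers[[sel]]
  full_sub <- vapply(subj_rdm_test, function(s) {
    rdm_similarity(compute_rdm(Xsel[split$test, , drop = FALSE],
                               labels = split$test), s)
  }, numeric(1))

  basis <- study$bases[[network_id]][[sel]]
  scores <- study$scores[[network_id]][[sel]]
  tbl_net <- table[table$network_id == network_id, , drop = FALSE]
  tbl_layer <- tbl_net[tbl_net$layer_id == sel, , drop = FALSE]
  reduced <- numeric(0)
  reduced_sub <- list()
  clamped <- logical(0)
  for (k in as.integer(ks)) {
    kk <- min(k, basis$rank)
    keep <- if (scope == "layer") {
      ord <- order(tbl_layer$universality, decreasing = TRUE)
      tbl_layer$pc_rank[ord[seq_len(kk)]]
    } else {
      ord <- order(tbl_net$universality, decreasing = TRUE)
      top <- tbl_net[ord[seq_len(min(k, nrow(tbl_net)))], , drop = FALSE]
      top$pc_rank[top$layer_id == sel]
    }
    # rows of `scores` follow evaluation order 1..n_eval; subset directly
    test_scores <- structure(list(scores = scores$scores[split$test, ,
                                                         drop = FALSE],
                                  pc_rank = scores$pc_rank),
                             class = "pc_scores")
    Xh <- reconstruct_topk(basis, test_scores, keep)
    sub <- vapply(subj_rdm_test, function(s) {
      rdm_similarity(compute_rdm(Xh, labels = split$test), s)
    }, numeric(1))
    reduced <- c(reduced, mean(sub))
    reduced_sub[[as.character(k)]] <- sub
    clamped <- c(clamped, kk < k)
  }
  names(reduced) <- as.character(as.integer(ks))
  names(clamped) <- names(reduced)
  structure(list(per_layer_train_similarity = train_sim,
                 selected_layer = sel,
                 test_similarity_full = mean(full_sub),
                 test_similarity_reduced = reduced,
                 subject_level = list(full = full_sub, reduced = reduced_sub),
                 clamped = clamped,
                 scope = scope),
            class = "rsa_result")
}
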