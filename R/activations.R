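#' Global max pooling over the spatial axis
#'
#' Collapses a stimuli x channels x spatial activation tensor to a
#' stimuli x channels matrix by taking the maximum over spatial positions,
#' removing spatial information so downstream analyses see only which
#' features are encoded. Already-pooled input (a matrix, or spatial length 1)
#' passes through unchanged.
#'
#' @param raw a stimuli x channels matrix or stimuli x channels x spatial
#'   array.
#' @return a stimuli x channels matrix.
#' @export
global_max_pool <- function(raw) {
  if (is.matrix(raw)) return(raw)
  d <- dim(raw)
  if (is.null(d) || length(d) != 3L) {
    stop("shape error: expected a matrix or a 3-d array", call. = FALSE)
  }
  if (d[3] < 1L) stop("shape error: empty spatial axis", call. = FALSE)
  if (d[3] == 1L) {
    out <- raw
    dim(out) <- d[1:2]
    return(out)
  }
  apply(raw, c(1L, 2L), max)
}

# pool every layer of an activation set
pool_activation_set <- function(aset) {
  stopifnot(inherits(aset, "activation_set"))
  aset$layers <- lapply(aset$layers, global_max_pool)
  aset
}

#' Fit a principal-component basis on the fit set
#'
#' PCA of the column-mean-centered activation matrix, retaining all
#' components up to the numerical matrix rank (tolerance: largest dimension
#' times machine epsilon times the top singular value — the conventional
#' default). Centering uses fit-set channel means only, which are stored so
#' evaluation-set projection never peeks at evaluation statistics.
#'
#' @param X_fit stimuli x channels matrix (>= 2 rows).
#' @return a `pc_basis`: `channel_means`, orthonormal `loadings`
#'   (channels x r), `variances` (descending eigenvalues of the covariance),
#'   and `rank`. All-constant input yields rank 0 and an empty basis.
#' @export
fit_pc_basis <- function(X_fit) {
  X_fit <- as.matrix(X_fit)
  if (nrow(X_fit) < 2L) stop("need at least 2 fit stimuli", call. = FALSE)
  mu <- colMeans(X_fit)
  Xc <- sweep(X_fit, 2L, mu)
  s <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  structure(list(channel_means = mu,
                 loadings = s$v[, seq_len(r), drop = FALSE],
                 variances = s$d[seq_len(r)]^2 / (nrow(X_fit) - 1),
                 rank = r),
            class = "pc_basis")
}

#' Project activations onto a fitted PC basis
#'
#' Scores are `(X - channel_means) %*% loadings` with the fit-set channel
#' means; the projected matrix is never re-centered on its own means.
#'
#' @param basis a `pc_basis`.
#' @param X stimuli x channels matrix with the basis's channel count.
#' @return a `pc_scores`: `scores` (stimuli x r) and 1-based `pc_rank`.
#' @export
project_scores <- function(basis, X) {
  stopifnot(inherits(basis, "pc_basis"))
  X <- as.matrix(X)
  if (ncol(X) != length(basis$channel_means)) {
    stop("shape error: channel count does not match basis", call. = FALSE)
  }
  scores <- sweep(X, 2L, basis$channel_means) %*% basis$loadings
  structure(list(scores = scores, pc_rank = seq_len(basis$rank)),
            class = "pc_scores")
}

#' Reconstruct activations from a subset of components
#'
#' `X_hat = scores[, keep] %*% t(loadings[, keep]) + channel_means`. With all
#' components kept this inverts [project_scores()]; with none it returns the
#' channel means in every row. Used to reduce a layer to its most universal
#' dimensions before recomputing representational similarity.
#'
#' @param basis a `pc_basis`.
#' @param scores a `pc_scores` projected with that basis.
#' @param keep integer vector of 1-based component indices (subset of 1..r).
#' @return stimuli x channels matrix.
#' @export
reconstruct_topk <- function(basis, scores, keep) {
  stopifnot(inherits(basis, "pc_basis"), inherits(scores, "pc_scores"))
  keep <- as.integer(keep)
  if (length(keep) > 0 && (any(keep < 1L) || any(keep > basis$rank))) {
    stop("index error: keep must be within 1..rank", call. = FALSE)
  }
  n <- nrow(scores$scores)
  if (length(keep) == 0L) {
    return(matrix(basis$channel_means, n, length(basis$channel_means),
                  byrow = TRUE))
  }
  Xh <- scores$scores[, keep, drop = FALSE] %*%
    t(basis$loadings[, keep, drop = FALSE])
  sweep(Xh, 2L, basis$channel_means, "+")
}
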