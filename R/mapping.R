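#' Ridge penalty grid
#'
#' Zero plus penalties with equal logarithmic spacing between 1e-3 and 1e4
#' (integer exponents by default). Zero is always included so unregularized
#' least squares competes in the inner selection loop.
#'
#' @param exponents integer exponents of the log-spaced positive values.
#' @return a `penalty_grid`: numeric vector, 0 first then increasing.
#' @export
penalty_grid <- function(exponents = -3:4) {
  vals <- sort(unique(10^exponents))
  structure(c(0, vals), class = "penalty_grid")
}

#' Outer cross-validation fold plan
#'
#' Assigns evaluation stimuli to folds by a uniformly random permutation with
#' a recorded seed; fold sizes differ by at most one.
#'
#' @param n_stim number of evaluation stimuli.
#' @param n_folds number of outer folds (default 5).
#' @param seed integer seed for the assignment.
#' @return a `fold_plan`: `n_folds`, `assignment` (fold label per stimulus),
#'   `seed`.
#' @export
fold_plan <- function(n_stim, n_folds = 5L, seed = 1L) {
  n_stim <- as.integer(n_stim)
  n_folds <- as.integer(n_folds)
  if (n_stim < n_folds) {
    stop("configuration error: fewer stimuli than folds", call. = FALSE)
  }
  assignment <- with_component_seed(seed, "folds", {
    sample(rep(seq_len(n_folds), length.out = n_stim))
  })
  structure(list(n_folds = n_folds, assignment = assignment, seed = seed),
            class = "fold_plan")
}

#' Fit ridge regression and predict
#'
#' The intercept is handled by centering predictors and target on training
#' means; coefficients solve the penalized least-squares problem via SVD.
#' `penalty = 0` reduces to least squares (the minimum-norm solution when the
#' training matrix is rank deficient).
#'
#' @param X_train,y_train training predictors (>= 2 rows) and target.
#' @param X_test test predictors with matching columns.
#' @param penalty ridge penalty lambda >= 0.
#' @return predicted numeric vector, one value per test row.
#' @export
ridge_fit_predict <- function(X_train, y_train, X_test, penalty = 0) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  stopifnot(nrow(X_train) >= 2L, penalty >= 0,
            ncol(X_test) == ncol(X_train))
  mu <- colMeans(X_train)
  ybar <- mean(y_train)
  Xc <- sweep(X_train, 2L, mu)
  s <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(s$d, 0)
  k <- sum(s$d > tol)
  if (k == 0L) return(rep(ybar, nrow(X_test)))
  d <- s$d[seq_len(k)]
  U <- s$u[, seq_len(k), drop = FALSE]
  V <- s$v[, seq_len(k), drop = FALSE]
  g <- d / (d^2 + penalty)
  beta <- V %*% (g * crossprod(U, y_train - ybar))
  drop(sweep(X_test, 2L, mu) %*% beta) + ybar
}

# ---------------------------------------------------------------------------
# CV engine: per-fold SVDs of a predictor matrix, reusable across any number
# of target variables (and across permutations of their rows). All ridge
# paths — inner LOO penalty selection, final fits, held-out predictions —
# are expressed through these factorizations.
# ---------------------------------------------------------------------------

#' Precompute per-fold factorizations of a predictor matrix
#'
#' The outer-fold SVDs depend only on the predictor matrix and the fold
#' plan, not on the target, so one engine serves every target dimension and
#' every label permutation. [engine_score()] consumes it.
#'
#' @param X stimuli x features predictor matrix, row-aligned with `plan`.
#' @param plan a [fold_plan()] over the same stimuli.
#' @return a `cv_engine` object.
#' @export
cv_engine <- function(X, plan) {
  X <- as.matrix(X)
  stopifnot(inherits(plan, "fold_plan"), nrow(X) == length(plan$assignment))
  folds <- lapply(seq_len(plan$n_folds), function(f) {
    te <- which(plan$assignment == f)
    tr <- which(plan$assignment != f)
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2L, mu)
    s <- svd(Xc)
    tol <- max(dim(Xc)) * .Machine$double.eps * max(s$d, 0)
    k <- sum(s$d > tol)
    U <- s$u[, seq_len(k), drop = FALSE]
    d <- s$d[seq_len(k)]
    V <- s$v[, seq_len(k), drop = FALSE]
    # column centering absorbs one rank; the fit interpolates (hat diag 1)
    # once the centered column space fills the remaining n_tr - 1 dims
    list(tr = tr, te = te, U = U, d = d, A = U^2, ninv = 1 / length(tr),
         Tte = sweep(X[te, , drop = FALSE], 2L, mu) %*% V,
         interpolating = (k >= length(tr) - 1L))
  })
  structure(list(folds = folds, n_stim = nrow(X), n_features = ncol(X),
                 plan = plan, X = X),
            class = "cv_engine")
}

# leave-one-out predictions (centered scale) for every grid value, one fold.
# Returns list of n_tr x m matrices of LOO residuals e; loo_pred_c = Yc - e.
loo_residuals_fold <- function(fold, Yc, grid) {
  G <- crossprod(fold$U, Yc)           # k x m
  d2 <- fold$d^2
  lapply(as.numeric(grid), function(lam) {
    if (lam == 0 && fold$interpolating) {
      # ridgeless limit: kernel LOO identity e_i = [K^-1 y]_i / [K^-1]_ii
      num <- fold$U %*% (G / d2)
      den <- as.vector(fold$A %*% (1 / d2))
      num / den
    } else {
      w <- d2 / (d2 + lam)
      Fit <- fold$U %*% (w * G)
      R <- Yc - Fit
      # hat diagonal includes the unpenalized intercept's 1/n term
      h <- fold$ninv + as.vector(fold$A %*% w)
      R / pmax(1 - h, 1e-12)
    }
  })
}

# inner-loop criterion for every grid value on one fold, vectorized over
# targets. Returns an m x n_grid matrix: LOO Pearson r (degenerate -> -Inf)
# or negated LOO MSE, so that which-max selects the penalty either way.
# Column sums replace explicit correlation calls in this hot path.
loo_crit_fold <- function(fold, Yc, grid, criterion = "r") {
  n <- nrow(Yc)
  G <- crossprod(fold$U, Yc)
  d2 <- fold$d^2
  cs_y2 <- .colSums(Yc * Yc, n, ncol(Yc))
  crit <- vapply(as.numeric(grid), function(lam) {
    if (lam == 0 && fold$interpolating) {
      e <- (fold$U %*% (G / d2)) / as.vector(fold$A %*% (1 / d2))
    } else {
      w <- d2 / (d2 + lam)
      R <- Yc - fold$U %*% (w * G)
      h <- fold$ninv + as.vector(fold$A %*% w)
      e <- R / pmax(1 - h, 1e-12)
    }
    if (criterion == "mse") return(-.colMeans(e * e, n, ncol(e)))
    # Pearson between loo predictions (Yc - e) and Yc, using that Yc has
    # zero column means: cov and variances reduce to column sums over e
    s_ey <- .colSums(e * Yc, n, ncol(e))
    s_e <- .colSums(e, n, ncol(e))
    s_e2 <- .colSums(e * e, n, ncol(e))
    num <- cs_y2 - s_ey
    va <- cs_y2 - 2 * s_ey + s_e2 - s_e^2 / n
    den <- sqrt(pmax(cs_y2, 0) * pmax(va, 0))
    ifelse(den > 0, pmin(1, pmax(-1, num / den)), -Inf)
  }, numeric(ncol(Yc)))
  matrix(crit, nrow = ncol(Yc))
}

#' Select the ridge penalty by leave-one-out cross-validation
#'
#' For each grid value, leave-one-out predictions are obtained in closed form
#' through the hat-matrix identity (equivalent to refitting n times) and the
#' grid value maximizing the LOO Pearson correlation with the target is
#' selected (or minimizing LOO mean squared error when
#' `criterion = "mse"`). A zero-variance target is flagged and assigned the
#' smallest grid value.
#'
#' @param X predictors (>= 3 rows), `y` target vector.
#' @param grid a [penalty_grid()].
#' @param criterion `"r"` (default) or `"mse"`.
#' @return list with `lambda` (the selected penalty), `criterion` values per
#'   grid entry, and `degenerate` flag.
#' @export
loo_select_penalty <- function(X, y, grid = penalty_grid(),
                               criterion = c("r", "mse")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3L, length(y) == nrow(X))
  # one "fold" whose training set is everything: factorize directly
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(s$d, 0)
  k <- sum(s$d > tol)
  fold <- list(U = s$u[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)],
               A = s$u[, seq_len(k), drop = FALSE]^2, ninv = 1 / nrow(X),
               interpolating = (k >= nrow(X) - 1L))
  if (stats::sd(y) == 0) {
    return(list(lambda = min(as.numeric(grid)), criterion = NULL,
                degenerate = TRUE))
  }
  Yc <- matrix(y - mean(y), ncol = 1L)
  es <- loo_residuals_fold(fold, Yc, grid)
  crit <- vapply(es, function(e) {
    if (criterion == "mse") mean(e^2) else safe_pearson(Yc - e, Yc,
                                                        degenerate = -Inf)
  }, numeric(1))
  best <- if (criterion == "mse") which.min(crit) else which.max(crit)
  list(lambda = as.numeric(grid)[best], criterion = crit, degenerate = FALSE)
}

#' Score targets with nested cross-validated regression
#'
#' The workhorse behind [nested_cv_score()], vectorized over any number of
#' target columns sharing one predictor engine. Per outer fold the penalty is
#' selected by leave-one-out on the training folds (ridge), weights are fit
#' on the training folds, and the Pearson correlation with the held-out fold
#' is recorded; a fold whose prediction has zero variance contributes r = 0.
#'
#' @param engine a [cv_engine()].
#' @param Y stimuli x targets matrix (or vector), row-aligned with the
#'   engine's predictor matrix.
#' @param grid a [penalty_grid()]; ignored for methods without a penalty.
#' @param method `"ridge"` (nested LOO penalty selection), `"ols"` (penalty
#'   fixed at 0, no inner loop), or `"one_to_one"` (best single training
#'   column by signed Pearson correlation).
#' @param criterion inner-loop criterion for ridge, `"r"` or `"mse"`.
#' @param return_predictions if TRUE, also return the held-out predicted
#'   series assembled in stimulus order.
#' @return list with `per_fold_r` (folds x targets), `mean_r` (per target),
#'   `chosen_penalty` (folds x targets, ridge/ols), and optionally
#'   `predictions`.
#' @export
engine_score <- function(engine, Y, grid = penalty_grid(),
                         method = c("ridge", "ols", "one_to_one"),
                         criterion = c("r", "mse"),
                         return_predictions = FALSE) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  stopifnot(inherits(engine, "cv_engine"))
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == engine$n_stim)
  m <- ncol(Y)
  nf <- length(engine$folds)
  per_fold_r <- matrix(NA_real_, nf, m)
  chosen <- matrix(NA_real_, nf, m)
  preds <- if (return_predictions) matrix(NA_real_, engine$n_stim, m) else NULL
  gridv <- as.numeric(grid)

  for (f in seq_len(nf)) {
    fold <- engine$folds[[f]]
    Ytr <- Y[fold$tr, , drop = FALSE]
    Yte <- Y[fold$te, , drop = FALSE]
    if (method == "one_to_one") {
      P <- one_to_one_fold(engine$X, fold, Ytr, Yte)
      per_fold_r[f, ] <- P$r
      if (return_predictions) preds[fold$te, ] <- P$pred
      next
    }
    ybar <- .colMeans(Ytr, nrow(Ytr), m)
    Yc <- Ytr - rep(ybar, each = nrow(Ytr))
    lam <- if (method == "ols") {
      rep(0, m)
    } else {
      crit <- loo_crit_fold(fold, Yc, gridv, criterion)  # m x n_grid
      pick <- max.col(crit, ties.method = "first")
      # fully degenerate targets (zero variance) fall back to smallest value
      deg <- .colSums(Yc * Yc, nrow(Yc), m) == 0
      pick[deg] <- 1L
      gridv[pick]
    }
    chosen[f, ] <- lam
    G <- crossprod(fold$U, Yc)
    P <- matrix(0, length(fold$te), m)
    for (l in unique(lam)) {
      cols <- which(lam == l)
      g <- fold$d / (fold$d^2 + l)
      P[, cols] <- fold$Tte %*% (g * G[, cols, drop = FALSE])
    }
    P <- P + rep(ybar, each = nrow(P))
    per_fold_r[f, ] <- colwise_pearson(P, Yte, degenerate = 0)
    if (return_predictions) preds[fold$te, ] <- P
  }
  out <- list(per_fold_r = per_fold_r, mean_r = colMeans(per_fold_r),
              chosen_penalty = chosen, method = method)
  if (return_predictions) out$predictions <- preds
  out
}

# one-to-one mapping within a fold: pick the training column with the highest
# signed Pearson correlation with each target; score it on the held-out fold.
one_to_one_fold <- function(X, fold, Ytr, Yte) {
  Xtr <- X[fold$tr, , drop = FALSE]
  sds <- apply(Xtr, 2L, stats::sd)
  ok <- which(sds > 0)
  m <- ncol(Ytr)
  if (length(ok) == 0L) {
    return(list(r = rep(0, m),
                pred = matrix(0, length(fold$te), m)))
  }
  C <- suppressWarnings(stats::cor(Xtr[, ok, drop = FALSE], Ytr))
  C[!is.finite(C)] <- -Inf            # degenerate targets select arbitrarily
  best <- ok[max.col(t(C), ties.method = "first")]
  pred <- X[fold$te, best, drop = FALSE]
  r <- vapply(seq_len(m), function(j) {
    safe_pearson(pred[, j], Yte[, j], degenerate = 0)
  }, numeric(1))
  list(r = r, pred = pred)
}

# wrap an engine_score single-target result as a mapping_score
as_mapping_score <- function(sc, j = 1L) {
  structure(list(per_fold_r = sc$per_fold_r[, j],
                 mean_r = sc$mean_r[j],
                 chosen_penalty = sc$chosen_penalty[, j],
                 method = sc$method),
            class = "mapping_score")
}

#' Nested cross-validated ridge score for one target dimension
#'
#' Outer loop over the fold plan; per fold, the penalty is selected by an
#' inner leave-one-out loop on the training folds, weights are fit on the
#' full training folds, and performance is the Pearson correlation between
#' the predicted and actual responses on the held-out fold. The returned
#' `mean_r` averages over the outer folds.
#'
#' @param X predictor matrix, `y` target vector, row-aligned with `plan`.
#' @param plan a [fold_plan()], `grid` a [penalty_grid()].
#' @param criterion inner-loop criterion (`"r"` or `"mse"`).
#' @return a `mapping_score`: `per_fold_r`, `mean_r`, `chosen_penalty`,
#'   `method`.
#' @export
nested_cv_score <- function(X, y, plan, grid = penalty_grid(),
                            criterion = c("r", "mse")) {
  eng <- cv_engine(as.matrix(X), plan)
  as_mapping_score(engine_score(eng, y, grid, method = "ridge",
                                criterion = match.arg(criterion)))
}

#' Ordinary least squares score (no regularization)
#'
#' Same outer cross-validation as [nested_cv_score()] with the penalty fixed
#' at zero and no inner loop.
#' @inheritParams nested_cv_score
#' @return a `mapping_score`.
#' @export
ols_score <- function(X, y, plan) {
  eng <- cv_engine(as.matrix(X), plan)
  as_mapping_score(engine_score(eng, y, method = "ols"))
}

#' One-to-one mapping score
#'
#' Per fold, the predictor column with the highest signed Pearson correlation
#' with the target on the training folds is selected, and the test score is
#' the Pearson correlation between that column and the target on the held-out
#' fold. Constant training columns are excluded; if none remain the fold
#' scores 0.
#' @inheritParams nested_cv_score
#' @return a `mapping_score`.
#' @export
one_to_one_score <- function(X, y, plan) {
  eng <- cv_engine(as.matrix(X), plan)
  as_mapping_score(engine_score(eng, y, method = "one_to_one"))
}

#' Concatenate a network's pooled layers into one predictor matrix
#'
#' Column blocks in layer order, row (stimulus) order preserved. All layers
#' must already be pooled (no spatial axis).
#'
#' @param network an `activation_set`.
#' @return stimuli x (sum of channel counts) matrix.
#' @export
concat_predictor_layers <- function(network) {
  stopifnot(inherits(network, "activation_set"))
  if (any(!vapply(network$layers, is.matrix, logical(1)))) {
    stop("contract error: unpooled layer present; apply global_max_pool first",
         call. = FALSE)
  }
  do.call(cbind, unname(network$layers))
}
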