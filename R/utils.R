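#' Derive a component seed from a global seed and a label
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the global seed and a short component label, so that reruns are
#' bit-identical and independent stages never share an RNG stream.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the component (e.g. "folds", "perm").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
component_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# set.seed with pinned generators, so results do not depend on session options
with_component_seed <- function(seed, label, expr) {
  old <- globalenv()$.Random.seed
  set.seed(component_seed(seed, label), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Pearson correlation that returns `degenerate` (default 0) instead of NA
# when either argument has zero variance. Keeps fold aggregation well-defined.
safe_pearson <- function(x, y, degenerate = 0) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    return(degenerate)
  }
  stats::cor(x, y)
}

# Column-wise Pearson correlation between two row-aligned matrices.
# Degenerate columns (zero variance on either side) score `degenerate`.
colwise_pearson <- function(A, B, degenerate = 0) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  n <- nrow(A)
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  sa <- sqrt(colSums(Ac^2))
  sb <- sqrt(colSums(Bc^2))
  num <- colSums(Ac * Bc)
  den <- sa * sb
  # clamp guards floating point overshoot; degenerate marker passes through
  ifelse(den > 0, pmin(1, pmax(-1, num / den)), degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
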