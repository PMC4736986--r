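#' Build a target distribution from training data
#'
#' The reference for quantile normalization: the per-rank mean of the
#' column-wise sorted training samples (the "mean sorted profile", the
#' convention of target-based quantile-normalization routines).  Its length
#' equals the number of genes.
#'
#' @param train An expression table.
#' @return An ascending numeric vector of length `nrow(train)`.
#' @export
build_target <- function(train) {
  train <- ensure_expr(train, arg = "train")
  m <- expr_mat(train)
  sorted <- apply(m, 2L, sort, method = "radix")
  if (is.null(dim(sorted))) sorted <- matrix(sorted, ncol = ncol(m))
  unname(rowMeans(sorted))
}

#' Quantile-normalize test samples to a target distribution
#'
#' Each sample is normalized independently: the value with rank `r` (ties
#' receive average ranks) is replaced by the sorted target interpolated at
#' the matching quantile position, i.e. position `(r-1)/(n-1)` rescaled to
#' `[1, m]` for a sample of `n` genes and a target of length `m`.  When the
#' lengths match and there are no ties, the sample's sorted values equal
#' the target exactly.  Ranks are scale-free, so linear-space RNA-seq data
#' can be normalized directly against a log2-scale target; the output is
#' declared log2 space.
#'
#' @param test Expression table to normalize.
#' @param target A numeric target distribution from [build_target()], or an
#'   expression table (the target is built from it).
#' @return An expression table in log2 space.
#' @export
quantile_normalize <- function(test, target) {
  test <- ensure_expr(test, arg = "test")
  if (inherits(target, "expr_tbl") || is.data.frame(target)) {
    target <- build_target(target)
  }
  if (!is.numeric(target) || length(target) == 0L) {
    rlang::abort("`target` must be a non-empty numeric vector",
                 class = "tdmnorm_invalid")
  }
  target <- sort(target)
  m <- expr_mat(test)
  mt <- length(target)
  out <- apply(m, 2L, function(v) {
    n <- length(v)
    r <- rank(v, ties.method = "average")
    if (mt == 1L) return(rep(target, n))
    # equal lengths: rank r takes target[r] exactly (interpolate only at ties)
    pos <- if (n == mt) r
           else if (n == 1L) (1 + mt) / 2
           else 1 + (r - 1) / (n - 1) * (mt - 1)
    whole <- pos == floor(pos)
    res <- numeric(n)
    res[whole] <- target[pos[whole]]
    if (any(!whole)) {
      res[!whole] <- stats::approx(seq_len(mt), target, xout = pos[!whole])$y
    }
    res
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = ncol(m))
  dimnames(out) <- dimnames(m)
  as_expr_tbl(out, space = "log2")
}

#' Nonparanormal (Gaussian copula) transform
#'
#' Transforms every gene (row) to Winsorized Gaussian scores, estimating
#' the marginals of a Gaussian copula.  Per gene over `n` samples: empirical
#' CDF values `r/n` from average ranks are truncated into
#' `[delta, 1 - delta]` with
#' `delta = 1 / (4 n^{1/4} sqrt(pi * log n))`
#' (the truncation level of the Winsorized estimator), the standard-normal
#' quantile function is applied, and the gene is rescaled to unit sample
#' standard deviation.  The output depends on the data only through
#' within-gene ranks, so it is invariant to any strictly monotone
#' transform of a gene.  Training and test data are each transformed
#' independently.
#'
#' @param x An expression table with at least 3 samples.
#' @return An expression table in log2 space (Gaussian-score scale).
#' @export
npn_transform <- function(x) {
  x <- ensure_expr(x, arg = "x")
  m <- expr_mat(x)
  n <- ncol(m)
  if (n < 3L) {
    rlang::abort("nonparanormal transform needs at least 3 samples",
                 class = "tdmnorm_invalid")
  }
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- t(apply(m, 1L, function(v) {
    if (max(v) == min(v)) return(rep(0, n))
    u <- rank(v, ties.method = "average") / n
    z <- stats::qnorm(pmin(pmax(u, delta), 1 - delta))
    z / stats::sd(z)
  }))
  if (any(apply(m, 1L, function(v) max(v) == min(v)))) {
    rlang::warn("constant gene(s) set to all zeros in nonparanormal transform")
  }
  dimnames(out) <- dimnames(m)
  as_expr_tbl(out, space = "log2")
}
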