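#' Restrict two expression tables to their shared genes
#'
#' Cross-platform work starts by intersecting the gene sets of the training
#' and test matrices (different platforms measure different genes).  Both
#' outputs are restricted to the intersection in the *training* table's
#' gene order, so coefficients of a model trained on the training matrix
#' stay aligned with the test matrix rows.  Sample sets are unchanged.
#'
#' @param train,test Expression tables ([as_expr_tbl]).
#' @return A named list with elements `train` and `test`.
#' @examples
#' tr <- as_expr_tbl(matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2"))),
#'                   "linear")
#' te <- as_expr_tbl(matrix(5:8, 2, dimnames = list(c("B", "C"), c("t1", "t2"))),
#'                   "linear")
#' align_genes(tr, te)
#' @export
align_genes <- function(train, test) {
  train <- ensure_expr(train, arg = "train")
  test <- ensure_expr(test, arg = "test")
  shared <- intersect(expr_genes(train), expr_genes(test))
  if (length(shared) == 0L) {
    rlang::abort("no genes shared between the two matrices",
                 class = "tdmnorm_invalid")
  }
  tr <- train[match(shared, expr_genes(train)), , drop = FALSE]
  te <- test[match(shared, expr_genes(test)), , drop = FALSE]
  list(train = as_expr_tbl(tr, expr_space(train)),
       test = as_expr_tbl(te, expr_space(test)))
}

#' Keep the k genes with the largest median absolute deviation
#'
#' Variance filtering before training: for each gene the MAD across samples
#' is `median(|x - median(x)|)` (no consistency constant — the ranking is
#' invariant to it), and the `k` genes with the largest MAD are kept.  The
#' original relative gene order is preserved; ties at the cutoff are broken
#' in favour of earlier rows.
#'
#' @param x An expression table.
#' @param k Number of genes to keep (positive, at most the gene count).
#' @return An expression table with `k` genes.
#' @export
filter_by_mad <- function(x, k) {
  x <- ensure_expr(x, arg = "x")
  n <- nrow(x)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    rlang::abort("`k` must be a positive integer", class = "tdmnorm_invalid")
  }
  if (k > n) {
    rlang::abort(sprintf("k (%d) exceeds the number of genes (%d)", k, n),
                 class = "tdmnorm_invalid")
  }
  m <- expr_mat(x)
  mads <- apply(m, 1L, function(v) stats::median(abs(v - stats::median(v))))
  keep <- sort(order(-mads, seq_len(n))[seq_len(k)])
  as_expr_tbl(x[keep, , drop = FALSE], expr_space(x))
}

#' Log2-transform a linear-space expression table
#'
#' RNA-seq abundances are mapped onto the scale microarray data are worked
#' with: `log2(x + pseudocount)`.  A positive pseudocount is required when
#' the table contains zeros (RNA-seq matrices usually do; the default of 1
#' maps zero counts to zero).
#'
#' @param x An expression table in linear space.
#' @param pseudocount Non-negative value added before taking logs.
#' @return An expression table in log2 space.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  x <- ensure_expr(x, space = "linear", arg = "x")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    rlang::abort("`pseudocount` must be a non-negative number",
                 class = "tdmnorm_invalid")
  }
  m <- expr_mat(x)
  if (pseudocount == 0 && any(m == 0)) {
    rlang::abort("zero values require a positive pseudocount",
                 class = "tdmnorm_invalid")
  }
  as_expr_tbl(log2(m + pseudocount), space = "log2")
}
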