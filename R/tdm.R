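#' Summarize a training distribution for TDM
#'
#' Training Distribution Matching (TDM) characterizes the training data by
#' the relationship between the spread of its middle half and its extremes,
#' pooled over *all* entries of the matrix:
#'
#' * `iqr = Q3 - Q1` (interquartile range of the pooled log2 values),
#' * `upper_ratio = (max - Q3) / iqr` — how many IQRs fit between the third
#'   quartile and the maximum,
#' * `lower_ratio = max(0, (Q1 - min) / iqr)` — the same below the first
#'   quartile, not allowed below zero.
#'
#' Quartiles use linear interpolation (R's default type-7 convention);
#' min/max are the observed pooled extremes.  Microarray training data are
#' normally already on the log2 scale; a linear-space table is first
#' log2-transformed with `pseudocount` (either convention is allowed).
#'
#' @param train Expression table of the training (microarray) data.
#' @param pseudocount Pseudocount used if `train` is in linear space.
#' @return An object of class `tdm_params`.
#' @seealso [tdm_transform()]
#' @examples
#' tr <- as_expr_tbl(matrix(c(0, 2, 6, 10), 2,
#'                          dimnames = list(c("g1", "g2"), c("a", "b"))),
#'                   space = "log2")
#' tdm_params(tr)
#' @export
tdm_params <- function(train, pseudocount = 1) {
  train <- ensure_expr(train, arg = "train")
  if (expr_space(train) == "linear") {
    train <- log2_transform(train, pseudocount)
  }
  v <- as.vector(expr_mat(train))
  q <- stats::quantile(v, probs = c(0, 0.25, 0.75, 1), type = 7, names = FALSE)
  iqr <- q[3L] - q[2L]
  if (iqr <= 0) {
    rlang::abort("degenerate training distribution (IQR is zero)",
                 class = "tdmnorm_degenerate")
  }
  structure(
    list(train_min_log2 = q[1L], train_q1_log2 = q[2L],
         train_q3_log2 = q[3L], train_max_log2 = q[4L],
         iqr_log2 = iqr,
         upper_ratio = (q[4L] - q[3L]) / iqr,
         lower_ratio = max(0, (q[2L] - q[1L]) / iqr)),
    class = "tdm_params")
}

#' @export
print.tdm_params <- function(x, ...) {
  cat("Training Distribution Matching parameters (log2 scale)\n")
  cat(sprintf("  min %.4f | Q1 %.4f | Q3 %.4f | max %.4f (IQR %.4f)\n",
              x$train_min_log2, x$train_q1_log2, x$train_q3_log2,
              x$train_max_log2, x$iqr_log2))
  cat(sprintf("  upper ratio (max-Q3)/IQR: %.4f\n", x$upper_ratio))
  cat(sprintf("  lower ratio (Q1-min)/IQR: %.4f\n", x$lower_ratio))
  invisible(x)
}

#' @export
tidy.tdm_params <- function(x, ...) {
  tibble::tibble(term = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' Serialize TDM parameters to JSON
#'
#' @param x A `tdm_params` object.
#' @return A JSON string (useful for audit logs alongside normalized files).
#' @export
tdm_params_json <- function(x) {
  stopifnot(inherits(x, "tdm_params"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' Apply Training Distribution Matching to test data
#'
#' Maps a linear-space test matrix (RNA-seq-like) into the training data's
#' log2 range, adjusting the *dataset as a whole* (never per sample).  With
#' pooled test quartiles `Q1_t`, `Q3_t` and `IQR_t` (type-7), the training
#' spread ratios bound the test range:
#'
#' * `new_max = Q3_t + upper_ratio * IQR_t`
#' * `new_min = max(0, Q1_t - lower_ratio * IQR_t)`
#'
#' Values outside `[new_min, new_max]` are clipped (Winsorized) — this is
#' the compression of the extreme tail the method accepts by design.  The
#' clipped values are then mapped affinely onto
#' `[2^train_min, 2^train_max]` (the training range in inverse-log space)
#' and log2-transformed.  The map is monotone, so within-matrix rank order
#' is preserved except for ties created by clipping.
#'
#' @param test Expression table in linear space, all values >= 0.
#' @param params A [tdm_params] object summarizing the training data.
#' @return An expression table in log2 space; every value lies in
#'   `[train_min_log2, train_max_log2]`.
#' @examples
#' tr <- as_expr_tbl(matrix(c(0, 2, 6, 10), 2,
#'                          dimnames = list(c("g1", "g2"), c("a", "b"))),
#'                   space = "log2")
#' te <- as_expr_tbl(matrix(c(0, 10, 55, 100), 2,
#'                          dimnames = list(c("g1", "g2"), c("a", "b"))),
#'                   space = "linear")
#' tdm_transform(te, tdm_params(tr))
#' @export
tdm_transform <- function(test, params) {
  test <- ensure_expr(test, space = "linear", arg = "test")
  if (!inherits(params, "tdm_params")) {
    rlang::abort("`params` must be a tdm_params object", class = "tdmnorm_invalid")
  }
  m <- expr_mat(test)
  if (any(m < 0)) {
    rlang::abort("negative test values are not allowed", class = "tdmnorm_invalid")
  }
  q <- stats::quantile(as.vector(m), probs = c(0.25, 0.75), type = 7,
                       names = FALSE)
  iqr_t <- q[2L] - q[1L]
  if (iqr_t <= 0) {
    rlang::abort("degenerate test distribution (IQR is zero)",
                 class = "tdmnorm_degenerate")
  }
  new_max <- q[2L] + params$upper_ratio * iqr_t
  new_min <- max(0, q[1L] - params$lower_ratio * iqr_t)
  clipped <- pmin(pmax(m, new_min), new_max)
  lo <- 2^params$train_min_log2
  hi <- 2^params$train_max_log2
  mapped <- lo + (clipped - new_min) * (hi - lo) / (new_max - new_min)
  as_expr_tbl(log2(mapped), space = "log2")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
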