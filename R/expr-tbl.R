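#' Expression tables
#'
#' An `expr_tbl` is a tibble holding a genes-by-samples expression matrix:
#' the first column, `gene`, carries unique gene identifiers and every other
#' column is one sample of numeric expression values.  A `space` attribute
#' declares the value space, `"linear"` (non-negative abundances or counts,
#' as delivered by RNA-seq quantification) or `"log2"` (the scale microarray
#' data are usually worked with).  All normalization and evaluation
#' functions in the package take and return this shape, so analyses chain
#' with the pipe.
#'
#' @param x A data frame whose first column is a character column of gene
#'   identifiers followed by numeric sample columns, or a numeric matrix
#'   with genes in rows (rownames = gene ids, colnames = sample ids).
#' @param space Value space of the expression values, `"linear"` or
#'   `"log2"`.
#' @return A tibble of subclass `expr_tbl` with a `space` attribute.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' as_expr_tbl(m, space = "linear")
#' @export
as_expr_tbl <- function(x, space = c("linear", "log2")) {
  space <- rlang::arg_match(space)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rlang::abort("matrix input must have gene identifiers as rownames",
                   class = "tdmnorm_invalid")
    }
    if (is.null(colnames(x))) {
      colnames(x) <- paste0("S", seq_len(ncol(x)))
    }
    out <- tibble::as_tibble(x, rownames = "gene")
  } else if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
    if (ncol(out) < 2L) {
      rlang::abort("expression table needs a gene column and at least one sample",
                   class = "tdmnorm_invalid")
    }
    names(out)[1L] <- "gene"
    out$gene <- as.character(out$gene)
  } else {
    rlang::abort("`x` must be a matrix or data frame", class = "tdmnorm_invalid")
  }
  validate_expr_tbl(out, space)
  attr(out, "space") <- space
  class(out) <- c("expr_tbl", class(tibble::tibble()))
  out
}

validate_expr_tbl <- function(x, space) {
  if (nrow(x) == 0L) {
    rlang::abort("expression table has no genes", class = "tdmnorm_invalid")
  }
  if (ncol(x) < 2L) {
    rlang::abort("expression table has no samples", class = "tdmnorm_invalid")
  }
  dup <- x$gene[duplicated(x$gene)]
  if (length(dup) > 0L) {
    rlang::abort(
      paste0("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", ")),
      class = "tdmnorm_invalid")
  }
  smp <- names(x)[-1L]
  if (anyDuplicated(smp)) {
    rlang::abort("duplicate sample identifiers", class = "tdmnorm_invalid")
  }
  for (j in smp) {
    v <- x[[j]]
    if (!is.numeric(v)) {
      rlang::abort(paste0("sample column '", j, "' is not numeric"),
                   class = "tdmnorm_invalid")
    }
    if (any(!is.finite(v))) {
      i <- which(!is.finite(v))[1L]
      rlang::abort(
        paste0("non-finite value at gene '", x$gene[i], "', sample '", j, "'"),
        class = "tdmnorm_invalid")
    }
  }
  if (space == "linear") {
    vals <- as.matrix(x[-1L])
    if (any(vals < 0)) {
      rlang::abort("linear-space expression values must be non-negative",
                   class = "tdmnorm_invalid")
    }
  }
  invisible(x)
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf("# Expression table: %d genes x %d samples, %s space\n",
              nrow(x), ncol(x) - 1L, expr_space(x)))
  NextMethod()
}

#' Accessors for expression tables
#'
#' `expr_mat()` returns the plain numeric matrix (genes in rows),
#' `expr_genes()` and `expr_samples()` the identifier vectors, and
#' `expr_space()` the declared value space.
#'
#' @param x An `expr_tbl` (or a data frame of the same shape).
#' @return A matrix, character vector, or the space string.
#' @export
expr_mat <- function(x) {
  m <- as.matrix(x[-1L])
  rownames(m) <- x[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname expr_mat
#' @export
expr_genes <- function(x) as.character(x[[1L]])

#' @rdname expr_mat
#' @export
expr_samples <- function(x) names(x)[-1L]

#' @rdname expr_mat
#' @export
expr_space <- function(x) {
  sp <- attr(x, "space")
  if (is.null(sp)) NA_character_ else sp
}

# Rebuild an expr_tbl from a numeric matrix, reusing ids.
expr_from_mat <- function(m, space) {
  as_expr_tbl(m, space = space)
}

# Coerce + check helper used at the top of user-facing functions.
ensure_expr <- function(x, space = NULL, arg = "x") {
  if (!inherits(x, "expr_tbl")) {
    sp <- attr(x, "space")
    if (is.null(sp)) {
      if (is.null(space)) {
        rlang::abort(
          paste0("`", arg, "` has no declared value space; pass an expr_tbl ",
                 "made with as_expr_tbl()"),
          class = "tdmnorm_invalid")
      }
      sp <- space
    }
    x <- as_expr_tbl(x, space = sp)
  }
  if (!is.null(space) && expr_space(x) != space) {
    rlang::abort(
      paste0("`", arg, "` must be in ", space, " space (declared: ",
             expr_space(x), ")"),
      class = "tdmnorm_space")
  }
  x
}
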