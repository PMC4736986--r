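#' Read and write expression tables
#'
#' Expression matrices travel as tab-separated text with gene identifiers in
#' the first column and one column per sample.  Two dialects are supported:
#' plain `tsv` (header `GENE<tab>sample1<tab>...`) and `pcl`, which carries
#' the extra `NAME` and `GWEIGHT` annotation columns after the gene column
#' and may contain an `EWEIGHT` row; both are skipped on read and
#' regenerated on write.  Parsing is locale-independent (dot decimal
#' separator).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"pcl"`.
#' @param space Declared value space of the stored values (`"linear"` or
#'   `"log2"`).
#' @return `read_expr()` returns an [expr_tbl][as_expr_tbl];
#'   `write_expr()` invisibly returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- as_expr_tbl(matrix(c(1, 2, 3, 4), 2,
#'                         dimnames = list(c("g1", "g2"), c("a", "b"))),
#'                  space = "linear")
#' write_expr(m, tf)
#' read_expr(tf, space = "linear")
#' @export
read_expr <- function(path, dialect = c("tsv", "pcl"),
                      space = c("linear", "log2")) {
  dialect <- rlang::arg_match(dialect)
  space <- rlang::arg_match(space)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "tdmnorm_io")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    rlang::abort(paste0("empty expression matrix in ", path),
                 class = "tdmnorm_io")
  }
  if (dialect == "pcl") {
    if (ncol(raw) < 4L) {
      rlang::abort("PCL file must have GENE, NAME, GWEIGHT and sample columns",
                   class = "tdmnorm_io")
    }
    raw <- raw[, -c(2L, 3L)]
    raw <- raw[toupper(raw[[1L]]) != "EWEIGHT", , drop = FALSE]
  }
  genes <- as.character(raw[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate gene id in ", path, ": ", dup[1L]),
                 class = "tdmnorm_io")
  }
  vals <- vector("list", ncol(raw) - 1L)
  for (j in seq_along(vals)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      rlang::abort(
        sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                col[bad[1L]], bad[1L], genes[bad[1L]], names(raw)[j + 1L]),
        class = "tdmnorm_io")
    }
    vals[[j]] <- num
  }
  out <- tibble::tibble(gene = genes)
  for (j in seq_along(vals)) out[[names(raw)[j + 1L]]] <- vals[[j]]
  as_expr_tbl(out, space = space)
}

#' @param x An `expr_tbl` to write.
#' @rdname read_expr
#' @export
write_expr <- function(x, path, dialect = c("tsv", "pcl")) {
  dialect <- rlang::arg_match(dialect)
  x <- ensure_expr(x, arg = "x")
  validate_expr_tbl(x, expr_space(x))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rlang::abort(paste0("cannot write to ", path, ": directory does not exist"),
                 class = "tdmnorm_io")
  }
  out <- tibble::as_tibble(x)
  names(out)[1L] <- "GENE"
  if (dialect == "pcl") {
    out <- tibble::add_column(out, NAME = out$GENE, GWEIGHT = 1, .after = 1L)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Labels travel as a two-column TSV (`sample`, `class`); a header line is
#' detected and skipped when its first field is one of the usual header
#' words.
#'
#' @param path Path to the labels file.
#' @return A tibble with columns `sample` and `class`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "tdmnorm_io")
  }
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) {
    rlang::abort("labels file must have two columns (sample, class)",
                 class = "tdmnorm_io")
  }
  if (tolower(raw[[1L]][1L]) %in% c("sample", "sample_id", "id")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  tibble::tibble(sample = raw[[1L]], class = raw[[2L]])
}

#' @param labels A tibble with columns `sample` and `class`.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble::tibble(sample = labels$sample, class = labels$class),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
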