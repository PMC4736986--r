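# Small fixture builders shared across the test files.

make_expr <- function(values, genes = NULL, samples = NULL, space = "linear") {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  as_expr_tbl(m, space = space)
}

rand_expr <- function(n_genes, n_samples, seed, space = "linear",
                      rfun = function(n) stats::rexp(n, rate = 1 / 50)) {
  withr::with_seed(seed, {
    make_expr(matrix(rfun(n_genes * n_samples), n_genes, n_samples),
              space = space)
  })
}

# training values whose pooled type-7 quartiles are exactly
# min 0, Q1 2, Q3 6, max 10
tdm_train_fixture <- function() {
  make_expr(matrix(c(0, 2, 4, 6, 10), 5, 1), space = "log2")
}

tdm_test_fixture <- function() {
  make_expr(matrix(c(0, 10, 55, 100, 400), 5, 1), space = "linear")
}
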