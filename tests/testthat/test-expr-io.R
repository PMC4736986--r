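test_that("expression tables validate their invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(as_expr_tbl(m, "linear"), "duplicate gene", class = "tdmnorm_invalid")
  m2 <- matrix(c(-1, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(as_expr_tbl(m2, "linear"), "non-negative", class = "tdmnorm_invalid")
  expect_s3_class(as_expr_tbl(m2, "log2"), "expr_tbl")
  m3 <- matrix(c(1, NA, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(as_expr_tbl(m3, "linear"), "non-finite", class = "tdmnorm_invalid")
})

test_that("write_expr / read_expr round-trips ids and values", {
  x <- make_expr(matrix(c(1.5, 2^-20, 3.25, 1234567.891, 0, 42), 3, 2))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_expr(x, tf)
  y <- read_expr(tf, space = "linear")
  expect_identical(expr_genes(y), expr_genes(x))
  expect_identical(expr_samples(y), expr_samples(x))
  expect_equal(expr_mat(y), expr_mat(x), tolerance = 1e-9)
  # tiny magnitudes survive within 1e-9 relative error
  expect_lt(abs(expr_mat(y)[2, 1] - 2^-20) / 2^-20, 1e-9)
})

test_that("PCL dialect parses to the same matrix as plain TSV", {
  x <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  pcl <- withr::local_tempfile(fileext = ".pcl")
  write_expr(x, tsv, dialect = "tsv")
  write_expr(x, pcl, dialect = "pcl")
  # inject an EWEIGHT row, which readers must tolerate
  lines <- readLines(pcl)
  eweight <- paste(c("EWEIGHT", "", "", rep("1", length(expr_samples(x)))),
                   collapse = "\t")
  writeLines(c(lines[1], eweight, lines[-1]), pcl)
  a <- read_expr(tsv, dialect = "tsv", space = "linear")
  b <- read_expr(pcl, dialect = "pcl", space = "linear")
  expect_equal(expr_mat(a), expr_mat(b))
})

test_that("malformed files produce located errors and no partial output", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GENE\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"), tf)
  expect_error(read_expr(tf, space = "linear"), "row 1.*column 's2'",
               class = "tdmnorm_io")
  writeLines(c("GENE\ts1", "g1\t1", "g1\t2"), tf)
  expect_error(read_expr(tf, space = "linear"), "duplicate gene id.*g1",
               class = "tdmnorm_io")
  writeLines("GENE\ts1", tf)
  expect_error(read_expr(tf, space = "linear"), "empty", class = "tdmnorm_io")
  # empty table never reaches the disk
  x <- make_expr(matrix(1:4, 2))
  out <- file.path(withr::local_tempdir(), "never.tsv")
  expect_error(write_expr(x[0, ], out), class = "tdmnorm_invalid")
  expect_false(file.exists(out))
})

test_that("align_genes intersects in training order", {
  tr <- make_expr(matrix(1:6, 3, 2), genes = c("A", "B", "C"))
  te <- make_expr(matrix(1:6, 3, 2), genes = c("B", "C", "D"))
  al <- align_genes(tr, te)
  expect_identical(expr_genes(al$train), c("B", "C"))
  expect_identical(expr_genes(al$test), c("B", "C"))
  expect_identical(expr_samples(al$test), expr_samples(te))
  # identical gene sets: identity
  al2 <- align_genes(tr, tr)
  expect_equal(expr_mat(al2$test), expr_mat(tr))
  # disjoint sets: error
  expect_error(align_genes(tr, make_expr(matrix(1:2, 1), genes = "Z")),
               "no genes shared", class = "tdmnorm_invalid")
})

test_that("a 3000-gene panel intersected with a platform sharing 2520 keeps 2520", {
  genes_train <- sprintf("T%04d", 1:3000)
  genes_test <- c(genes_train[1:2520], sprintf("X%04d", 1:480))
  tr <- make_expr(matrix(1, 3000, 1), genes = genes_train)
  te <- make_expr(matrix(1, 3000, 1), genes = sample(genes_test))
  al <- align_genes(tr, te)
  expect_equal(nrow(al$train), 2520)
  expect_identical(expr_genes(al$test), genes_train[1:2520])
})

test_that("filter_by_mad keeps the k highest-MAD genes in original order", {
  x <- make_expr(rbind(A = c(1, 1, 1), B = c(1, 5, 9), C = c(2, 3, 4)),
                 genes = c("A", "B", "C"))
  # MADs: A = 0, B = 4, C = 1
  expect_identical(expr_genes(filter_by_mad(x, 2)), c("B", "C"))
  expect_equal(expr_mat(filter_by_mad(x, 3)), expr_mat(x))
  expect_error(filter_by_mad(x, 4), "exceeds", class = "tdmnorm_invalid")
  # kept MADs dominate excluded MADs on random data
  y <- rand_expr(40, 8, seed = 5)
  mads <- apply(expr_mat(y), 1, function(v) median(abs(v - median(v))))
  kept <- expr_genes(filter_by_mad(y, 15))
  expect_gte(min(mads[kept]), max(mads[setdiff(expr_genes(y), kept)]))
})

test_that("MAD filtering at k = 3000 returns exactly 3000 genes", {
  x <- rand_expr(3200, 3, seed = 7)
  expect_equal(nrow(filter_by_mad(x, 3000)), 3000)
})

test_that("log2_transform is exact on powers of two and invertible", {
  x <- make_expr(rbind(c(0, 1024), c(7, 3)))
  y <- log2_transform(x, pseudocount = 1)
  expect_equal(expr_mat(y)[1, 1], 0)
  expect_equal(expr_mat(y)[2, 1], 3)           # log2(7 + 1)
  expect_equal(expr_space(y), "log2")
  y0 <- log2_transform(make_expr(rbind(c(4, 1024))), pseudocount = 0)
  expect_equal(unname(expr_mat(y0)[1, ]), c(2, 10))
  expect_error(log2_transform(x, pseudocount = 0), "pseudocount",
               class = "tdmnorm_invalid")
  # strictly monotone, and 2^y - pseudocount recovers the input
  z <- rand_expr(30, 4, seed = 1)
  w <- log2_transform(z, 1)
  expect_true(all(order(as.vector(expr_mat(w))) == order(as.vector(expr_mat(z)))))
  expect_equal(2^expr_mat(w) - 1, expr_mat(z), tolerance = 1e-9)
})

test_that("labels round-trip through the two-column TSV format", {
  lab <- tibble::tibble(sample = c("s1", "s2"), class = c("A", "B"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lab, tf)
  expect_equal(as.data.frame(read_labels(tf)), as.data.frame(lab))
})
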