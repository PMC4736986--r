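# Independent oracle: the TDM mapping executed step by step from its prose
# definition, kept free of the package's own code paths.
tdm_oracle <- function(train_vals, test_vals) {
  tq <- stats::quantile(train_vals, c(0, 0.25, 0.75, 1), type = 7, names = FALSE)
  iqr <- tq[3] - tq[2]
  up <- (tq[4] - tq[3]) / iqr
  lo <- max(0, (tq[2] - tq[1]) / iqr)
  q <- stats::quantile(test_vals, c(0.25, 0.75), type = 7, names = FALSE)
  iqr_t <- q[2] - q[1]
  new_max <- q[2] + up * iqr_t
  new_min <- max(0, q[1] - lo * iqr_t)
  v <- pmin(pmax(test_vals, new_min), new_max)
  mapped <- 2^tq[1] + (v - new_min) / (new_max - new_min) * (2^tq[4] - 2^tq[1])
  list(upper = up, lower = lo, new_max = new_max, new_min = new_min,
       out = log2(mapped))
}

test_that("the hand-worked training summary and transform reproduce the oracle", {
  train <- tdm_train_fixture()   # pooled quartiles: 0 / 2 / 6 / 10
  test <- tdm_test_fixture()     # pooled values: 0, 10, 55, 100, 400
  p <- tdm_params(train)
  expect_equal(p$iqr_log2, 4)
  expect_equal(p$upper_ratio, 1)
  expect_equal(p$lower_ratio, 0.5)
  oracle <- tdm_oracle(c(0, 2, 4, 6, 10), c(0, 10, 55, 100, 400))
  expect_equal(oracle$new_max, 190)
  expect_equal(oracle$new_min, 0)
  out <- tdm_transform(test, p)
  expect_equal(unname(expr_mat(out)[, 1]), oracle$out, tolerance = 1e-9)
  # the spec-level hand values: v -> log2(1 + v * 1023/190)
  expect_equal(unname(expr_mat(out)[, 1]),
               log2(1 + c(0, 10, 55, 100, 400 * 0 + 190) * 1023 / 190),
               tolerance = 1e-9)
})

test_that("degenerate and invalid inputs are rejected", {
  flat <- make_expr(matrix(5, 3, 2), space = "log2")
  expect_error(tdm_params(flat), "degenerate", class = "tdmnorm_degenerate")
  p <- tdm_params(tdm_train_fixture())
  expect_error(tdm_transform(make_expr(matrix(3, 2, 2)), p),
               class = "tdmnorm_degenerate")
  neg <- make_expr(matrix(c(-1, 2, 3, 4), 2), space = "log2")
  attr(neg, "space") <- "linear"   # bypass constructor to hit the op's check
  expect_error(tdm_transform(neg, p), "negative", class = "tdmnorm_invalid")
  expect_error(tdm_transform(log2_transform(tdm_test_fixture()), p),
               class = "tdmnorm_space")
})

test_that("symmetric training tails give equal spread ratios", {
  train <- make_expr(matrix(c(0, 2, 5, 8, 10), 5, 1), space = "log2")
  p <- tdm_params(train)
  expect_equal(p$upper_ratio, p$lower_ratio)
})

test_that("linear-space training data are log2-transformed first", {
  lin <- make_expr(matrix(c(0, 3, 15, 63, 1023), 5, 1), space = "linear")
  p <- tdm_params(lin, pseudocount = 1)
  expect_equal(p$train_min_log2, 0)
  expect_equal(p$train_max_log2, 10)
})

test_that("clipping maps the out-of-bound tails exactly to the training extremes", {
  p <- tdm_params(tdm_train_fixture())
  test <- make_expr(matrix(c(0, 10, 55, 100, 400, 1e6, 0.0001), 7, 1))
  out <- unname(expr_mat(tdm_transform(test, p))[, 1])
  expect_equal(out[6], 10)   # >= new_max -> train max
  expect_equal(out[1], 0)    # <= new_min -> train min
  expect_true(all(out >= 0 & out <= 10))
})

test_that("TDM invariants hold on seeded random matrices", {
  for (seed in 1:25) {
    train <- rand_expr(30, 6, seed = seed,
                       rfun = function(n) runif(n, 0, 1), space = "log2")
    test <- rand_expr(25, 8, seed = seed + 1000)
    p <- tdm_params(train)
    out <- tdm_transform(test, p)
    mo <- expr_mat(out)
    mi <- expr_mat(test)
    # range containment
    expect_true(all(mo >= p$train_min_log2 - 1e-12 &
                    mo <= p$train_max_log2 + 1e-12))
    # monotonicity over the whole matrix
    expect_true(all(diff(as.vector(mo)[order(as.vector(mi))]) >= -1e-12))
    # exact rank preservation off the clip region
    q <- quantile(mi, c(0.25, 0.75), type = 7, names = FALSE)
    hi <- q[2] + p$upper_ratio * (q[2] - q[1])
    lo <- max(0, q[1] - p$lower_ratio * (q[2] - q[1]))
    keep <- mi > lo & mi < hi
    if (sum(keep) > 2) {
      expect_equal(cor(mi[keep], mo[keep], method = "spearman"), 1)
    }
    # whole-dataset adjustment: column permutation equivariance
    perm <- withr::with_seed(seed, sample(ncol(mi)))
    shuffled <- as_expr_tbl(mi[, perm, drop = FALSE], "linear")
    back <- expr_mat(tdm_transform(shuffled, p))[, order(perm), drop = FALSE]
    expect_equal(unname(back), unname(mo))
  }
})

test_that("a test set drawn as the inverse-log of the training data lands near it", {
  # 2^x is only near-affine on [0, 1], so recovery is approximate: the TDM
  # output quartiles sit close to the training quartiles (absolute scale of
  # the data is 1) and far closer than a bare log2(x + 1) leaves them
  train <- rand_expr(60, 5, seed = 3, rfun = function(n) runif(n, 0, 1),
                     space = "log2")
  test <- as_expr_tbl(2^expr_mat(train), "linear")   # round-free inverse log
  probs <- c(0.25, 0.5, 0.75)
  qs_train <- unname(quantile(as.vector(expr_mat(train)), probs, type = 7))
  qs_tdm <- unname(quantile(
    as.vector(expr_mat(tdm_transform(test, tdm_params(train)))), probs,
    type = 7))
  qs_log2 <- unname(quantile(
    as.vector(expr_mat(log2_transform(test, 1))), probs, type = 7))
  expect_lt(max(abs(qs_tdm - qs_train)), 0.1)
  expect_lt(max(abs(qs_tdm - qs_train)), max(abs(qs_log2 - qs_train)))
})

test_that("TDM output matches the training distribution better than log2(x+1)", {
  ds <- simulate_microarray(sim_config(n_genes = 100, n_samples = 100), seed = 8)
  rna <- to_rnaseq_like(ds$expr)
  train_pool <- as.vector(expr_mat(ds$expr))
  ks <- function(x) suppressWarnings(
    stats::ks.test(as.vector(expr_mat(x)), train_pool)$statistic)
  expect_lt(ks(tdm_transform(rna, tdm_params(ds$expr))),
            ks(log2_transform(rna, 1)))
})

test_that("parameters serialize to JSON and tidy to a tibble", {
  p <- tdm_params(tdm_train_fixture())
  parsed <- jsonlite::fromJSON(tdm_params_json(p))
  expect_equal(parsed$upper_ratio, 1)
  td <- tidy(p)
  expect_identical(td$term[1], "train_min_log2")
  expect_equal(nrow(td), 7)
})
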