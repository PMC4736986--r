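#' L1-regularized multinomial logistic regression
#'
#' Fits a LASSO multinomial model of class on gene expression (samples are
#' observations, genes are predictors, features standardized internally and
#' coefficients reported on the original scale), selecting the penalty that
#' minimizes mean cross-validated multinomial deviance over a descending
#' penalty path, then keeping the full-data fit at that penalty.  Fold
#' assignment is stratified by class and seeded, so the fit is
#' deterministic given the seed.  When a class has fewer samples than
#' `n_folds`, the fold count is capped at the smallest class size with a
#' warning.
#'
#' @param x An expression table (training data).
#' @param labels A tibble with columns `sample`, `class` (or a vector of
#'   classes in column order).
#' @param n_folds Number of CV folds (default 100).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `tdm_classifier`.
#' @export
train_l1_multinomial <- function(x, labels, n_folds = 100, seed) {
  x <- ensure_expr(x, arg = "x")
  y <- labels_for(x, labels)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    rlang::abort("need at least 2 classes to train a classifier",
                 class = "tdmnorm_invalid")
  }
  min_class <- min(table(y))
  if (n_folds > min_class) {
    rlang::warn(sprintf(
      "n_folds capped at the smallest class size (%d, was %d)",
      min_class, n_folds))
    n_folds <- min_class
  }
  n_folds <- max(3L, as.integer(n_folds))
  m <- t(expr_mat(x))
  foldid <- integer(nrow(m))
  withr::with_seed(as.integer(seed), {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    cv <- glmnet::cv.glmnet(m, y, family = "multinomial", alpha = 1,
                            foldid = foldid, type.measure = "deviance",
                            standardize = TRUE)
  })
  structure(
    list(classes = classes, gene_ids = colnames(m), cvfit = cv,
         lambda = cv$lambda.min, n_folds = n_folds, seed = as.integer(seed)),
    class = "tdm_classifier")
}

labels_for <- function(x, labels) {
  smp <- expr_samples(x)
  if (is.data.frame(labels)) {
    i <- match(smp, labels$sample)
    if (anyNA(i)) {
      rlang::abort("labels missing for some samples", class = "tdmnorm_invalid")
    }
    as.character(labels$class[i])
  } else {
    if (length(labels) != length(smp)) {
      rlang::abort("one label per sample required", class = "tdmnorm_invalid")
    }
    as.character(labels)
  }
}

#' @export
print.tdm_classifier <- function(x, ...) {
  cat(sprintf(
    "L1 multinomial classifier: %d classes, %d genes, lambda = %.5g (%d-fold CV)\n",
    length(x$classes), length(x$gene_ids), x$lambda, x$n_folds))
  invisible(x)
}

#' @export
tidy.tdm_classifier <- function(x, ...) {
  coefs <- stats::coef(x$cvfit, s = "lambda.min")
  purrr::map_dfr(names(coefs), function(cl) {
    cc <- as.matrix(coefs[[cl]])
    tibble::tibble(class = cl, term = rownames(cc), estimate = cc[, 1L])
  })
}

#' @export
glance.tdm_classifier <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    lambda = x$lambda,
    n_folds = x$n_folds,
    n_classes = length(x$classes),
    nonzero_genes = length(unique(
      td$term[td$term != "(Intercept)" & td$estimate != 0])),
    cv_deviance = x$cvfit$cvm[x$cvfit$lambda == x$lambda][1L])
}

#' Predict classes for new samples
#'
#' Argmax of the per-class scores of a [train_l1_multinomial()] model; exact
#' ties go to the first class in model order.  Genes of `x` must match the
#' model's genes in order.
#'
#' @param model A `tdm_classifier`.
#' @param x An expression table with aligned genes.
#' @return A tibble with columns `sample` and `class`.
#' @export
predict_classes <- function(model, x) {
  stopifnot(inherits(model, "tdm_classifier"))
  x <- ensure_expr(x, arg = "x")
  if (!identical(expr_genes(x), model$gene_ids)) {
    rlang::abort("gene identifiers/order do not match the classifier; align first",
                 class = "tdmnorm_invalid")
  }
  p <- stats::predict(model$cvfit, newx = t(expr_mat(x)), s = "lambda.min",
                      type = "response")[, , 1L, drop = FALSE]
  p <- matrix(p, nrow = ncol(x) - 1L,
              dimnames = list(NULL, dimnames(p)[[2L]]))
  ord <- match(model$classes, colnames(p))
  p <- p[, ord, drop = FALSE]
  cl <- model$classes[apply(p, 1L, which.max)]
  tibble::tibble(sample = expr_samples(x), class = cl)
}
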