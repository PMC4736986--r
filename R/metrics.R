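#' Score predicted against true classes
#'
#' Computes the classifier-transfer report: total accuracy, Cohen's kappa
#' (`(p_o - p_e)/(1 - p_e)` with the chance agreement `p_e` from the
#' marginal products; defined as 1 when both sides are constant and equal),
#' per-class balanced accuracy (mean of sensitivity and specificity with
#' that class as positive, one-vs-rest), the no-information rate (the
#' frequency of the most common true class), and the confusion matrix
#' (rows = truth, columns = predicted) over the union of both class sets.
#'
#' @param pred Predicted labels (vector, or tibble with a `class` column).
#' @param truth True labels, same length.
#' @return An object of class `eval_report`; see also [tidy()] (per-class
#'   balanced accuracy) and [glance()] (one-row summary).
#' @export
score_predictions <- function(pred, truth) {
  if (is.data.frame(pred)) pred <- pred$class
  if (is.data.frame(truth)) truth <- truth$class
  pred <- as.character(pred)
  truth <- as.character(truth)
  n <- length(truth)
  if (n == 0L || length(pred) != n) {
    rlang::abort("`pred` and `truth` must be non-empty and equal length",
                 class = "tdmnorm_invalid")
  }
  classes <- sort(union(pred, truth))
  conf <- table(factor(truth, classes), factor(pred, classes))
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  bal <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    (sens + spec) / 2
  }, numeric(1))
  structure(
    list(total_accuracy = p_o,
         kappa = kappa,
         balanced_accuracy = bal,
         no_information_rate = max(table(truth)) / n,
         confusion = unclass(conf)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy %.4f | kappa %.4f | no-information rate %.4f\n",
              x$total_accuracy, x$kappa, x$no_information_rate))
  cat("Balanced accuracy per class:\n")
  print(round(x$balanced_accuracy, 4))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(class = names(x$balanced_accuracy),
                 balanced_accuracy = unname(x$balanced_accuracy))
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(total_accuracy = x$total_accuracy,
                 kappa = x$kappa,
                 no_information_rate = x$no_information_rate,
                 mean_balanced_accuracy = mean(x$balanced_accuracy, na.rm = TRUE))
}

#' Between/within class variability of sample distributions
#'
#' A distribution-level variability score in the spirit of quantile-based
#' tests for whether global normalization would erase class signal: each
#' sample is summarized by `n_quantiles` empirical quantiles of its values;
#' at each quantile position a one-way ANOVA decomposition of the
#' per-sample quantiles into between-class and within-class mean squares is
#' computed, and the score is the mean over positions of the ratio
#' `MS_between / MS_within`.  Scores well above 1 mean the classes differ
#' in their value *distributions* (so quantile normalization could remove
#' biological signal); scores near 1 mean exchangeable distributions.
#' This is a simplified quantile-ANOVA statistic, not a re-implementation
#' of any external package's test.
#'
#' @param x An expression table.
#' @param labels Class labels (tibble `sample`/`class` or vector); at least
#'   2 classes with at least 2 samples each.
#' @param n_quantiles Number of quantile positions per sample (default 100).
#' @return A non-negative number.
#' @export
variability_f_score <- function(x, labels, n_quantiles = 100) {
  x <- ensure_expr(x, arg = "x")
  y <- labels_for(x, labels)
  tab <- table(y)
  if (length(tab) < 2L) {
    rlang::abort("need at least 2 classes", class = "tdmnorm_invalid")
  }
  if (any(tab < 2L)) {
    rlang::abort("every class needs at least 2 samples", class = "tdmnorm_invalid")
  }
  m <- expr_mat(x)
  probs <- seq(0, 1, length.out = n_quantiles)
  qs <- apply(m, 2L, stats::quantile, probs = probs, type = 7, names = FALSE)
  n <- ncol(m)
  k <- length(tab)
  ratios <- apply(qs, 1L, function(v) {
    gm <- tapply(v, y, mean)
    ssb <- sum(tab * (gm - mean(v))^2)
    ssw <- sum((v - gm[y])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    if (msw == 0) {
      if (msb == 0) 1 else Inf
    } else {
      msb / msw
    }
  })
  mean(ratios)
}

#' Mean Kendall rank correlation between matched samples
#'
#' Tie-corrected Kendall's tau-b between each pair of matched sample
#' columns (over genes), averaged across samples.  Used to track how much
#' of the within-sample gene ranking survives noise or a transform.
#'
#' @param a,b Expression tables with identical dimensions and matched
#'   sample order.
#' @return A number in `[-1, 1]`.
#' @export
mean_kendall_tau <- function(a, b) {
  a <- ensure_expr(a, arg = "a")
  b <- ensure_expr(b, arg = "b")
  ma <- expr_mat(a)
  mb <- expr_mat(b)
  if (!all(dim(ma) == dim(mb))) {
    rlang::abort("matrices must have identical dimensions",
                 class = "tdmnorm_invalid")
  }
  taus <- vapply(seq_len(ncol(ma)),
                 function(j) stats::cor(ma[, j], mb[, j], method = "kendall"),
                 numeric(1))
  mean(taus)
}
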