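#' Normalize a test table by a named method
#'
#' Dispatch helper used by the benchmark harnesses and the command-line
#' tool: `"tdm"` and `"qn"` normalize against the training matrix,
#' `"npn"` and `"log2"` transform the test data standalone,
#' `"untransformed"` (alias `"none"`) passes the data through.
#'
#' @param test Expression table in linear space (except `"untransformed"`,
#'   which accepts anything).
#' @param method One of `"tdm"`, `"qn"`, `"npn"`, `"log2"`,
#'   `"untransformed"`/`"none"`.
#' @param train Training expression table (required for `"tdm"`, `"qn"`).
#' @param pseudocount Pseudocount for the `"log2"` method.
#' @return A normalized expression table.
#' @export
normalize_by_method <- function(test, method, train = NULL, pseudocount = 1) {
  method <- rlang::arg_match(method,
                             c("tdm", "qn", "npn", "log2", "untransformed", "none"))
  if (method %in% c("tdm", "qn") && is.null(train)) {
    rlang::abort(paste0("method '", method, "' needs a training matrix"),
                 class = "tdmnorm_invalid")
  }
  switch(method,
         tdm = tdm_transform(test, tdm_params(train)),
         qn = quantile_normalize(test, build_target(train)),
         npn = npn_transform(test),
         log2 = log2_transform(test, pseudocount),
         test)
}

#' Clustering accuracy across the noise ladder
#'
#' Replicates the simulation study's unsupervised benchmark end to end:
#' simulate a microarray-like dataset and its matched RNA-seq-like
#' duplicate, then for every noise level and normalization method
#' normalize the noisy RNA-seq-like matrix (TDM and QN against the
#' microarray data; NPN and log2 standalone), cluster the normalized,
#' now microarray-like samples with PAM (`k` = number of conditions), and
#' record the cluster-majority accuracy.  The default `refit = TRUE` fits
#' PAM on each normalized test matrix: this is the only mode in which all
#' normalizations are on a common footing at zero noise (each method's
#' output is then a monotone reshaping of the same clean data).  With
#' `refit = FALSE` a single PAM model is fitted on the microarray training
#' data and normalized test samples are assigned to its medoids; the
#' nonparanormal transforms both sides by construction, so in that mode
#' the `"npn"` method assigns to a PAM model fitted on the NPN-transformed
#' microarray data.  Optionally the mean Kendall tau between each noisy
#' matrix and the clean RNA-seq-like matrix is tracked.
#'
#' @param cfg A [sim_config()].
#' @param percentages Noise ladder in percent (see [noise_ladder()]).
#' @param methods Subset of `c("tdm", "qn", "npn", "log2", "untransformed")`.
#' @param seed Integer seed driving the whole run.
#' @param refit Refit PAM per normalized dataset instead of assigning to
#'   the training-side model.
#' @param compute_tau Also record mean Kendall tau of noisy vs clean data.
#' @return A tibble (class `tdm_sweep`) with one row per noise level and
#'   method: `noise_pct`, `method`, `accuracy`, and `tau_noisy_vs_clean`.
#'   Plot with [ggplot2::autoplot()].
#' @export
run_noise_sweep <- function(cfg = sim_config(),
                            percentages = noise_ladder(),
                            methods = c("tdm", "qn", "npn", "log2"),
                            seed,
                            refit = TRUE,
                            compute_tau = TRUE) {
  methods <- match.arg(methods,
                       c("tdm", "qn", "npn", "log2", "untransformed"),
                       several.ok = TRUE)
  ds <- simulate_microarray(cfg, seed)
  rna <- to_rnaseq_like(ds$expr, cfg$rnaseq_max)
  k <- cfg$n_conditions
  base_model <- if (!refit) pam_fit(ds$expr, k)
  npn_model <- if (!refit && "npn" %in% methods) pam_fit(npn_transform(ds$expr), k)
  ladder <- make_noise_ladder(rna, percentages, seed = as.integer(seed) + 1000L)

  rows <- purrr::map_dfr(seq_along(percentages), function(i) {
    noisy <- ladder[[i]]
    tau <- if (compute_tau) mean_kendall_tau(noisy, rna) else NA_real_
    purrr::map_dfr(methods, function(meth) {
      norm <- normalize_by_method(noisy, meth, train = ds$expr)
      model <- if (refit) {
        pam_fit(norm, k)
      } else if (meth == "npn") {
        npn_model
      } else {
        base_model
      }
      cl <- pam_assign(model, norm)
      tibble::tibble(noise_pct = percentages[i], method = meth,
                     accuracy = cluster_majority_accuracy(cl$cluster,
                                                          ds$labels$class),
                     tau_noisy_vs_clean = tau)
    })
  })
  attr(rows, "config") <- cfg
  attr(rows, "seed") <- as.integer(seed)
  class(rows) <- c("tdm_sweep", class(rows))
  rows
}

#' @rdname run_noise_sweep
#' @param object,x A `tdm_sweep` table.
#' @param ... Unused.
#' @export
autoplot.tdm_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$noise_pct, y = .data$accuracy,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "added Gaussian noise (% of sample sd)",
                  y = "cluster-majority accuracy",
                  colour = "normalization") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname run_noise_sweep
#' @export
plot.tdm_sweep <- function(x, ...) print(autoplot.tdm_sweep(x, ...))

#' Supervised transfer across the platform gap
#'
#' Simulates matched microarray / RNA-seq-like data, trains an
#' L1-multinomial classifier on the microarray side, then predicts the
#' class of the noisy RNA-seq-like samples after each normalization and
#' scores the predictions.  As in the unsupervised benchmark, the `"npn"`
#' method uses its own classifier trained on the NPN-transformed
#' microarray data, since the transform applies to both sides.
#'
#' @inheritParams run_noise_sweep
#' @param noise_pct Noise level (percent) applied to the RNA-seq-like data.
#' @param n_folds CV folds for classifier training.
#' @return A tibble with one row per method: accuracy, kappa,
#'   no-information rate, mean balanced accuracy.
#' @export
run_transfer_benchmark <- function(cfg = sim_config(),
                                   noise_pct = 1,
                                   methods = c("tdm", "qn", "log2",
                                               "untransformed"),
                                   n_folds = 20,
                                   seed) {
  methods <- match.arg(methods,
                       c("tdm", "qn", "npn", "log2", "untransformed"),
                       several.ok = TRUE)
  ds <- simulate_microarray(cfg, seed)
  rna <- to_rnaseq_like(ds$expr, cfg$rnaseq_max)
  noisy <- add_noise(rna, noise_pct, seed = as.integer(seed) + 5000L)
  model <- train_l1_multinomial(ds$expr, ds$labels, n_folds = n_folds,
                                seed = seed)
  npn_model <- if ("npn" %in% methods) {
    train_l1_multinomial(npn_transform(ds$expr), ds$labels,
                         n_folds = n_folds, seed = seed)
  }
  purrr::map_dfr(methods, function(meth) {
    norm <- normalize_by_method(noisy, meth, train = ds$expr)
    mdl <- if (meth == "npn") npn_model else model
    rep <- score_predictions(predict_classes(mdl, norm), ds$labels$class)
    dplyr::bind_cols(tibble::tibble(method = meth, noise_pct = noise_pct),
                     glance(rep))
  })
}

#' Repeated cross-platform classification of user data
#'
#' The file-level supervised protocol: align genes between training and
#' test tables, normalize the test table by one method, train the L1
#' multinomial classifier on the training table with `n_folds`-fold CV,
#' repeat over `repeats` seeds (`seed`, `seed + 1`, ...), and score each
#' repeat.  Repeats differ in CV fold assignment only; the summary
#' attribute carries per-metric means with normal-approximation 95%
#' confidence intervals across repeats.
#'
#' @param train,test Expression tables (training platform / test platform).
#' @param train_labels,test_labels Labels (tibble `sample`,`class`).
#' @param method Normalization for the test table (see
#'   [normalize_by_method()]).
#' @param n_folds,repeats,seed Protocol parameters.
#' @param pseudocount Pseudocount for `"log2"`.
#' @return A tibble with one row per repeat (accuracy, kappa,
#'   no-information rate, mean balanced accuracy), with a `summary`
#'   attribute tibble of means and 95% CIs.
#' @export
classify_transfer <- function(train, train_labels, test, test_labels,
                              method = "tdm", n_folds = 100, repeats = 10,
                              seed, pseudocount = 1) {
  al <- align_genes(train, test)
  train_side <- if (method == "npn") npn_transform(al$train) else al$train
  norm <- normalize_by_method(al$test, method, train = al$train,
                              pseudocount = pseudocount)
  truth <- labels_for(al$test, test_labels)
  rows <- purrr::map_dfr(seq_len(repeats), function(r) {
    model <- train_l1_multinomial(train_side, train_labels,
                                  n_folds = n_folds,
                                  seed = as.integer(seed) + r - 1L)
    rep <- score_predictions(predict_classes(model, norm), truth)
    dplyr::bind_cols(tibble::tibble(repeat_id = r, method = method),
                     glance(rep))
  })
  summ <- rows |>
    tidyr::pivot_longer(c("total_accuracy", "kappa", "no_information_rate",
                          "mean_balanced_accuracy"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     ci_lo = mean(.data$value) -
                       1.96 * stats::sd(.data$value) / sqrt(dplyr::n()),
                     ci_hi = mean(.data$value) +
                       1.96 * stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  attr(rows, "summary") <- summ
  rows
}
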