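#' Configuration for the synthetic expression study
#'
#' The generator emulates a condition-structured microarray compendium:
#' `n_genes` genes, of which a `background_fraction` are background genes
#' mostly unaffected by condition, over `n_samples` samples split evenly
#' across `n_conditions` experimental conditions.  Signal genes carry
#' condition-specific mean shifts; gene--gene correlation is induced by
#' shared latent factors ("modules").  Defaults: 500 genes, half
#' background, 400 samples, 4 conditions (100 samples each), and an
#' RNA-seq-like duplicate rescaled to `[0, 1e6]`.
#'
#' Tunables beyond the headline sizes (all in latent log-expression units,
#' i.e. multiples of the residual sd):
#' `effect_size` scales the gene-level condition mean shifts on signal
#' genes (default 2 — strong enough that clustering of the clean data
#' saturates for every normalization, so performance differences emerge
#' from the noise ladder, not from the base task);
#' `condition_shift_sd` draws one location offset per condition applied to
#' *all* genes of its samples (an array-brightness-like, rank-invisible
#' effect creating the between-class distribution-level variability that
#' distinguishes distribution-preserving from distribution-erasing
#' normalizations); it is expressed as a fraction of the pooled dynamic
#' range, i.e. applied after the unit-interval rescale (and the matrix is
#' rescaled once more so the final range is exactly `[0, 1]`);
#' `sample_effect_sd` adds per-sample offsets (technical,
#' within-class distributional variability); `baseline_mean`/`baseline_sd`
#' set the spread of per-gene baselines; `n_modules`,
#' `loading_min`/`loading_max` control the latent-factor correlation
#' structure; `noise_sd` is the residual sd.  The finished matrix is
#' rescaled to the unit interval, the scale network-based expression
#' simulators emit — the matched RNA-seq-like duplication
#' ([to_rnaseq_like()]) relies on `2^x` being near-affine there.
#'
#' @param n_genes,background_fraction,n_samples,n_conditions,rnaseq_max
#'   Study dimensions (see above).
#' @param effect_size,condition_shift_sd,sample_effect_sd Signal strengths.
#' @param baseline_mean,baseline_sd,n_modules,loading_min,loading_max,noise_sd
#'   Distributional shape of the generated data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, background_fraction = 0.5,
                       n_samples = 400, n_conditions = 4,
                       rnaseq_max = 1e6,
                       effect_size = 2, condition_shift_sd = 0.3,
                       sample_effect_sd = 0.2,
                       baseline_mean = 7, baseline_sd = 1.5,
                       n_modules = 10, loading_min = 0.3, loading_max = 0.9,
                       noise_sd = 1) {
  cfg <- as.list(environment())
  if (cfg$n_samples %% cfg$n_conditions != 0) {
    rlang::abort("n_samples must be divisible by n_conditions",
                 class = "tdmnorm_invalid")
  }
  if (cfg$background_fraction <= 0 || cfg$background_fraction >= 1) {
    rlang::abort("background_fraction must be strictly between 0 and 1",
                 class = "tdmnorm_invalid")
  }
  if (cfg$n_genes < 2 || cfg$n_conditions < 2) {
    rlang::abort("need at least 2 genes and 2 conditions",
                 class = "tdmnorm_invalid")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a condition-structured microarray-like dataset
#'
#' Generates a log2-scale genes-by-samples table with class labels.  Each
#' gene has a baseline drawn from `N(baseline_mean, baseline_sd)` and loads
#' (with random sign) on one of `n_modules` latent factors shared across
#' genes, inducing gene--gene correlation.  Signal genes additionally
#' receive condition means: equally spaced levels
#' `effect_size * (c - (k+1)/2)` for `k` conditions, randomly permuted per
#' gene (so every pair of conditions differs by at least `effect_size` at
#' every signal gene).  Per-sample offsets (sd `sample_effect_sd`) and
#' i.i.d. residual noise (sd `noise_sd`) complete the latent model, which
#' is then pooled-rescaled to `[0, 1]`.  On top of the gene-level signal,
#' every condition finally draws one location offset
#' (sd `condition_shift_sd`, in units of the dynamic range) applied to all
#' genes of its samples, and the matrix is rescaled once more to `[0, 1]`:
#' a rank-invisible, distribution-level class effect, so background genes
#' carry no gene-specific condition signal (compare conditions after
#' centering each sample to see this).  Identical seeds give bit-identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (required; runs are pure functions of it).
#' @return A list of class `sim_dataset`: `expr` (log2 [expr_tbl][as_expr_tbl]),
#'   `labels` (tibble `sample`, `class`), `signal_genes` (character).
#' @export
simulate_microarray <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(seed), {
    g <- cfg$n_genes
    s <- cfg$n_samples
    k <- cfg$n_conditions
    per <- s %/% k
    n_signal <- round(g * (1 - cfg$background_fraction))
    gene_ids <- sprintf("G%04d", seq_len(g))
    sample_ids <- sprintf("S%04d", seq_len(s))
    cond <- rep(sprintf("C%d", seq_len(k)), each = per)
    signal <- sort(sample.int(g, n_signal))

    baseline <- stats::rnorm(g, cfg$baseline_mean, cfg$baseline_sd)
    module <- sample.int(cfg$n_modules, g, replace = TRUE)
    loading <- stats::runif(g, cfg$loading_min, cfg$loading_max) *
      sample(c(-1, 1), g, replace = TRUE)
    factors <- matrix(stats::rnorm(cfg$n_modules * s), cfg$n_modules, s)

    # per (signal gene, condition) means: equally spaced levels assigned by
    # randomized Latin squares over blocks of k signal genes, so that every
    # condition receives every level (near-)equally often and the mean shift
    # per condition over the signal genes is (essentially) zero -- the
    # gene-level design is orthogonal to the array-level condition offsets
    levels_k <- cfg$effect_size * (seq_len(k) - (k + 1) / 2)
    shift <- matrix(0, g, k)
    cyc <- outer(seq_len(k), seq_len(k), function(i, j) (i + j - 2L) %% k + 1L)
    pos <- 0L
    while (pos < n_signal) {
      sq <- cyc[sample.int(k), sample.int(k), drop = FALSE]
      take <- min(k, n_signal - pos)
      for (r in seq_len(take)) {
        shift[signal[pos + r], ] <- levels_k[sq[r, ]]
      }
      pos <- pos + take
    }
    cond_offset <- stats::rnorm(k, 0, cfg$condition_shift_sd)
    sample_offset <- stats::rnorm(s, 0, cfg$sample_effect_sd)
    cond_idx <- rep(seq_len(k), each = per)

    x <- matrix(baseline, g, s) +
      loading * factors[module, , drop = FALSE] +
      shift[, cond_idx, drop = FALSE] +
      matrix(sample_offset, g, s, byrow = TRUE) +
      matrix(stats::rnorm(g * s, 0, cfg$noise_sd), g, s)
    # rescale pooled values to [0, 1]: network-based expression simulators
    # emit normalized expression on the unit interval, and the whole
    # matched-duplicate design (2^x is near-affine on [0, 1]) relies on it
    x <- (x - min(x)) / (max(x) - min(x))
    # condition-level brightness offsets on the unit scale, then re-rescale
    x <- sweep(x, 2L, cond_offset[cond_idx], "+")
    x <- (x - min(x)) / (max(x) - min(x))
    dimnames(x) <- list(gene_ids, sample_ids)

    structure(
      list(expr = as_expr_tbl(x, space = "log2"),
           labels = tibble::tibble(sample = sample_ids, class = cond),
           signal_genes = gene_ids[signal],
           config = cfg, seed = as.integer(seed)),
      class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated expression study: %d genes x %d samples, %d conditions (%d signal genes)\n",
    nrow(x$expr), ncol(x$expr) - 1L, x$config$n_conditions,
    length(x$signal_genes)))
  invisible(x)
}

#' Derive an RNA-seq-like duplicate of a log2 matrix
#'
#' Mimics the higher dynamic range of RNA-seq on matched samples: take the
#' inverse log (`2^x`), rescale affinely over the pooled matrix min/max to
#' `[0, rnaseq_max]`, and round.  The result is integer-valued linear-space
#' data with pooled minimum 0 and pooled maximum `rnaseq_max`, and each
#' sample is a monotone transform (up to rounding) of the source sample.
#'
#' @param x An expression table in log2 space.
#' @param rnaseq_max Upper end of the rescaled range (default 1e6).
#' @return An expression table in linear space.
#' @export
to_rnaseq_like <- function(x, rnaseq_max = 1e6) {
  x <- ensure_expr(x, space = "log2", arg = "x")
  m <- 2^expr_mat(x)
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    rlang::abort("constant matrix: rescaling is undefined",
                 class = "tdmnorm_degenerate")
  }
  out <- round((m - lo) / (hi - lo) * rnaseq_max)
  as_expr_tbl(out, space = "linear")
}

#' Add a graded level of Gaussian noise
#'
#' Adds i.i.d. Gaussian noise scaled to each variable's standard
#' deviation: with `per = "sample"` (default, the convention of
#' column-wise noise tools applied to genes-in-rows expression files) the
#' noise sd for a sample column is `pct * sd(column)`; with `per = "gene"`
#' it is `pct * sd(gene row)`.  The ladder's level labels (0--3.8, see
#' [noise_ladder()]) are thus used directly as multiples of the variable
#' sd: this calibration makes the rank correlation between the noisiest
#' dataset and the original approach zero at the top of the default
#' ladder — the ladder's design target — which noise at `pct`/100 of a
#' variable's sd provably cannot do (the correlation would stay above 0.97
#' for any data).  Linear-space results are floored at 0 so downstream
#' log/TDM preconditions hold.  `pct = 0` returns the input unchanged.
#'
#' @param x An expression table.
#' @param pct Noise level (>= 0), in units of the variable's sd.
#' @param seed Integer seed.
#' @param per `"sample"` or `"gene"`: which variable's sd scales the noise.
#' @return An expression table in the same space as `x`.
#' @export
add_noise <- function(x, pct, seed, per = c("sample", "gene")) {
  per <- rlang::arg_match(per)
  x <- ensure_expr(x, arg = "x")
  if (!is.numeric(pct) || length(pct) != 1L || pct < 0) {
    rlang::abort("`pct` must be a non-negative number", class = "tdmnorm_invalid")
  }
  if (pct == 0) return(x)
  m <- expr_mat(x)
  withr::with_seed(as.integer(seed), {
    if (per == "sample") {
      sds <- apply(m, 2L, stats::sd)
      eps <- matrix(stats::rnorm(length(m)), nrow(m), ncol(m)) *
        matrix(sds * pct, nrow(m), ncol(m), byrow = TRUE)
    } else {
      sds <- apply(m, 1L, stats::sd)
      eps <- matrix(stats::rnorm(length(m)), nrow(m), ncol(m)) * (sds * pct)
    }
    out <- m + eps
    if (expr_space(x) == "linear") out <- pmax(out, 0)
    as_expr_tbl(out, space = expr_space(x))
  })
}

#' The default noise ladder
#'
#' Twenty noise levels from 0 to 3.8 in increments of 0.2; the increment is
#' sized so the rank correlation between the noisiest dataset and the
#' original approaches zero at the top of the ladder (see [add_noise()] for
#' the scaling of one ladder unit).
#'
#' @param from,to,by Ladder limits and step.
#' @return An ascending numeric vector of noise percentages.
#' @export
noise_ladder <- function(from = 0, to = 3.8, by = 0.2) {
  p <- seq(from, to, by = by)
  if (any(p < 0)) {
    rlang::abort("noise percentages must be non-negative",
                 class = "tdmnorm_invalid")
  }
  p
}

#' Generate one noisy dataset per ladder level
#'
#' Each level is independently seeded (`seed + level index - 1`), so any
#' level can be regenerated in isolation; the 0% level is the input itself.
#'
#' @param x An expression table.
#' @param percentages Noise levels in percent (see [noise_ladder()]).
#' @param seed Integer base seed.
#' @inheritParams add_noise
#' @return A named list of expression tables, one per level.
#' @export
make_noise_ladder <- function(x, percentages = noise_ladder(), seed,
                              per = c("sample", "gene")) {
  per <- rlang::arg_match(per)
  x <- ensure_expr(x, arg = "x")
  out <- purrr::map(seq_along(percentages), function(i) {
    add_noise(x, percentages[i], seed = as.integer(seed) + i - 1L, per = per)
  })
  rlang::set_names(out, sprintf("%.1f", percentages))
}
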