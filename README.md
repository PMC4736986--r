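# tdmnorm

Cross-platform normalization of gene-expression data for machine
learning: apply models trained on **microarray** data to **RNA-seq**
samples.

Microarray archives hold decades of expression experiments on the log2
scale; new samples arrive as linear-scale RNA-seq abundances with a far
higher dynamic range. A classifier or clustering model trained on one
platform fails on the other because the value distributions differ —
classic dataset shift. `tdmnorm` implements **Training Distribution
Matching (TDM)**: summarize the training distribution's shape by the
ratio of its tail spreads to its interquartile range,

```
upper_ratio = (max − Q3) / IQR        lower_ratio = max(0, (Q1 − min) / IQR)
```

(pooled log2 training values, type-7 quartiles), then bound the pooled
linear-scale test values at `Q3_t + upper_ratio·IQR_t` and
`max(0, Q1_t − lower_ratio·IQR_t)`, clip, map affinely onto the training
range in inverse-log space, and log2-transform. The whole test dataset is
adjusted at once — never per sample — so within-dataset relationships
survive while the distributions become commensurable.

The package also provides the comparators TDM is evaluated against —
quantile normalization to a mean-sorted training target, the Winsorized
nonparanormal (Gaussian-copula) transform, and plain `log2(x + 1)` — plus
a synthetic-data generator (condition-structured microarray-like data
with a matched RNA-seq-like duplicate and a 20-level noise ladder) and
the evaluation harness: PAM (k-medoids) clustering with nearest-medoid
assignment of new samples, L1-regularized multinomial classification with
stratified cross-validation, cluster-majority accuracy, balanced
accuracy, Cohen's kappa, the no-information rate, a distribution-level
variability score, and mean Kendall tau between matched samples.

Everything is tidyverse-shaped: expression matrices travel as tibbles
(`gene` column + one column per sample, with a declared `linear`/`log2`
value space), functions are data-frame-first and pipe-friendly,
benchmark results are tidy tibbles with `autoplot()` methods, and fitted
objects have `tidy()`/`glance()` methods.

## Worked example

Simulate a matched microarray / RNA-seq study, train on the microarray
side, and classify the noisy RNA-seq-like samples after TDM:

```r
library(tdmnorm)

cfg <- sim_config(n_genes = 100, n_samples = 200)   # 4 conditions x 50 samples
ds  <- simulate_microarray(cfg, seed = 1)
rna <- to_rnaseq_like(ds$expr)                       # inverse-log, rounded, [0, 1e6]
noisy <- add_noise(rna, 1, seed = 2)                 # mid-ladder noise level

params <- tdm_params(ds$expr)
params
#> Training Distribution Matching parameters (log2 scale)
#>   min 0.0000 | Q1 0.3780 | Q3 0.5572 | max 1.0000 (IQR 0.1793)
#>   upper ratio (max-Q3)/IQR: 2.4697
#>   lower ratio (Q1-min)/IQR: 2.1083

normalized <- tdm_transform(noisy, params)           # back on the training scale

model <- train_l1_multinomial(ds$expr, ds$labels, n_folds = 20, seed = 3)
report <- score_predictions(predict_classes(model, normalized), ds$labels$class)
report
#> Accuracy 0.9950 | kappa 0.9933 | no-information rate 0.2500
#> Balanced accuracy per class:
#>     C1     C2     C3     C4
#> 1.0000 0.9900 1.0000 0.9967
```

The training summary says the training tail holds about 2.5 IQRs above
the third quartile; the transform grants the test data the same headroom
and clips the rest. After normalization, a classifier trained purely on
microarray-scale data recovers the four simulated conditions from noisy
RNA-seq-like samples almost perfectly (total accuracy 0.995 against a
0.25 no-information rate, kappa 0.993); feeding it the raw 0–10⁶-scale
values instead leaves it at the no-information rate.

The unsupervised benchmark reproduces the whole noise sweep in one call:

```r
sweep <- run_noise_sweep(cfg, methods = c("tdm", "qn", "npn", "log2"), seed = 1)
autoplot(sweep)   # accuracy vs noise, one line per normalization
```

At zero noise all four methods cluster identically; as noise grows, TDM
holds its accuracy longer than quantile normalization (which erases the
between-class distributional signal), while plain log2 degrades first.

A command-line front end over the same functions ships in
`exec/tdm.R` (`normalize`, `qn`, `npn`, `log2`, `simulate`,
`evaluate-sweep`, `classify`).

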