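# rhythmecon

Many genes show a **nycthemeral rhythm** — a 24-hour periodic variation —
in their mRNA or protein abundance, and most such rhythms are
tissue-specific. `rhythmecon` is an R package for computational biologists
who want to test *why* rhythmic expression exists: is rhythmic protein
expression a cost-saving strategy for expensive genes, are genes rhythmic
precisely in the tissues where they are highly expressed, do rhythmic
transcripts show lower cell-to-cell expression noise, and are rhythmic
genes under stronger purifying selection once their higher expression is
controlled for?

The package provides, as composable tibble-in/tibble-out functions:

* **Rhythm detection** — cosinor regression
  `y(t) = a + b·cos(2πt/P) + c·sin(2πt/P)` at `P = 24 h` with an F-test of
  `(b, c) = (0, 0)`, and a robust Tukey-bisquare variant with permutation
  p-values; replicates and cycles enter as extra observations of the same
  phase. Probe-level p-values are combined per gene with the **empirical
  Brown's method** (Fisher's method rescaled by the covariance of
  ECDF-transformed data, correct under dependence).
* **Expression cost** — `C_p = N_p · L_p · c̄_AA`: protein abundance ×
  length × mean per-residue amino-acid synthesis cost, with built-in
  Wagner and Akashi–Gojobori cost tables, abundance under both the mean
  and the distinct-top-two maximum conventions, and Welch contrasts
  between rhythm classes.
* **Tissue analyses** — per-gene δ (mean normalized expression in
  rhythmic minus non-rhythmic tissues, tested against 0), the Yanai
  tissue-specificity index τ ∈ [0, 1] on log expression, τ versus rhythmic
  breadth with an expression-controlled partial correlation, and per-gene
  expression–rhythm correlations across tissues.
* **Single-cell noise** — the mean-decorrelated noise statistic
  `F* = σ²/exp(P_d(log μ))`, with the polynomial degree chosen as the
  lowest that removes the F*–mean association (Kendall and slope
  criteria), plus the five standard rhythm-class contrasts.
* **Selection** — Welch contrasts of log dN/dS between rhythm classes,
  raw and on residuals of `lm(log(dN/dS) ~ log(expression))` to remove
  the expression–conservation confound.
* **A synthetic-data generator** — log-normal baselines, planted cosine
  rhythms with uniform phases, tissue-specific expression coupled to
  tissue-specific rhythmicity, negative-binomial single-cell counts with
  a planted low-noise set, and dN/dS coupled to expression and
  rhythmicity — so every stage has parameter-recovery tests and the whole
  pipeline runs with no downloads.

`run_all()` orchestrates everything from one configuration (R object or
YAML) into a deterministic bundle of TSVs plus a JSON manifest.

## Worked example

Simulate a coupled study (genes rhythmic where highly expressed, costlier
rhythmic proteins, rhythmic transcripts more conserved) and run the full
pipeline:

```r
library(rhythmecon)

cfg <- sim_config(n_genes = 300, n_tissues = 4, n_cells = 100,
                  tissue_coupling = 2, cost_coupling = 0.7,
                  dnds_gamma = -0.3, seed = 1)
res <- run_all(run_config(tempdir(), sim = cfg, min_cells = 20, seed = 1))
res$tissue$delta_test
#>   mean_delta statistic  df   p_value conf_low conf_high   n
#> 1     0.1071     7.089 169 3.512e-11  0.07729    0.1369 170
```

The positive mean δ (0.107, t = 7.09 on 170 genes) recovers the planted
effect: genes are more highly expressed in the tissues where they are
rhythmic. The report table collects every group contrast; excerpts:

```r
res$report[c(1, 12, 13), c("category", "statistic", "p_value", "direction")]
#>   category  statistic  p_value direction
#> 1 c_p_mean       4.70  1.5e-05    higher   # rhythmic proteins costlier
#> 2 dnds_a        -6.07  1.5e-08     lower   # raw: rhythmic more conserved
#> 3 dnds_a        -3.50  6.6e-04     lower   # still true after expression control
```

`direction` refers to the rhythmic group. Diagnostics and figures:
`plot_pvalue_histogram()`, `plot_delta_distribution()`, and `autoplot()`
methods for F* fits and comparison tables; `tidy()`/`glance()` methods
give broom-style summaries.

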