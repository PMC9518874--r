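---
title: "Methods: rhythmicity, expression cost, noise, and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythmicity, expression cost, noise, and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmecon)
```

# The question

Many genes show a nycthemeral rhythm — a 24-hour periodic variation — in
their mRNA or protein abundance, and most of these rhythms are
tissue-specific. `rhythmecon` implements a statistical pipeline for asking
*why*: whether rhythmic protein expression associates with high expression
cost (a cost-saving account), whether genes are rhythmic precisely in the
tissues where they are highly expressed, whether rhythmic transcripts show
lower cell-to-cell expression noise (a precision account), and whether
rhythmic genes sit under stronger purifying selection once their higher
expression is controlled for.

Every stage works on tabular data (tibbles in, tibbles out) and every
stage can be exercised end to end on synthetic data with planted effects,
so the statistical machinery is testable without any external download.

# Rhythm detection

The unit of analysis is a gene-by-sample abundance matrix with sample
times in hours. Both detectors fit the cosinor design

$$y(t) = a + b\cos(2\pi t/P) + c\sin(2\pi t/P),\qquad P = 24\,\mathrm{h},$$

at the *absolute* sample hours: consecutive cycles and biological
replicates enter as additional observations of the same phase rather than
being averaged, which increases power.

* `cosinor_F` — ordinary least squares; p-value from the F-test of
  $(b,c)=(0,0)$ on $2$ and $n-3$ degrees of freedom. Fast and exactly
  calibrated for symmetric noise; the default.
* `robust_regression_perm` — the same design fitted by iteratively
  reweighted least squares with a Tukey bisquare loss. The statistic is
  the relative reduction in robust residual scale versus an intercept-only
  robust fit, and the null is built by permuting the time labels (default
  1000 permutations; the seed is part of the interface because the
  p-values are stochastic). Use it when outliers or heavy tails make the
  F-test untrustworthy.

Abundances are `log1p`-transformed by default — the usual
variance-stabilizing choice for expression data; pass `transform = "none"`
for data already on a symmetric scale. Constant series get $p = 1$ with a
warning; genes with fewer than 4 usable samples get `NA`.

When a gene is represented by several probes or transcripts, their
p-values are combined by the empirical Brown's method
(`combine_pvalues_brown()`): each probe's data row is passed through its
empirical CDF, $w = -2\log(\mathrm{ECDF})$, and the covariance of the $w$
rows rescales the Fisher chi-square null (scale $c$, degrees of freedom
$f$). Independent probes recover Fisher's method exactly; a duplicated
probe contributes no extra evidence and the combined p-value collapses to
the single-probe value. The estimated scale is never allowed below 1
(equivalently $f \le 2k$), so sampling noise in the covariance cannot make
the combination anti-conservative.

`diagnose_pvalue_distribution()` encodes the sanity check applied before
trusting a genome-wide scan: p-values above 0.5, where true rhythms
contribute nothing, should be uniform (Kolmogorov–Smirnov distance below a
threshold, default 0.1), and the lowest histogram bin should be at least
as full as the uniform expectation. Scans skewed towards *high* p-values
indicate a mis-specified detector for that dataset.

Classification uses two published conventions: thresholds (rhythmic at
$p \le 0.01$, non-rhythmic at $p > 0.5$, the intermediate band *ambiguous*
and excluded from group contrasts — reliable rhythmicity cutoffs are hard
to set), or ranking (the first 15% of genes by p-value called rhythmic),
which is the convention used for the cost comparisons. Proteomics rhythms
are harder to detect, so the conventional protein-level threshold is the
laxer $p \le 0.05$. Ties in ranks are broken by gene id, making ranks a
stable permutation.

# Expression cost

The energetic cost of expressing protein $p$ is

$$C_p = N_p \cdot L_p \cdot \bar{c}_{AA},$$

abundance times length times mean per-residue amino-acid synthesis cost
(high-energy phosphate bonds per molecule). Two built-in cost tables are
provided (Wagner respiration values; Akashi–Gojobori values); they are
strongly linearly correlated, so conclusions do not depend on the choice.
Residues without a defined cost (B, Z, X, U) are skipped in the average
while still counting toward $L_p$: no cost is defined for them, but they
occupy positions.

Abundance enters under two conventions, because the "sufficient constant
level" that a rhythmic protein would otherwise need is bracketed by its
mean and its maximum over the cycle:

* `mean_n` — arithmetic mean over all time points (cycles and replicates
  pooled);
* `max_n` — the mean of the two highest *distinct* values, which guards
  the maximum against one-off spikes. A constant series has no two
  distinct values; by continuity its maximum is the constant itself.

Group contrasts (`compare_costs()`) are Welch two-sample t-tests on the
natural-log scale for every component except $\bar{c}_{AA}$, which is
already a bounded per-residue average. Zeros are floored at half the
smallest positive value before logging, the standard pseudo-floor for
abundance data.

# Multi-tissue analyses

Cross-tissue comparability is obtained by the two-step normalization
written as: z-score across genes within a tissue, then division by the
largest z-score, so the per-tissue maximum is exactly 1. The formula's
output is not confined to $[0,1]$ (values below the mean are negative);
this is implemented literally, and it is immaterial for the downstream
statistic because $\delta$ is a difference of group means.

For each gene, $\delta$ is the mean normalized expression over the
tissues where the gene is rhythmic minus the mean over the tissues where
it is not; genes lacking a tissue in either group are excluded and
counted. A one-sample Student's t-test of the $\delta$ distribution
against zero asks whether genes are systematically more expressed where
they are rhythmic.

Tissue-specificity uses the Yanai index
$\tau = \sum_j (1 - \hat{N}_j) / (n - 1)$ on log-transformed mean
expression. The log base and pseudocount are not fixed by the index's
definition; `log2(x + 1)` is used here — the pseudocount keeps sub-unit
abundances from producing negative logs, and any residual negative value
is clamped to zero. On the linear scale $\tau$ is exactly invariant to a
common scale factor; after the log transform the invariance is
asymptotic, holding to within ~0.02 for highly expressed genes.

`tau_vs_rhythmic_breadth()` correlates $\tau$ with the number of tissues
in which the gene is called rhythmic, with a partial correlation
controlling for cross-tissue mean expression (residual-on-residual). The
covariate for the partial correlation is a configuration choice; mean
expression is the default because expression level influences both
quantities. `expression_rhythm_correlation()` computes, for
tissue-specific genes ($\tau > 0.5$), the per-gene correlation between
expression level and rhythm p-value across tissues, and partitions genes
by the sign of the Spearman coefficient into set A (rhythmic where highly
expressed) and set B (the reverse) for the selection stage.

# Single-cell expression noise

Raw cell-to-cell variance tracks the mean, so variances are not
comparable across expression levels. After the standard expression filter
(`log10(FPKM + 1) > 1.5` in at least one cell; the log base is a
configuration choice, with base 10 the convention of the method's source),
a polynomial of $\log\sigma^2$ on $\log\mu$ is fitted across genes and

$$F^*_i = \sigma^2_i / \exp\!\big(P_d(\log\mu_i)\big),$$

the gene's variance relative to the mean–variance trend. $F^*$ is defined
in ratio (exponentiated-residual) form; any monotone back-transform would
give the same rank-based comparisons downstream. The degree $d$ is chosen
by `select_degree()`: the lowest degree in 1..5 whose $F^*$ has both
$|\mathrm{Kendall}\ \tau(F^*, \mu)| < 0.05$ and absolute log–log
regression slope $< 0.05$; if none qualifies, the degree minimizing the
Kendall correlation wins, with ties resolved to the lowest degree. Note
that the OLS slope of $\log F^*$ on $\log\mu$ is zero by construction for
the fitted sample, so the Kendall criterion does the real work of
catching curvature the polynomial missed.

When cell-type labels are present, cell types observed in fewer than
`min_cells` cells are dropped (100 for large atlases; dedicated small
datasets pass at their own scale), and moments can be computed either
pooled or per cell type and averaged with cell-count weights
(`noise_stats(mode = "by_cell_type")`) — the aggregation rule is not
dictated by the data, so both are provided.

Noise contrasts (`compare_noise()`) are Welch tests on $\log F^*$ under
five designs: (a) rhythmic vs non-rhythmic transcripts; (b) the same for
proteins; (c) and (d) transcript contrasts conditioned on rhythmic /
non-rhythmic proteins; (e) protein contrasts among genes with constant
transcripts.

# Selection (dN/dS)

Highly expressed genes are more conserved, and rhythmic genes are
enriched in highly expressed genes, so a raw rhythmic-vs-non-rhythmic
dN/dS contrast is confounded. The control is an OLS fit of $\log(dN/dS)$
on $\log(\text{expression})$, with Welch tests run on the residuals.
Genes with $dN/dS = 0$ or non-positive expression are excluded before the
log (counted); a gene with several orthologue entries is collapsed to its
median. The residuals are invariant to rescaling expression, so the
expression unit is irrelevant.

One behaviour of residual-based control deserves note: when the group
indicator is strongly correlated with the regressed-out covariate, the
residualized group contrast becomes *conservative* (the covariate
regression absorbs part of the between-group variation), with rejection
rates below nominal under the null. It is never anti-conservative, which
is the direction that would matter for the conclusions. Under moderate
expression–rhythmicity coupling the control is near-nominal (~4–5%
rejections at $\alpha = 0.05$ in the shipped simulations) while the
uncontrolled test rejects essentially always when the coupling is on.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all generators are
bit-reproducible given the seed.

* **Bulk time series** — log-normal baselines
  (`baseline_log_mean = 3`, `baseline_log_sd = 1`); a rhythmic fraction
  (default 0.2) follows a single cosine on the log scale with phases drawn
  Uniform(0, 24): real peak times are dispersed across the day and uniform
  is the maximum-entropy choice. The default design is 12 time points at
  2-h spacing over 2 cycles — a standard circadian layout. Replicates are
  independent noise realizations of the same deterministic curve.
  `cost_coupling` shifts rhythmic genes' log baselines, planting
  "rhythmic genes are highly expressed".
* **Multi-tissue** — a fraction of genes gets an elevated home-tissue
  baseline; with probability $1 - e^{-\text{tissue\_coupling}}$ such a
  gene's rhythmicity is tissue-specific (rhythmic in the home tissue and
  nowhere else), otherwise rhythm flags draw independently per tissue.
  Coupling 0 is an exact null; large coupling plants both the positive
  $\delta$ and the negative $\tau$-vs-breadth relation.
* **Single cell** — negative-binomial counts with
  $\mathrm{Var} = \mu + \phi\mu^2$, the standard overdispersion law,
  giving the monotone mean–variance relation the $F^*$ step must remove;
  the planted low-noise set (by default the rhythmic-transcript genes) has
  dispersion $\phi(1 - \text{noise\_coupling})$.
* **dN/dS** — $\log(dN/dS) = \alpha + \beta\log(\text{expr}) +
  \gamma\,\mathbf{1}[\text{rhythmic}] + \varepsilon$; negative $\beta$
  reproduces the expression–conservation relationship, negative $\gamma$
  plants the rhythmicity effect the controlled test must isolate.
* **Proteome** — random amino-acid sequences with log-normal lengths
  (median 350 residues) and typical proteome-wide residue frequencies, so
  the cost stage runs without external FASTA input.

No published effect sizes exist for the couplings, so defaults are chosen
for test power, not biological realism. The generator deliberately does
*not* emulate platform artifacts (microarray saturation, UMI collisions),
probe→gene mapping noise, batch effects between tissues, or a central
clock hierarchy; passing tests therefore demonstrate that the statistical
machinery is correct and calibrated, not that any particular biological
dataset will show the planted effects.

One subtlety worth knowing: a cosine on the log scale inflates the
*arithmetic* mean abundance of rhythmic genes by $I_0(A)$ (≈1.27 at
amplitude 1) even with no planted baseline shift. This is a real property
of rhythmic expression, not a generator bug; null-calibration tests of
group contrasts therefore permute class labels rather than relying on
`cost_coupling = 0`.

# The pipeline

`run_all()` chains the stages from a single `run_config()` (or a YAML
file): rhythm detection and classification at both levels, cost table and
ranking-based cost contrasts, the multi-tissue $\delta$/$\tau$ analyses,
noise contrasts (a–e), and dN/dS contrasts (a–d, raw and controlled),
writing one TSV per stage plus `report.tsv` and a JSON manifest with the
seed, thresholds, and the gene counts surviving every filter. P-values in
the report are raw — that is the conventional presentation for these
contrast tables — with an advisory Benjamini–Hochberg column. A
configurable tissue blacklist supports excluding tissues whose
rhythmicity is dominated by central-clock synchronization (e.g. a
hypothalamus-like tissue) rather than local regulation. Two runs with the
same configuration produce byte-identical bundles; stage failures abort
with the stage name and remove partial output.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (2,000
genes for detector calibration and power, 5,000 for the dN/dS control,
400 genes × 6 tissues for the tissue stage, 1,000 genes × 300 cells for
noise) were chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite stays quick to run.

# Known limitations

* The detectors target a single fixed period; no multi-period scan, no
  phase or amplitude reporting, and no JTK/RAIN-style rank tests.
* Numerical equality with the GeneCycle robust periodogram is not a goal;
  the detectors are specified by their calibration and power properties.
* dN/dS is taken as given (one value per gene); no alignment-based
  estimation or phylogenetic correction.
* Noise is estimated from a single time point per dataset, as in the
  available single-cell data; rhythm-resolved noise is out of reach
  without single-cell time series.
* The cost model covers biosynthesis only — polymerization, degradation
  and maintenance costs scale with the same quantities and would not
  change rank-based comparisons.

# A worked miniature

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 300, n_tissues = 4, n_cells = 100,
                  tissue_coupling = 2, cost_coupling = 0.7,
                  dnds_gamma = -0.3, seed = 1)
res <- run_all(run_config(tempfile(), sim = cfg, min_cells = 20, seed = 1))
res$report
```
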