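#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults describe a bulk circadian design of the kind the
#' pipeline targets: a 24-h period sampled every 2 h over two cycles, a
#' minority of rhythmic genes with uniformly distributed peak phases,
#' log-normal baseline expression, and optional couplings that plant the
#' downstream effects (rhythmic genes more highly expressed, rhythmic in
#' their high-expression tissues, less noisy, more conserved).
#'
#' @param n_genes number of genes.
#' @param n_timepoints time points per cycle.
#' @param sampling_interval_h hours between consecutive time points.
#' @param n_cycles number of consecutive cycles sampled.
#' @param n_replicates biological replicates; each is an independent noise
#'   realization of the same deterministic curve.
#' @param rhythmic_fraction expected fraction of rhythmic genes, in `[0, 1]`.
#' @param period_h rhythm period in hours.
#' @param amplitude_rel cosine amplitude on the natural-log expression scale.
#' @param noise_sd residual standard deviation on the log scale.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline parameters.
#' @param cost_coupling additive shift of log baseline for rhythmic genes;
#'   positive values plant "rhythmic genes are highly expressed".
#' @param n_tissues number of tissues for the multi-tissue generator.
#' @param tissue_specific_fraction fraction of genes with an elevated home
#'   tissue.
#' @param tissue_effect log-scale elevation of a tissue-specific gene in its
#'   home tissue.
#' @param tissue_coupling non-negative coupling between high expression and
#'   rhythmicity across tissues: a tissue-specific gene is rhythmic exactly
#'   in its home tissue with probability `1 - exp(-tissue_coupling)`, and in
#'   a random tissue otherwise. Zero gives an exact null.
#' @param noise_coupling in `[0, 1)`: multiplicative shrinkage of the
#'   negative-binomial dispersion for the planted low-noise gene set.
#' @param dnds_alpha,dnds_beta,dnds_gamma intercept, log-expression slope and
#'   rhythmicity effect on log dN/dS.
#' @param dnds_noise_sd residual sd of log dN/dS.
#' @param n_cells cells in the single-cell generator.
#' @param nb_dispersion negative-binomial dispersion phi in
#'   `Var = mu + phi * mu^2`.
#' @param seed integer seed; every generator is bit-reproducible given it.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' cfg$rhythmic_fraction
#' @export
sim_config <- function(n_genes = 2000,
                       n_timepoints = 12,
                       sampling_interval_h = 2,
                       n_cycles = 2,
                       n_replicates = 1,
                       rhythmic_fraction = 0.2,
                       period_h = 24,
                       amplitude_rel = 1,
                       noise_sd = 0.5,
                       baseline_log_mean = 3,
                       baseline_log_sd = 1,
                       cost_coupling = 0,
                       n_tissues = 4,
                       tissue_specific_fraction = 0.3,
                       tissue_effect = 2,
                       tissue_coupling = 0,
                       noise_coupling = 0,
                       dnds_alpha = -1.5,
                       dnds_beta = -0.2,
                       dnds_gamma = 0,
                       dnds_noise_sd = 0.5,
                       n_cells = 200,
                       nb_dispersion = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_genes", "n_timepoints", "n_cycles", "n_replicates",
              "n_tissues", "n_cells")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v)) {
      abort(sprintf("`%s` must be a single integer >= 1 (got %s).",
                    nm, format(v)))
    }
    cfg[[nm]] <- as.integer(v)
  }
  fracs <- c("rhythmic_fraction", "tissue_specific_fraction")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  pos <- c("period_h", "sampling_interval_h", "nb_dispersion")
  for (nm in pos) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be > 0.", nm))
  }
  nonneg <- c("amplitude_rel", "noise_sd", "dnds_noise_sd", "tissue_coupling")
  for (nm in nonneg) {
    if (cfg[[nm]] < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  if (cfg$noise_coupling < 0 || cfg$noise_coupling >= 1) {
    abort("`noise_coupling` must lie in [0, 1).")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes, %d tp x %d cycles x %d reps, period %g h\n",
              x$n_genes, x$n_timepoints, x$n_cycles, x$n_replicates,
              x$period_h))
  cat(sprintf("  rhythmic fraction %.2f, amplitude %.2f, noise sd %.2f\n",
              x$rhythmic_fraction, x$amplitude_rel, x$noise_sd))
  cat(sprintf("  couplings: cost %.2f, tissue %.2f, noise %.2f, dnds gamma %.2f\n",
              x$cost_coupling, x$tissue_coupling, x$noise_coupling,
              x$dnds_gamma))
  invisible(x)
}
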