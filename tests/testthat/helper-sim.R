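# Shared fixtures, all generated in code.

# Rhythm-class table straight from planted truth flags (bypasses detection
# where only the downstream machinery is under test).
truth_classes <- function(truth, flag = "is_rhythmic_rna") {
  tibble::tibble(
    gene_id = truth$gene_id,
    p_value = ifelse(truth[[flag]], 0.001, 0.9),
    class = ifelse(truth[[flag]], "rhythmic", "non_rhythmic")
  )
}

# Per-tissue class tables from a multitissue truth (list keyed by tissue).
tissue_truth_classes <- function(mt) {
  tissues <- unique(mt$truth_tissue$tissue)
  out <- lapply(tissues, function(tt) {
    fl <- mt$truth_tissue[mt$truth_tissue$tissue == tt, ]
    tibble::tibble(
      gene_id = fl$gene_id,
      p_value = ifelse(fl$is_rhythmic, 0.001, 0.9),
      class = ifelse(fl$is_rhythmic, "rhythmic", "non_rhythmic")
    )
  })
  names(out) <- tissues
  out
}

# Profile built from the deterministic truth baselines (no sampling noise,
# no cosine inflation of arithmetic means): isolates the delta machinery
# from the realized time series.
truth_profile <- function(mt) {
  tt <- merge(mt$truth_tissue, mt$truth[, c("gene_id", "baseline_log")],
              by = "gene_id")
  tt$mean_n <- exp(tt$baseline_log + tt$baseline_shift)
  out <- dplyr::group_by(tibble::as_tibble(tt), tissue) |>
    dplyr::mutate(mean_z = z_normalize(mean_n), max_z = mean_z,
                  max_n = mean_n,
                  p_value = ifelse(is_rhythmic, 0.001, 0.9),
                  class = ifelse(is_rhythmic, "rhythmic", "non_rhythmic")) |>
    dplyr::ungroup()
  out[, c("gene_id", "tissue", "mean_n", "max_n", "mean_z", "max_z",
          "p_value", "class")]
}

# Small cosinor series on an arbitrary time grid.
cosine_series <- function(t_h, amplitude = 1, phase = 3, baseline = 5,
                          period = 24, noise_sd = 0) {
  baseline + amplitude * cos(2 * pi * (t_h - phase) / period) +
    rnorm(length(t_h), 0, noise_sd)
}
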