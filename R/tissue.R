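#' Z-score normalization with max scaling
#'
#' Cross-tissue expression levels are only comparable after per-tissue
#' standardization. Within one tissue, values are z-scored across genes and
#' then divided by the largest z-score, so the maximum is exactly 1. The
#' result is location- and scale-invariant; because the tissue contrast
#' delta is a difference of group means, the (negative, unbounded) lower
#' range is immaterial.
#'
#' @param x numeric vector (one tissue's per-gene expression summaries).
#' @return Normalized vector with `max(result) == 1`.
#' @examples
#' z_normalize(c(1, 2, 3))
#' @export
z_normalize <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) abort("Need >= 2 finite values to normalize.")
  s <- sd(x[ok])
  if (s == 0) abort("Zero standard deviation; normalization undefined.")
  z <- (x - mean(x[ok])) / s
  z / max(z[ok])
}

#' Assemble a multi-tissue expression/rhythm profile
#'
#' Combines per-tissue expression summaries (mean and max abundance per
#' gene, then Z-normalized within tissue) with per-tissue rhythm classes
#' into the long table all tissue-level analyses consume.
#'
#' @param tissue_list named list; each element a list with `expr` and
#'   `meta` (one tissue's time series over the same genes).
#' @param rhythm_list named list of classified rhythm tables (same names),
#'   each with `gene_id`, `p_value`, `class`.
#' @param blacklist tissue names to exclude (e.g. a hypothalamus-like
#'   tissue whose rhythmicity is dominated by the central clock rather than
#'   local regulation).
#' @return A tibble `gene_id`, `tissue`, `mean_n`, `max_n`, `mean_z`,
#'   `max_z`, `p_value`, `class`.
#' @export
tissue_profile <- function(tissue_list, rhythm_list, blacklist = character()) {
  tissues <- setdiff(names(tissue_list), blacklist)
  if (length(tissues) < 2) abort("Need >= 2 tissues after blacklisting.")
  if (!all(tissues %in% names(rhythm_list))) {
    abort("`rhythm_list` must provide a table for every tissue.")
  }
  purrr::map_dfr(tissues, function(tt) {
    ts <- tissue_list[[tt]]
    value_cols <- setdiff(names(ts$expr), c("gene_id", "probe_id"))
    m <- as.matrix(ts$expr[, value_cols])
    summ <- tibble(
      gene_id = ts$expr$gene_id,
      tissue = tt,
      mean_n = apply(m, 1, mean_abundance),
      max_n = apply(m, 1, max_abundance)
    )
    summ$mean_z <- z_normalize(summ$mean_n)
    summ$max_z <- z_normalize(summ$max_n)
    left_join(summ,
              select(rhythm_list[[tt]], "gene_id", "p_value", "class"),
              by = "gene_id")
  })
}

#' Per-gene expression difference between rhythmic and non-rhythmic tissues
#'
#' For each gene, delta is the mean normalized expression over the tissues
#' where the gene is rhythmic minus the mean over the tissues where it is
#' not. Genes lacking at least one tissue in each group are excluded and
#' counted in the `n_excluded` attribute. A positive mean delta across
#' genes says genes are more highly expressed where they are rhythmic.
#'
#' @param profile a [tissue_profile()].
#' @param stat which normalized summary to contrast: `"mean_z"` or
#'   `"max_z"`.
#' @return A tibble `gene_id`, `delta`, `n_r`, `n_nr`, with attribute
#'   `n_excluded`.
#' @export
delta_expression <- function(profile, stat = c("mean_z", "max_z")) {
  stat <- match.arg(stat)
  per_gene <- profile |>
    filter(.data$class %in% c("rhythmic", "non_rhythmic"),
           is.finite(.data[[stat]])) |>
    group_by(.data$gene_id) |>
    summarise(
      n_r = sum(.data$class == "rhythmic"),
      n_nr = sum(.data$class == "non_rhythmic"),
      delta = mean(.data[[stat]][.data$class == "rhythmic"]) -
        mean(.data[[stat]][.data$class == "non_rhythmic"]),
      .groups = "drop"
    )
  out <- filter(per_gene, .data$n_r >= 1, .data$n_nr >= 1)
  attr(out, "n_excluded") <- length(unique(profile$gene_id)) - nrow(out)
  out
}

#' One-sample test of the delta distribution against zero
#'
#' Student's t-test of the per-gene deltas against a mean of 0.
#'
#' @param deltas a [delta_expression()] result (or a numeric vector).
#' @return A one-row tibble: `mean_delta`, `statistic`, `df`, `p_value`,
#'   `conf_low`, `conf_high`, `n`.
#' @export
test_delta <- function(deltas) {
  x <- if (is.data.frame(deltas)) deltas$delta else deltas
  x <- x[is.finite(x)]
  if (length(x) < 2) abort("Need >= 2 deltas.")
  ht <- t.test(x, mu = 0)
  tibble(mean_delta = unname(ht$estimate), statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
         n = length(x))
}

#' Tissue-specificity index tau
#'
#' The Yanai index: `tau = sum(1 - N_hat) / (n - 1)` where `N_hat` is each
#' tissue's log expression relative to the maximum across tissues. Zero for
#' uniform expression, one for expression confined to a single tissue.
#' Expression is transformed as `log2(x + 1)`; the pseudocount keeps
#' sub-unit abundances from producing negative logs, and any residual
#' negative value is clamped to zero before the index.
#'
#' @param profile a [tissue_profile()] (uses `mean_n`), or a wide tibble
#'   `gene_id` + one numeric column per tissue.
#' @return A tibble `gene_id`, `tau`, `n_tissues`.
#' @examples
#' tau_index(tibble::tibble(gene_id = "g1", t1 = 15, t2 = 3, t3 = 3))
#' @export
tau_index <- function(profile) {
  wide <- if (all(c("tissue", "mean_n") %in% names(profile))) {
    tidyr::pivot_wider(select(profile, "gene_id", "tissue", "mean_n"),
                       names_from = "tissue", values_from = "mean_n")
  } else {
    profile
  }
  m <- as.matrix(wide[, setdiff(names(wide), "gene_id")])
  if (ncol(m) < 2) abort("tau needs >= 2 tissues.")
  if (any(m < 0, na.rm = TRUE)) abort("Expression must be >= 0.")
  lg <- pmax(log2(m + 1), 0)
  tau <- apply(lg, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || max(v) == 0) return(NA_real_)
    sum(1 - v / max(v)) / (length(v) - 1)
  })
  tibble(gene_id = wide$gene_id, tau = tau,
         n_tissues = rowSums(is.finite(m)))
}

#' Correlate tissue-specificity with rhythmic breadth
#'
#' Tests whether genes rhythmic in few tissues are tissue-specifically
#' expressed: tau against the number of tissues in which each gene is
#' called rhythmic. Pearson and Spearman coefficients are reported, plus a
#' partial Pearson correlation controlling for cross-tissue mean expression
#' (residual-on-residual), since expression level influences both
#' quantities.
#'
#' @param taus a [tau_index()] result.
#' @param profile a [tissue_profile()].
#' @param p_rhythmic a tissue counts as rhythmic at `p <= p_rhythmic`.
#' @return A tibble with rows `pearson`, `spearman`, `partial_pearson`:
#'   `method`, `estimate`, `statistic`, `p_value`, `n`.
#' @export
tau_vs_rhythmic_breadth <- function(taus, profile, p_rhythmic = 0.01) {
  breadth <- profile |>
    group_by(.data$gene_id) |>
    summarise(
      n_rhythmic = sum(.data$p_value <= p_rhythmic, na.rm = TRUE),
      mean_expr = mean(.data$mean_n, na.rm = TRUE),
      .groups = "drop"
    )
  d <- inner_join(taus, breadth, by = "gene_id") |>
    filter(is.finite(.data$tau), is.finite(.data$n_rhythmic))
  if (nrow(d) < 10) abort("Need >= 10 genes with both tau and breadth.")
  if (sd(d$n_rhythmic) == 0 || sd(d$tau) == 0) {
    abort("Degenerate variance: correlation undefined.")
  }
  pear <- cor.test(d$tau, d$n_rhythmic, method = "pearson")
  spear <- suppressWarnings(
    cor.test(d$tau, d$n_rhythmic, method = "spearman"))
  r_tau <- resid(lm(tau ~ log(mean_expr + 1), data = d))
  r_breadth <- resid(lm(n_rhythmic ~ log(mean_expr + 1), data = d))
  part <- cor.test(r_tau, r_breadth, method = "pearson")
  tibble(
    method = c("pearson", "spearman", "partial_pearson"),
    estimate = c(pear$estimate, spear$estimate, part$estimate),
    statistic = c(pear$statistic, spear$statistic, part$statistic),
    p_value = c(pear$p.value, spear$p.value, part$p.value),
    n = nrow(d)
  )
}

#' Per-gene correlation of expression with rhythm signal across tissues
#'
#' For tissue-specific genes (tau above a threshold), correlates expression
#' level with the rhythm p-value across tissues. A negative coefficient
#' means the gene is most rhythmic (lowest p) where it is most expressed.
#' Genes are partitioned by the sign of the Spearman coefficient into set A
#' (negative) and set B (positive) for the downstream dN/dS contrast.
#'
#' @param profile a [tissue_profile()].
#' @param taus a [tau_index()] result.
#' @param tau_threshold minimum tau for a gene to be considered
#'   tissue-specific.
#' @param min_tissues minimum tissues with both expression and p-value.
#' @return A tibble `gene_id`, `pearson`, `spearman`, `set` (`"A"`, `"B"`,
#'   or `NA` for zero correlation).
#' @export
expression_rhythm_correlation <- function(profile, taus, tau_threshold = 0.5,
                                          min_tissues = 4) {
  keep <- taus$gene_id[!is.na(taus$tau) & taus$tau > tau_threshold]
  profile |>
    filter(.data$gene_id %in% keep,
           is.finite(.data$mean_n), is.finite(.data$p_value)) |>
    group_by(.data$gene_id) |>
    filter(n() >= min_tissues) |>
    summarise(
      pearson = cor(.data$mean_n, .data$p_value, method = "pearson"),
      spearman = suppressWarnings(
        cor(.data$mean_n, .data$p_value, method = "spearman")),
      .groups = "drop"
    ) |>
    mutate(set = dplyr::case_when(
      .data$spearman < 0 ~ "A",
      .data$spearman > 0 ~ "B",
      TRUE ~ NA_character_
    ))
}
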