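#' Detect 24-h rhythmicity per gene
#'
#' Fits the cosinor model `y ~ a + b*cos(2*pi*t/P) + c*sin(2*pi*t/P)` at
#' the absolute sample hours — replicates and consecutive cycles enter as
#' additional observations of the same phase, which increases power, and
#' are never averaged.
#'
#' Two detectors are available:
#' \describe{
#'   \item{`cosinor_F`}{ordinary least squares; the p-value is the F-test
#'     of `(b, c) = (0, 0)` on 2 and `n - 3` degrees of freedom.}
#'   \item{`robust_regression_perm`}{the same harmonic design fitted by
#'     iteratively reweighted least squares with a Tukey bisquare loss
#'     (M-estimation); the statistic is the relative reduction in robust
#'     residual scale versus an intercept-only robust fit, and its p-value
#'     comes from permutations of the time labels (one shared permutation
#'     set across genes, fixed seed).}
#' }
#'
#' Abundances are log-transformed (`log1p`) by default, the usual
#' variance-stabilizing choice for expression data; pass
#' `transform = "none"` for already-symmetric signals. Missing values are
#' dropped per gene. Constant series get `p = 1` with a warning; genes with
#' fewer than 4 usable samples get `NA`.
#'
#' @param expr expression tibble (`gene_id` + sample columns).
#' @param meta metadata tibble (`sample_id`, `time_h`, `replicate`).
#' @param period_h rhythm period tested, hours.
#' @param detector `"cosinor_F"` or `"robust_regression_perm"`.
#' @param transform `"log1p"` or `"none"`.
#' @param n_perm permutations for the robust detector.
#' @param seed seed for the permutation set (mandatory for the robust
#'   detector so stochastic p-values are reproducible).
#' @return A tibble `gene_id`, `p_value`, `n_used`, `detector`, `period_h`.
#' @examples
#' sim <- simulate_timeseries(sim_config(n_genes = 30, seed = 2))
#' head(detect_rhythm(sim$expr, sim$meta))
#' @export
detect_rhythm <- function(expr, meta, period_h = 24,
                          detector = c("cosinor_F", "robust_regression_perm"),
                          transform = c("log1p", "none"),
                          n_perm = 1000, seed = 1L) {
  detector <- match.arg(detector)
  transform <- match.arg(transform)
  check_expr_meta(expr, meta)
  samples <- meta$sample_id
  y_mat <- as.matrix(expr[, samples])
  if (transform == "log1p") y_mat <- log1p(y_mat)
  t_h <- meta$time_h
  if (length(unique(t_h %% period_h)) < 2) {
    abort("Need >= 2 distinct time points within the period.")
  }
  omega <- 2 * pi / period_h
  X <- cbind(1, cos(omega * t_h), sin(omega * t_h))

  p <- if (detector == "cosinor_F") {
    cosinor_f_pvalues(y_mat, X)
  } else {
    robust_perm_pvalues(y_mat, X, n_perm = n_perm, seed = seed)
  }
  n_used <- rowSums(is.finite(y_mat))
  tibble(gene_id = expr$gene_id, p_value = p, n_used = n_used,
         detector = detector, period_h = period_h)
}

cosinor_f_pvalues <- function(y_mat, X) {
  n <- ncol(y_mat)
  p <- rep(NA_real_, nrow(y_mat))
  complete <- rowSums(!is.finite(y_mat)) == 0

  f_from_rss <- function(rss0, rss1, n_obs) {
    if (rss0 <= .Machine$double.eps * n_obs) return(1)  # constant series
    if (rss1 <= 0) return(0)
    f <- ((rss0 - rss1) / 2) / (rss1 / (n_obs - 3))
    pf(f, 2, n_obs - 3, lower.tail = FALSE)
  }

  if (any(complete)) {
    Yc <- y_mat[complete, , drop = FALSE]
    H <- X %*% solve(crossprod(X), t(X))
    fitted <- Yc %*% H
    rss1 <- rowSums((Yc - fitted)^2)
    rss0 <- rowSums((Yc - rowMeans(Yc))^2)
    p[complete] <- vapply(seq_along(rss1), function(i) {
      f_from_rss(rss0[i], rss1[i], n)
    }, numeric(1))
  }
  for (i in which(!complete)) {
    ok <- is.finite(y_mat[i, ])
    if (sum(ok) < 4) next
    y <- y_mat[i, ok]
    Xi <- X[ok, , drop = FALSE]
    fit <- stats::lm.fit(Xi, y)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    p[i] <- f_from_rss(rss0, rss1, sum(ok))
  }
  if (any(p == 1 & complete, na.rm = TRUE)) {
    n_const <- sum(p == 1 & rowSums(abs(y_mat - y_mat[, 1]) >
                                      .Machine$double.eps * 100) == 0,
                   na.rm = TRUE)
    if (n_const > 0) {
      warn(sprintf("%d constant series assigned p = 1.", n_const))
    }
  }
  p
}

robust_scale_stat <- function(y, X) {
  # non-convergence at maxit still yields a usable scale; only that
  # permutation's statistic is affected marginally
  s0 <- tryCatch(
    suppressWarnings(MASS::rlm(matrix(1, length(y), 1), y,
                               psi = MASS::psi.bisquare, maxit = 100)$s),
    error = function(e) sd(y))
  if (!is.finite(s0) || s0 <= 0) return(NA_real_)
  s1 <- tryCatch(
    suppressWarnings(MASS::rlm(X, y, psi = MASS::psi.bisquare,
                               maxit = 100)$s),
    error = function(e) {
      sqrt(sum(stats::lm.fit(X, y)$residuals^2) / (length(y) - ncol(X)))
    })
  1 - s1 / s0
}

robust_perm_pvalues <- function(y_mat, X, n_perm, seed) {
  set.seed(seed)
  n <- nrow(X)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  apply(y_mat, 1, function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 4) return(NA_real_)
    yi <- y[ok]
    if (sd(yi) <= .Machine$double.eps * 100) return(1)
    Xi <- X[ok, , drop = FALSE]
    obs <- robust_scale_stat(yi, Xi)
    if (!is.finite(obs)) return(NA_real_)
    null_stats <- vapply(perms, function(pm) {
      pm <- pm[pm <= sum(ok)]  # restrict to usable rows when NAs present
      robust_scale_stat(yi, Xi[pm, , drop = FALSE])
    }, numeric(1))
    (1 + sum(null_stats >= obs, na.rm = TRUE)) / (n_perm + 1)
  })
}

#' Combine dependent p-values by the empirical Brown's method
#'
#' Fisher's statistic `psi = -2 * sum(log p)` is chi-square with `2k`
#' degrees of freedom only when the k tests are independent. Brown's method
#' rescales the null using the covariance of the transformed data: each
#' underlying data row is mapped through its empirical CDF,
#' `w = -2 * log(ECDF)`, and the null mean and variance become `2k` and
#' `4k + 2 * sum_{i<j} cov(w_i, w_j)`. The combined p-value is the upper
#' tail of a scaled chi-square with `f = 2 * mean^2 / var` degrees of
#' freedom at `psi / c`, `c = var / (2 * mean)`. Independent rows recover
#' Fisher; perfectly duplicated rows collapse to the single-row p-value.
#'
#' @param pvals numeric vector of k p-values in (0, 1].
#' @param data numeric matrix with k rows, the data underlying each
#'   p-value (e.g. the probe-level expression values of one gene), used to
#'   estimate the dependence. Required for k >= 2.
#' @return A single combined p-value in \[0, 1\].
#' @examples
#' x <- matrix(rnorm(2 * 100), nrow = 2)
#' combine_pvalues_brown(c(0.5, 0.5), x)
#' @export
combine_pvalues_brown <- function(pvals, data = NULL) {
  k <- length(pvals)
  if (k == 0) abort("Need at least one p-value.")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  if (k == 1) return(pvals)
  if (is.null(data)) abort("`data` is required to estimate dependence for k >= 2.")
  data <- as.matrix(data)
  if (nrow(data) != k) {
    abort(sprintf("`data` must have %d rows, one per p-value.", k))
  }
  w <- t(apply(data, 1, function(x) {
    ok <- is.finite(x)
    e <- ecdf(x[ok])
    -2 * log(e(x[ok]))
  }))
  cov_w <- stats::cov(t(w))
  mean_psi <- 2 * k
  var_psi <- 4 * k + 2 * sum(cov_w[upper.tri(cov_w)])
  f <- 2 * mean_psi^2 / var_psi
  c_scale <- var_psi / (2 * mean_psi)
  if (f > 2 * k || c_scale < 1) {  # do not let noise make the test anti-conservative
    f <- 2 * k
    c_scale <- 1
  }
  psi <- -2 * sum(log(pvals))
  pchisq(psi / c_scale, df = f, lower.tail = FALSE)
}

#' Combine probe-level rhythm p-values per gene
#'
#' Applies [combine_pvalues_brown()] across the probes (or transcripts)
#' mapping to each gene, giving one rhythm p-value per gene.
#'
#' @param rhythm per-probe rhythm table (`gene_id`, `probe_id`, `p_value`).
#' @param expr probe-level expression tibble (`probe_id` + sample columns)
#'   supplying the dependence structure.
#' @return A tibble `gene_id`, `p_value`, `n_probes`.
#' @export
combine_rhythm_by_gene <- function(rhythm, expr) {
  if (!all(c("gene_id", "probe_id", "p_value") %in% names(rhythm))) {
    abort("`rhythm` needs columns `gene_id`, `probe_id`, `p_value`.")
  }
  value_cols <- setdiff(names(expr), c("gene_id", "probe_id"))
  rhythm |>
    filter(is.finite(.data$p_value)) |>
    group_by(.data$gene_id) |>
    group_modify(function(df, key) {
      rows <- match(df$probe_id, expr$probe_id)
      dat <- as.matrix(expr[rows, value_cols])
      p <- if (nrow(df) == 1) df$p_value else
        combine_pvalues_brown(pmin(pmax(df$p_value, 1e-300), 1), dat)
      tibble(p_value = p, n_probes = nrow(df))
    }) |>
    ungroup()
}

#' Diagnose a rhythm p-value distribution
#'
#' A healthy genome-wide scan yields p-values that are uniform except for
#' an excess near zero contributed by truly rhythmic genes. This check
#' flags scans whose distribution is skewed the wrong way (towards high
#' p-values), which indicates a mis-specified detector for that dataset.
#' The upper half (p > 0.5), where true signals contribute nothing, is
#' compared with Uniform(0.5, 1) by a Kolmogorov-Smirnov distance, and the
#' lowest histogram bin must be at least as full as the uniform
#' expectation.
#'
#' @param pvals at least 100 p-values.
#' @param n_bins histogram bins over \[0, 1\].
#' @param ks_threshold maximum acceptable KS distance for the upper half.
#' @return A list: `bin_counts`, `ks_distance`, `lowest_bin_enrichment`
#'   (observed / expected count in the first bin), `acceptable`.
#' @export
diagnose_pvalue_distribution <- function(pvals, n_bins = 20,
                                         ks_threshold = 0.1) {
  pvals <- pvals[is.finite(pvals)]
  if (length(pvals) < 100) abort("Need >= 100 p-values to diagnose.")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- as.vector(table(cut(pvals, breaks, include.lowest = TRUE)))
  upper <- pvals[pvals > 0.5]
  ks <- if (length(upper) >= 10) {
    suppressWarnings(unname(ks.test((upper - 0.5) / 0.5, "punif")$statistic))
  } else {
    1
  }
  enrich <- counts[1] / (length(pvals) / n_bins)
  list(bin_counts = counts,
       ks_distance = ks,
       lowest_bin_enrichment = enrich,
       acceptable = ks < ks_threshold && enrich >= 1)
}

#' Classify genes as rhythmic, non-rhythmic or ambiguous
#'
#' Two published conventions are supported. `threshold` calls a gene
#' rhythmic at `p <= p_rhythmic` and non-rhythmic at `p > p_flat`,
#' ignoring the intermediate band — reliable rhythmicity thresholds are
#' hard to set, so intermediate genes are excluded from two-group tests.
#' `top_fraction` ranks genes from most to least rhythmic and labels the
#' first `top_fraction` (default 15%) rhythmic, the rest non-rhythmic.
#' Ties are broken by gene id so ranks are a stable permutation.
#'
#' @param rhythm tibble with `gene_id` and `p_value`.
#' @param mode `"threshold"` or `"top_fraction"`.
#' @param p_rhythmic,p_flat thresholds for `threshold` mode.
#' @param top_fraction fraction labelled rhythmic in `top_fraction` mode.
#' @return `rhythm` with added `rank` and `class`
#'   (`rhythmic` / `non_rhythmic` / `ambiguous`).
#' @export
classify_rhythm <- function(rhythm, mode = c("threshold", "top_fraction"),
                            p_rhythmic = 0.01, p_flat = 0.5,
                            top_fraction = 0.15) {
  mode <- match.arg(mode)
  if (p_rhythmic > p_flat) {
    abort("`p_rhythmic` must be <= `p_flat`.")
  }
  ord <- order(rhythm$p_value, rhythm$gene_id)
  rank <- integer(nrow(rhythm))
  rank[ord] <- seq_len(nrow(rhythm))
  out <- mutate(rhythm, rank = rank)
  if (mode == "threshold") {
    out$class <- dplyr::case_when(
      !is.finite(out$p_value) ~ NA_character_,
      out$p_value <= p_rhythmic ~ "rhythmic",
      out$p_value > p_flat ~ "non_rhythmic",
      TRUE ~ "ambiguous"
    )
  } else {
    n_r <- floor(top_fraction * nrow(out))
    out$class <- ifelse(out$rank <= n_r, "rhythmic", "non_rhythmic")
    out$class[!is.finite(out$p_value)] <- NA_character_
  }
  out
}
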