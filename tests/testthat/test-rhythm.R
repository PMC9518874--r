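make_ts <- function(y_list, t_h) {
  expr <- tibble::tibble(gene_id = sprintf("g%02d", seq_along(y_list)))
  m <- do.call(rbind, y_list)
  colnames(m) <- sprintf("s%02d", seq_along(t_h))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(m))
  meta <- tibble::tibble(sample_id = colnames(m), time_h = t_h,
                         replicate = "r1")
  list(expr = expr, meta = meta)
}

test_that("a pure cosine is detected with a numerically zero p-value", {
  t_h <- seq(0, 46, by = 2)
  ts <- make_ts(list(cosine_series(t_h)), t_h)
  p <- detect_rhythm(ts$expr, ts$meta, transform = "none")$p_value
  expect_lt(p, 1e-10)
})

test_that("constant and short series follow the degenerate contracts", {
  t_h <- seq(0, 22, by = 2)
  ts <- make_ts(list(rep(3, 12), c(1, 2, 3, rep(NA, 9))), t_h)
  expect_warning(r <- detect_rhythm(ts$expr, ts$meta, transform = "none"),
                 "constant")
  expect_equal(r$p_value[1], 1)
  expect_true(is.na(r$p_value[2]))  # < 4 usable samples
})

test_that("missing values are tolerated per gene", {
  set.seed(1)
  t_h <- seq(0, 46, by = 2)
  y <- cosine_series(t_h, noise_sd = 0.1)
  y[c(3, 10)] <- NA
  ts <- make_ts(list(y), t_h)
  p <- detect_rhythm(ts$expr, ts$meta, transform = "none")$p_value
  expect_lt(p, 1e-6)
})

test_that("the robust permutation detector separates signal from noise", {
  set.seed(42)
  t_h <- rep(seq(0, 22, by = 2), 2)
  genes <- c(
    lapply(1:5, function(i) cosine_series(t_h, amplitude = 2, noise_sd = 0.3)),
    lapply(1:15, function(i) rnorm(length(t_h), 5, 0.5))
  )
  ts <- make_ts(genes, t_h)
  r <- detect_rhythm(ts$expr, ts$meta, detector = "robust_regression_perm",
                     transform = "none", n_perm = 200, seed = 7)
  expect_true(all(r$p_value[1:5] < 0.01))
  expect_gt(mean(r$p_value[6:20] > 0.05), 0.7)
  # stochastic p-values are reproducible under the same seed
  r2 <- detect_rhythm(ts$expr, ts$meta, detector = "robust_regression_perm",
                      transform = "none", n_perm = 200, seed = 7)
  expect_identical(r$p_value, r2$p_value)
})

test_that("increasing amplitude never worsens the median p-value", {
  amps <- c(0, 0.25, 0.5, 1, 2)
  med <- vapply(seq_along(amps), function(i) {
    cfg <- sim_config(n_genes = 300, rhythmic_fraction = 1,
                      amplitude_rel = amps[i], noise_sd = 0.5, seed = 77)
    sim <- simulate_timeseries(cfg)
    median(detect_rhythm(sim$expr, sim$meta)$p_value)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-12))
})

test_that("Brown combination matches its analytic limits", {
  # k = 1 passes through
  expect_equal(combine_pvalues_brown(0.37), 0.37)
  # independence: Fisher closed form
  set.seed(3)
  x <- matrix(rnorm(2 * 200), nrow = 2)
  fisher <- pchisq(-2 * sum(log(c(0.5, 0.5))), df = 4, lower.tail = FALSE)
  expect_equal(combine_pvalues_brown(c(0.5, 0.5), x), fisher,
               tolerance = 0.1)
  # perfect dependence: collapses to the single-row p
  dup <- rbind(x[1, ], x[1, ])
  expect_equal(combine_pvalues_brown(c(0.2, 0.2), dup), 0.2,
               tolerance = 0.02)
  # contracts
  expect_error(combine_pvalues_brown(numeric(0)), "at least one")
  expect_error(combine_pvalues_brown(c(0.5, 1.5), x), "\\(0, 1\\]")
  expect_error(combine_pvalues_brown(c(0.5, 0.5)), "data")
})

test_that("Brown never leaves [0,1] and discounts dependent evidence", {
  set.seed(11)
  for (i in 1:20) {
    shared <- rnorm(100)
    x <- rbind(shared + rnorm(100, 0, 0.2), shared + rnorm(100, 0, 0.2),
               rnorm(100))
    # in the significant regime, correlated tests carry less evidence
    # than Fisher assumes, so the combined p must not undercut Fisher
    p <- runif(3, 0.001, 0.05)
    b <- combine_pvalues_brown(p, x)
    expect_true(b >= 0 && b <= 1)
    fisher <- pchisq(-2 * sum(log(p)), df = 6, lower.tail = FALSE)
    expect_gte(b, fisher - 1e-12)
  }
})

test_that("per-gene combination over probes gives one p per gene", {
  sim <- simulate_timeseries(sim_config(n_genes = 6, seed = 2))
  probes <- sim$expr |>
    dplyr::rename(probe_id = gene_id) |>
    dplyr::mutate(gene_id = rep(c("gA", "gB", "gC"), each = 2),
                  .before = 1)
  per_probe <- detect_rhythm(dplyr::select(probes, -gene_id) |>
                               dplyr::rename(gene_id = probe_id),
                             sim$meta) |>
    dplyr::rename(probe_id = gene_id) |>
    dplyr::mutate(gene_id = rep(c("gA", "gB", "gC"), each = 2))
  comb <- combine_rhythm_by_gene(per_probe, probes)
  expect_equal(nrow(comb), 3)
  expect_true(all(comb$p_value >= 0 & comb$p_value <= 1))
  expect_true(all(comb$n_probes == 2))
})

test_that("p-value distribution diagnostics flag the pathological shapes", {
  set.seed(5)
  ok_null <- diagnose_pvalue_distribution(runif(2000))
  expect_true(ok_null$acceptable)
  expect_equal(ok_null$lowest_bin_enrichment, 1, tolerance = 0.25)

  mixture <- c(rbeta(400, 0.1, 10), runif(1600))
  ok_mix <- diagnose_pvalue_distribution(mixture)
  expect_true(ok_mix$acceptable)
  expect_gt(ok_mix$lowest_bin_enrichment, 1)

  skew_high <- rbeta(2000, 2, 1)  # mass at high p: detector mis-specified
  expect_false(diagnose_pvalue_distribution(skew_high)$acceptable)

  expect_error(diagnose_pvalue_distribution(runif(50)), ">= 100")
})

test_that("threshold classification applies the published rule", {
  rt <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       p_value = c(0.005, 0.3, 0.7))
  out <- classify_rhythm(rt, p_rhythmic = 0.01, p_flat = 0.5)
  expect_equal(out$class, c("rhythmic", "ambiguous", "non_rhythmic"))
  expect_error(classify_rhythm(rt, p_rhythmic = 0.6, p_flat = 0.5), "<=")
})

test_that("top-fraction classification takes exactly the first 15%", {
  rt <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                       p_value = seq(0.001, 1, length.out = 100))
  out <- classify_rhythm(rt, mode = "top_fraction", top_fraction = 0.15)
  expect_equal(sum(out$class == "rhythmic"), 15)
  expect_true(all(sort(out$rank) == 1:100))

  # ties broken by stable gene-id order
  tie <- tibble::tibble(gene_id = c("gB", "gA", "gC"), p_value = rep(0.5, 3))
  out_tie <- classify_rhythm(tie, mode = "top_fraction", top_fraction = 1 / 3)
  expect_equal(out_tie$class[out_tie$gene_id == "gA"], "rhythmic")
  expect_equal(sum(out_tie$class == "rhythmic"), 1)
})
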