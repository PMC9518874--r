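test_that("the expression filter applies the log10(FPKM+1) rule", {
  sc <- list(values = tibble::tibble(gene_id = c("g1", "g2", "g3"),
                                     c1 = c(0, 10^1.5, 100),
                                     c2 = c(0, 0, 5)),
             cells = tibble::tibble(cell_id = c("c1", "c2"),
                                    cell_type = "t"))
  kept <- filter_expressed(sc, threshold = 1.5)
  # log10(10^1.5 + 1) > 1.5, so g2 passes; all-zero g1 is dropped
  expect_equal(kept$values$gene_id, c("g2", "g3"))
  expect_equal(filter_expressed(sc, threshold = -Inf)$values$gene_id,
               sc$values$gene_id)
  expect_error(filter_expressed(sc, threshold = 10), "No gene")
})

test_that("cell-type-weighted moments match pooled ones for one type and a
           hand-computed two-type case", {
  cfg <- sim_config(n_genes = 20, n_cells = 50, seed = 6)
  sc <- simulate_single_cell(cfg)
  expect_equal(noise_stats(sc, mode = "by_cell_type"),
               noise_stats(sc, mode = "pooled"))

  sc$cells$cell_type <- rep(c("A", "B"), c(20, 30))
  ns <- noise_stats(sc, mode = "by_cell_type")
  m <- as.matrix(sc$values[, -1])
  mu_oracle <- (rowMeans(m[, 1:20]) * 20 + rowMeans(m[, 21:50]) * 30) / 50
  expect_equal(ns$mu, mu_oracle, tolerance = 1e-12)
})

test_that("genes on the fitted curve get F* = 1 and F* scales with sigma2", {
  set.seed(4)
  mu <- exp(seq(log(5), log(500), length.out = 60))
  stats <- tibble::tibble(gene_id = paste0("g", seq_along(mu)), mu = mu,
                          sigma2 = exp(1 + 1.3 * log(mu)))
  f1 <- fstar(stats, degree = 1)
  expect_equal(f1$fstar, rep(1, nrow(stats)), tolerance = 1e-8)

  noisy <- dplyr::mutate(stats, sigma2 = sigma2 * exp(rnorm(60, 0, 0.3)))
  fa <- fstar(noisy, degree = 1)
  doubled <- fstar(dplyr::mutate(noisy, sigma2 = sigma2 * 2), degree = 1)
  # doubling all variances doubles the numerator but also shifts the fit;
  # the ratio between genes is preserved exactly
  expect_equal(doubled$fstar / fa$fstar,
               rep((doubled$fstar / fa$fstar)[1], 60), tolerance = 1e-8)
})

test_that("auto degree selection decorrelates NB data from the mean", {
  cfg <- sim_config(n_genes = 800, n_cells = 300, nb_dispersion = 0.4,
                    baseline_log_mean = 4, baseline_log_sd = 1.5, seed = 5)
  ns <- noise_stats(simulate_single_cell(cfg))
  raw_kendall <- cor(ns$mu, ns$sigma2, method = "kendall")
  expect_gt(raw_kendall, 0.5)
  f <- fstar(ns, degree = "auto")
  expect_lt(abs(cor(f$fstar, f$mu, method = "kendall")), 0.05)
  diag <- attr(f, "diagnostics")
  expect_equal(sum(diag$selected), 1)
})

test_that("degree selection finds the generating polynomial order", {
  set.seed(8)
  lmu <- seq(log(2), log(2000), length.out = 200)
  mu <- exp(lmu)
  linear <- tibble::tibble(gene_id = paste0("g", 1:200), mu = mu,
                           sigma2 = exp(0.5 + 1.8 * lmu + rnorm(200, 0, 0.2)))
  expect_equal(fstar(linear, degree = "auto")$degree_selected[1], 1L)

  # skewed mean distribution: curvature missed by the linear fit shows up
  # as a residual-mean association the diagnostics must catch
  set.seed(8)
  lmu <- sort(log(rlnorm(200, 2, 1.2)))
  mu <- exp(lmu)
  quad <- tibble::tibble(gene_id = paste0("g", 1:200), mu = mu,
                         sigma2 = exp(0.5 + 0.2 * lmu + 0.4 * lmu^2 +
                                        rnorm(200, 0, 0.2)))
  fq <- fstar(quad, degree = "auto")
  expect_gte(fq$degree_selected[1], 2L)
  diag <- attr(fq, "diagnostics")
  d1 <- diag[diag$degree == 1, ]
  expect_true(abs(d1$kendall) >= 0.05 || abs(d1$slope) >= 0.05)

  # all candidates tie (already decorrelated): lowest degree wins
  flat <- lapply(1:3, function(d) rep(1, 200))
  expect_equal(select_degree(1:3, flat, mu)$degree, 1L)
})

test_that("noise contrasts recover the planted low-noise rhythmic set", {
  hits <- vapply(1:20, function(i) {
    cfg <- sim_config(n_genes = 600, n_cells = 200, noise_coupling = 0.6,
                      nb_dispersion = 0.6, baseline_log_mean = 4,
                      baseline_log_sd = 1, rhythmic_fraction = 0.3,
                      seed = 600 + i)
    sc <- simulate_single_cell(cfg)
    f <- fstar(noise_stats(sc), degree = "auto")
    cmp <- compare_noise(f, truth_classes(sc$truth, "is_rhythmic_rna"),
                         category = "a")
    cmp$p_value < 0.05 && cmp$direction == "lower"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("noise contrasts are null-calibrated without coupling", {
  pvals <- vapply(1:40, function(i) {
    cfg <- sim_config(n_genes = 400, n_cells = 150, noise_coupling = 0,
                      nb_dispersion = 0.6, baseline_log_mean = 4,
                      baseline_log_sd = 1, rhythmic_fraction = 0.3,
                      seed = 700 + i)
    sc <- simulate_single_cell(cfg)
    f <- fstar(noise_stats(sc), degree = 2)
    compare_noise(f, truth_classes(sc$truth, "is_rhythmic_rna"),
                  category = "a")$p_value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.2)  # ~alpha at 40 reps
  expect_gt(mean(pvals < 0.05), 0)    # never pathologically conservative...
})

test_that("conditioned categories build the right groups and fail loudly", {
  cfg <- sim_config(n_genes = 300, n_cells = 100, baseline_log_mean = 4,
                    seed = 3)
  sc <- simulate_single_cell(cfg)
  f <- fstar(noise_stats(sc), degree = 2)
  rna <- truth_classes(sc$truth, "is_rhythmic_rna")
  prot <- truth_classes(sc$truth, "is_rhythmic_protein")
  for (cc in c("a", "b", "c", "d", "e")) {
    cmp <- compare_noise(f, rna, prot, category = cc)
    expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  }
  # category c restricted to rhythmic proteins must be smaller than a
  cmp_a <- compare_noise(f, rna, prot, category = "a")
  cmp_c <- compare_noise(f, rna, prot, category = "c")
  expect_lte(cmp_c$n_rhythmic + cmp_c$n_other,
             cmp_a$n_rhythmic + cmp_a$n_other)

  prot_empty <- dplyr::mutate(prot, class = "non_rhythmic")
  expect_error(compare_noise(f, rna, prot_empty, category = "c"),
               "category 'c'")
  expect_error(compare_noise(f, rna, NULL, category = "b"), "protein")
})
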