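test_that("residualization satisfies the OLS identities", {
  set.seed(6)
  n <- 200
  expr <- rlnorm(n, 3, 1)
  dnds <- tibble::tibble(gene_id = paste0("g", 1:n),
                         dnds = exp(-1 - 0.2 * log(expr) + rnorm(n, 0, 0.3)))
  res <- residualize_dnds(dnds, tibble::tibble(gene_id = dnds$gene_id,
                                               expression = expr))
  expect_lt(abs(sum(res$residual)), 1e-9)
  expect_lt(abs(cor(res$residual, log(expr))), 1e-9)

  # noiseless: residuals identically zero, slope recovered exactly
  exact <- tibble::tibble(gene_id = dnds$gene_id,
                          dnds = exp(-1 - 0.2 * log(expr)))
  res0 <- residualize_dnds(exact, tibble::tibble(gene_id = dnds$gene_id,
                                                 expression = expr))
  expect_lt(max(abs(res0$residual)), 1e-10)
  expect_equal(attr(res0, "slope"), -0.2, tolerance = 1e-10)
})

test_that("the regression recovers a planted slope at scale", {
  cfg <- sim_config(n_genes = 5000, dnds_beta = -0.2, dnds_noise_sd = 0.3,
                    n_timepoints = 2, n_cycles = 1, seed = 15)
  sim <- simulate_timeseries(cfg)
  expr <- exp(sim$truth$baseline_log)
  dn <- simulate_dnds(cfg, sim$truth, expr)
  res <- residualize_dnds(dn, tibble::tibble(gene_id = dn$gene_id,
                                             expression = expr))
  expect_lt(abs(attr(res, "slope") - (-0.2)), 0.02)
})

test_that("residuals are invariant to rescaling expression", {
  set.seed(7)
  expr <- rlnorm(100, 2, 1)
  dn <- tibble::tibble(gene_id = paste0("g", 1:100),
                       dnds = exp(-1 - 0.3 * log(expr) + rnorm(100, 0, 0.2)))
  r1 <- residualize_dnds(dn, tibble::tibble(gene_id = dn$gene_id,
                                            expression = expr))
  r2 <- residualize_dnds(dn, tibble::tibble(gene_id = dn$gene_id,
                                            expression = expr * 1000))
  expect_equal(r1$residual, r2$residual, tolerance = 1e-10)
})

test_that("Welch machinery matches the textbook formula", {
  x <- c(1.1, 2.3, 0.7, 1.9, 1.5)
  y <- c(2.8, 3.1, 2.2, 3.6)
  cmp <- welch_compare(c(x, y), rep(c(TRUE, FALSE), c(5, 4)),
                       log_transform = FALSE)
  s2x <- var(x) / length(x)
  s2y <- var(y) / length(y)
  t_oracle <- (mean(x) - mean(y)) / sqrt(s2x + s2y)
  df_oracle <- (s2x + s2y)^2 /
    (s2x^2 / (length(x) - 1) + s2y^2 / (length(y) - 1))
  expect_equal(cmp$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(cmp$df, df_oracle, tolerance = 1e-10)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_oracle), df_oracle),
               tolerance = 1e-10)
  expect_equal(cmp$direction, "lower")
})

test_that("identical groups give a null comparison", {
  v <- rep(c(1, 2, 3, 4), 2)
  cmp <- welch_compare(v, rep(c(TRUE, FALSE), each = 4),
                       log_transform = FALSE)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)
})

test_that("uncontrolled contrast is confounded, controlled one is calibrated", {
  reps <- 60
  rej <- matrix(NA, reps, 2)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_genes = 2000, rhythmic_fraction = 0.2,
                      cost_coupling = 1, dnds_beta = -0.2, dnds_gamma = 0,
                      dnds_noise_sd = 0.5, n_timepoints = 2, n_cycles = 1,
                      seed = 2000 + i)
    sim <- simulate_timeseries(cfg)
    expr <- exp(sim$truth$baseline_log +
                  cfg$cost_coupling * sim$truth$is_rhythmic_rna)
    dn <- simulate_dnds(cfg, sim$truth, expr, seed = cfg$seed + 1)
    cl <- truth_classes(sim$truth)
    expr_tbl <- tibble::tibble(gene_id = dn$gene_id, expression = expr)
    rej[i, 1] <- compare_dnds(dn, cl, category = "a")$p_value < 0.05
    rej[i, 2] <- compare_dnds(dn, cl, category = "a", controlled = TRUE,
                              expression = expr_tbl)$p_value < 0.05
  }
  expect_gt(mean(rej[, 1]), 0.5)       # confounding drives rejections
  expect_lt(mean(rej[, 2]), 0.15)      # control restores ~alpha
})

test_that("a planted rhythmicity effect on dN/dS is detected with its sign", {
  hits <- vapply(1:30, function(i) {
    cfg <- sim_config(n_genes = 5000, rhythmic_fraction = 0.2,
                      cost_coupling = 1, dnds_beta = -0.2,
                      dnds_gamma = -0.3, dnds_noise_sd = 0.5,
                      n_timepoints = 2, n_cycles = 1, seed = 3000 + i)
    sim <- simulate_timeseries(cfg)
    expr <- exp(sim$truth$baseline_log +
                  cfg$cost_coupling * sim$truth$is_rhythmic_rna)
    dn <- simulate_dnds(cfg, sim$truth, expr, seed = cfg$seed + 1)
    cmp <- compare_dnds(dn, truth_classes(sim$truth), category = "a",
                        controlled = TRUE,
                        expression = tibble::tibble(gene_id = dn$gene_id,
                                                    expression = expr))
    cmp$p_value < 0.05 && cmp$direction == "lower"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("set contrasts enforce their contracts", {
  dn <- tibble::tibble(gene_id = paste0("g", 1:40), dnds = rlnorm(40, -2, 0.5))
  expect_error(compare_dnds_sets(c("g1", "g2"), c("g2", "g3"), dn),
               "disjoint")
  expect_error(compare_dnds_sets("g1", "g2", dn), ">= 2")
  cmp <- compare_dnds_sets(paste0("g", 1:20), paste0("g", 21:40), dn)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})
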