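#' Simulate a rhythmic expression time series
#'
#' Generates a gene-by-sample abundance matrix with a planted rhythmic
#' subset. A rhythmic gene follows
#' `log N(t) = b + A * cos(2*pi*(t - phase)/period) + e`,
#' with `e ~ Normal(0, noise_sd)`; non-rhythmic genes omit the cosine.
#' Phases are Uniform(0, period): peak times of real rhythmic transcripts
#' are dispersed across the day, and uniform is the maximum-entropy choice.
#' Replicates are independent noise realizations of the same deterministic
#' curve and enter as additional cycles, mirroring how the detectors use
#' them. A positive `cost_coupling` shifts the log baseline of rhythmic
#' genes upward, planting the association between rhythmicity and high
#' expression.
#'
#' @param config a [sim_config()].
#' @param level `"mRNA"` or `"protein"`; selects which truth flag drives the
#'   cosine term.
#' @param truth optional truth table from a previous call, so mRNA and
#'   protein matrices for the same genes share phases and baselines.
#' @param seed seed for this call; defaults to `config$seed`.
#'
#' @return A list with `expr` (tibble: `gene_id` + one column per sample),
#'   `meta` (tibble: `sample_id`, `time_h`, `replicate`), and `truth`
#'   (tibble: `gene_id`, `is_rhythmic_rna`, `is_rhythmic_protein`,
#'   `phase_h`, `amplitude`, `baseline_log`, `planted_low_noise`).
#' @examples
#' sim <- simulate_timeseries(sim_config(n_genes = 50, seed = 7))
#' dim(sim$expr)
#' @export
simulate_timeseries <- function(config,
                                level = c("mRNA", "protein"),
                                truth = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  level <- match.arg(level)
  set.seed(seed)
  if (is.null(truth)) truth <- draw_truth(config)

  meta <- sim_sample_sheet(config)
  flag <- if (level == "mRNA") truth$is_rhythmic_rna else
    truth$is_rhythmic_protein

  base <- truth$baseline_log + config$cost_coupling * flag
  omega <- 2 * pi / config$period_h
  phase <- ifelse(is.na(truth$phase_h), 0, truth$phase_h)
  # deterministic curve: genes x samples
  curve <- outer(truth$amplitude * flag, rep(1, nrow(meta))) *
    cos(omega * outer(phase, meta$time_h, function(p, t) t - p))
  logx <- base + curve +
    matrix(rnorm(config$n_genes * nrow(meta), 0, config$noise_sd),
           nrow = config$n_genes)
  values <- exp(logx)

  expr <- bind_cols(
    tibble(gene_id = truth$gene_id),
    as_tibble(`colnames<-`(values, meta$sample_id))
  )
  list(expr = expr, meta = meta, truth = truth)
}

draw_truth <- function(config) {
  ids <- sprintf("g%0*d", nchar(config$n_genes), seq_len(config$n_genes))
  rf <- if (config$amplitude_rel == 0) 0 else config$rhythmic_fraction
  is_r_rna <- runif(config$n_genes) < rf
  is_r_prot <- runif(config$n_genes) < rf
  any_r <- is_r_rna | is_r_prot
  phase <- ifelse(any_r, runif(config$n_genes, 0, config$period_h), NA_real_)
  tibble(
    gene_id = ids,
    is_rhythmic_rna = is_r_rna,
    is_rhythmic_protein = is_r_prot,
    phase_h = phase,
    amplitude = ifelse(any_r, config$amplitude_rel, 0),
    baseline_log = rnorm(config$n_genes, config$baseline_log_mean,
                         config$baseline_log_sd),
    planted_low_noise = is_r_rna
  )
}

sim_sample_sheet <- function(config) {
  grid <- expand.grid(
    tp = seq_len(config$n_timepoints),
    cycle = seq_len(config$n_cycles),
    rep = seq_len(config$n_replicates)
  )
  grid <- grid[order(grid$rep, grid$cycle, grid$tp), ]
  time_h <- (grid$cycle - 1) * config$period_h +
    (grid$tp - 1) * config$sampling_interval_h
  tibble(
    sample_id = sprintf("r%d_c%d_t%02d", grid$rep, grid$cycle, grid$tp),
    time_h = time_h,
    replicate = paste0("r", grid$rep)
  )
}

#' Simulate multi-tissue expression with tissue-specific rhythmicity
#'
#' Each tissue gets its own time series over the same genes. A
#' `tissue_specific_fraction` of genes receives an elevated baseline
#' (`tissue_effect`, log scale) in one home tissue. Rhythmicity is assigned
#' per gene and tissue; with probability `1 - exp(-tissue_coupling)` a
#' tissue-specific gene has tissue-specific rhythmicity: it is rhythmic in
#' its home tissue and nowhere else. Otherwise all tissues draw
#' independently at `rhythmic_fraction` — so `tissue_coupling = 0` is an
#' exact null in which rhythmicity carries no information about where a
#' gene is highly expressed, and large coupling plants both "genes are
#' rhythmic where they are highly expressed" and the negative relation
#' between rhythmic breadth and tissue-specificity.
#'
#' @inheritParams simulate_timeseries
#' @return A list with `tissues` (named list; each element a list with
#'   `expr` and `meta`), `truth` (gene-level tibble with `tissue_specific`,
#'   `home_tissue`), and `truth_tissue` (long tibble: `gene_id`, `tissue`,
#'   `is_rhythmic`, `baseline_shift`).
#' @export
simulate_multitissue <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 2) abort("`n_tissues` must be >= 2.")
  set.seed(seed)
  n <- config$n_genes
  nt <- config$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(nt))
  ids <- sprintf("g%0*d", nchar(n), seq_len(n))

  specific <- runif(n) < config$tissue_specific_fraction
  home <- sample(tissues, n, replace = TRUE)
  phase <- runif(n, 0, config$period_h)
  baseline <- rnorm(n, config$baseline_log_mean, config$baseline_log_sd)

  w <- 1 - exp(-config$tissue_coupling)
  aligned <- specific & (runif(n) < w)
  rhythm <- matrix(runif(n * nt) < config$rhythmic_fraction, n, nt,
                   dimnames = list(ids, tissues))
  rhythm[aligned, ] <- FALSE
  rhythm[cbind(which(aligned), match(home[aligned], tissues))] <- TRUE

  shift <- matrix(0, n, nt, dimnames = list(ids, tissues))
  shift[cbind(which(specific), match(home[specific], tissues))] <-
    config$tissue_effect

  omega <- 2 * pi / config$period_h
  meta <- sim_sample_sheet(config)
  tissue_list <- lapply(seq_len(nt), function(j) {
    curve <- outer(config$amplitude_rel * rhythm[, j], rep(1, nrow(meta))) *
      cos(omega * outer(phase, meta$time_h, function(p, t) t - p))
    logx <- baseline + shift[, j] + curve +
      matrix(rnorm(n * nrow(meta), 0, config$noise_sd), nrow = n)
    expr <- bind_cols(tibble(gene_id = ids),
                      as_tibble(`colnames<-`(exp(logx), meta$sample_id)))
    list(expr = expr, meta = meta)
  })
  names(tissue_list) <- tissues

  truth <- tibble(gene_id = ids, tissue_specific = specific,
                  home_tissue = ifelse(specific, home, NA_character_),
                  phase_h = phase, baseline_log = baseline)
  truth_tissue <- tibble(
    gene_id = rep(ids, nt),
    tissue = rep(tissues, each = n),
    is_rhythmic = as.vector(rhythm),
    baseline_shift = as.vector(shift)
  )
  list(tissues = tissue_list, truth = truth, truth_tissue = truth_tissue)
}

#' Simulate a single-cell expression matrix
#'
#' Per-gene counts across cells follow a negative-binomial model with
#' `Var = mu + phi * mu^2`, the standard overdispersion law for single-cell
#' RNA-seq, which gives the monotone mean-variance relation the F*
#' decorrelation step must remove. Genes flagged `planted_low_noise` in the
#' truth table get dispersion `phi * (1 - noise_coupling)`, planting lower
#' cell-to-cell variability for (by default) genes with rhythmic
#' transcripts. Values are returned on an FPKM-like scale: abundances are
#' used as-is by the expression filter.
#'
#' @inheritParams simulate_timeseries
#' @param truth truth table; if `NULL` one is drawn from `config`.
#' @return A list with `values` (tibble: `gene_id` + one column per cell),
#'   `cells` (tibble: `cell_id`, `cell_type`) and `truth`.
#' @export
simulate_single_cell <- function(config, truth = NULL,
                                 seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cells < 20) abort("`n_cells` must be >= 20.")
  if (config$noise_coupling < 0 || config$noise_coupling >= 1) {
    abort("`noise_coupling` must lie in [0, 1).")
  }
  set.seed(seed)
  if (is.null(truth)) truth <- draw_truth(config)
  n <- nrow(truth)
  mu <- exp(truth$baseline_log)
  phi <- config$nb_dispersion *
    (1 - config$noise_coupling * truth$planted_low_noise)
  counts <- t(vapply(seq_len(n), function(i) {
    if (phi[i] < 1e-12) {
      stats::rpois(config$n_cells, mu[i])
    } else {
      rnbinom(config$n_cells, mu = mu[i], size = 1 / phi[i])
    }
  }, numeric(config$n_cells)))
  cell_ids <- sprintf("cell%0*d", nchar(config$n_cells),
                      seq_len(config$n_cells))
  values <- bind_cols(tibble(gene_id = truth$gene_id),
                      as_tibble(`colnames<-`(counts, cell_ids)))
  cells <- tibble(cell_id = cell_ids, cell_type = "simulated")
  list(values = values, cells = cells, truth = truth)
}

#' Simulate per-gene dN/dS coupled to expression and rhythmicity
#'
#' `log(dN/dS) = alpha + beta * log(expr) + gamma * rhythmic + e`, with
#' `e ~ Normal(0, dnds_noise_sd)`. A negative `beta` reproduces the
#' universal negative expression-conservation relationship; a negative
#' `gamma` plants stronger purifying selection on rhythmic genes over and
#' above their expression level, which is exactly what the
#' residual-controlled comparison must isolate.
#'
#' @inheritParams simulate_timeseries
#' @param truth truth table providing gene ids and rhythm flags.
#' @param expression per-gene mean expression level (strictly positive),
#'   aligned with `truth$gene_id`.
#' @param flag which truth column marks rhythmicity; default
#'   `"is_rhythmic_rna"`.
#' @return A tibble `gene_id`, `dnds`.
#' @export
simulate_dnds <- function(config, truth, expression,
                          flag = "is_rhythmic_rna",
                          seed = config$seed + 5L) {
  stopifnot(inherits(config, "sim_config"))
  if (any(!is.finite(expression)) || any(expression <= 0)) {
    abort("`expression` must be strictly positive and finite.")
  }
  if (length(expression) != nrow(truth)) {
    abort("`expression` must align with `truth` rows.")
  }
  set.seed(seed)
  r <- as.numeric(truth[[flag]])
  log_dnds <- config$dnds_alpha + config$dnds_beta * log(expression) +
    config$dnds_gamma * r + rnorm(nrow(truth), 0, config$dnds_noise_sd)
  tibble(gene_id = truth$gene_id, dnds = exp(log_dnds))
}

#' Simulate a proteome of random amino-acid sequences
#'
#' Sequence lengths are log-normal around `mean_length` (protein length
#' distributions are right-skewed); residues are drawn i.i.d. from typical
#' proteome-wide amino-acid frequencies. Used by the cost stage so the full
#' pipeline runs without external FASTA input.
#'
#' @inheritParams simulate_timeseries
#' @param truth truth table providing gene ids.
#' @param mean_length median sequence length in residues.
#' @return A tibble `protein_id`, `sequence`, `length`.
#' @export
simulate_proteome <- function(config, truth, mean_length = 350,
                              seed = config$seed + 4L) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  # approximate vertebrate proteome composition
  freq <- c(7.0, 5.6, 3.6, 4.7, 2.3, 4.8, 7.1, 6.6, 2.6, 4.3,
            10.0, 5.7, 2.1, 3.7, 6.3, 8.3, 5.3, 1.2, 2.7, 6.1)
  len <- pmax(30L, as.integer(round(rlnorm(nrow(truth),
                                           log(mean_length), 0.4))))
  seqs <- vapply(len, function(L) {
    paste(sample(aa, L, replace = TRUE, prob = freq), collapse = "")
  }, character(1))
  tibble(protein_id = truth$gene_id, sequence = seqs, length = len)
}
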