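#' Pipeline run configuration
#'
#' Validates and bundles everything [run_all()] needs. The default mode
#' simulates its own inputs from a [sim_config()], so the whole pipeline is
#' reproducible from a single seed; alternatively, paths to on-disk inputs
#' can be given for the RNA/protein time series, FASTA, single-cell matrix
#' and dN/dS table.
#'
#' @param outdir output directory (created if missing).
#' @param sim a [sim_config()] (or list of its arguments) for simulated
#'   inputs; `NULL` to run from files.
#' @param paths named list of input paths for file mode: `rna_expr`,
#'   `rna_meta`, `protein_expr`, `protein_meta`, `fasta`, `sc`, `dnds`
#'   (+ optional `sc_genes`, `sc_cells` for MTX input).
#' @param detector rhythm detector (see [detect_rhythm()]).
#' @param p_rhythmic,p_flat RNA-level class thresholds; genes in between
#'   are ambiguous and excluded from contrasts.
#' @param protein_p_rhythmic,protein_p_flat protein-level thresholds
#'   (proteomics rhythms are harder to detect, so the conventional cut is
#'   laxer: 0.05).
#' @param top_fraction fraction labelled rhythmic for the ranking-based
#'   cost comparison.
#' @param tissue_blacklist tissues excluded from the multi-tissue stage.
#' @param noise_filter threshold for [filter_expressed()].
#' @param min_cells cell-type filter for [filter_cell_types()].
#' @param degree polynomial degree policy for [fstar()].
#' @param noise_categories,selection_categories contrast designs to run.
#' @param seed master seed; every stage derives its own stream from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(outdir,
                       sim = sim_config(),
                       paths = NULL,
                       detector = "cosinor_F",
                       p_rhythmic = 0.01, p_flat = 0.5,
                       protein_p_rhythmic = 0.05, protein_p_flat = 0.5,
                       top_fraction = 0.15,
                       tissue_blacklist = character(),
                       noise_filter = 1.5,
                       min_cells = 20,
                       degree = "auto",
                       noise_categories = c("a", "b", "c", "d", "e"),
                       selection_categories = c("a", "b", "c", "d"),
                       seed = 1L) {
  if (p_rhythmic > p_flat) abort("`p_rhythmic` must be <= `p_flat`.")
  if (protein_p_rhythmic > protein_p_flat) {
    abort("`protein_p_rhythmic` must be <= `protein_p_flat`.")
  }
  if (is.null(sim) && is.null(paths)) {
    abort("Provide either `sim` or `paths`.")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  if (!is.null(paths)) {
    required <- c("rna_expr", "rna_meta")
    missing <- setdiff(required, names(paths))
    if (length(missing)) {
      abort(sprintf("`paths` is missing: %s", paste(missing, collapse = ", ")))
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) abort(sprintf("Input path does not exist: %s", p))
    }
  }
  structure(
    list(outdir = outdir, sim = sim, paths = paths, detector = detector,
         p_rhythmic = p_rhythmic, p_flat = p_flat,
         protein_p_rhythmic = protein_p_rhythmic,
         protein_p_flat = protein_p_flat,
         top_fraction = top_fraction, tissue_blacklist = tissue_blacklist,
         noise_filter = noise_filter, min_cells = min_cells,
         degree = degree, noise_categories = noise_categories,
         selection_categories = selection_categories,
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; a `sim:` mapping
#' holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param outdir overrides the YAML `outdir` if given.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(outdir)) y$outdir <- outdir
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Orchestrates the stages end to end: rhythm detection and classification
#' at both molecular levels, expression-cost comparison, the multi-tissue
#' delta and tau analyses, single-cell noise contrasts, and the dN/dS
#' contrasts (raw and expression-controlled). Writes one TSV per stage plus
#' `report.tsv` (every group contrast with sizes, direction and p-value)
#' and `manifest.json` (seed, thresholds, per-stage gene counts, package
#' version). A stage failure aborts with the stage name and removes partial
#' outputs. Two runs with the same configuration produce byte-identical
#' bundles.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(tbl, name) {
    path <- file.path(config$outdir, name)
    readr::write_tsv(tbl, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  seed <- config$seed

  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      rna <- simulate_timeseries(cfg, level = "mRNA", seed = seed)
      prot <- simulate_timeseries(cfg, level = "protein",
                                  truth = rna$truth, seed = seed + 1L)
      mt <- simulate_multitissue(cfg, seed = seed + 2L)
      sc <- simulate_single_cell(cfg, truth = rna$truth, seed = seed + 3L)
      proteome <- simulate_proteome(cfg, rna$truth, seed = seed + 4L)
      expr_level <- tibble(gene_id = rna$truth$gene_id,
                           expression = exp(rna$truth$baseline_log +
                                              cfg$cost_coupling *
                                              rna$truth$is_rhythmic_rna))
      dnds <- simulate_dnds(cfg, rna$truth, expr_level$expression,
                            seed = seed + 5L)
      list(rna = rna, prot = prot, mt = mt, sc = sc, proteome = proteome,
           dnds = dnds)
    } else {
      p <- config$paths
      rna <- read_expression_tsv(p$rna_expr, p$rna_meta)
      prot <- if (!is.null(p$protein_expr)) {
        read_expression_tsv(p$protein_expr, p$protein_meta)
      }
      proteome <- if (!is.null(p$fasta)) read_fasta(p$fasta)
      sc <- if (!is.null(p$sc)) {
        read_single_cell(p$sc, p$sc_genes, p$sc_cells)
      }
      dnds <- if (!is.null(p$dnds)) read_dnds(p$dnds)
      list(rna = rna, prot = prot, mt = NULL, sc = sc, proteome = proteome,
           dnds = dnds)
    }
  })

  rhythm_rna <- stage("rhythm_rna", {
    detect_rhythm(inputs$rna$expr, inputs$rna$meta,
                  detector = config$detector, seed = seed + 10L) |>
      classify_rhythm(p_rhythmic = config$p_rhythmic, p_flat = config$p_flat)
  })
  emit(rhythm_rna, "rhythm_rna.tsv")

  rhythm_prot <- stage("rhythm_protein", {
    if (is.null(inputs$prot)) return(NULL)
    detect_rhythm(inputs$prot$expr, inputs$prot$meta,
                  detector = config$detector, seed = seed + 11L) |>
      classify_rhythm(p_rhythmic = config$protein_p_rhythmic,
                      p_flat = config$protein_p_flat)
  })
  if (!is.null(rhythm_prot)) emit(rhythm_prot, "rhythm_protein.tsv")

  report <- list()

  cost <- stage("cost", {
    if (is.null(inputs$proteome) || is.null(inputs$prot)) return(NULL)
    ct <- cost_table(inputs$proteome, inputs$prot$expr)
    rank_classes <- classify_rhythm(
      detect_rhythm(inputs$prot$expr, inputs$prot$meta,
                    detector = config$detector, seed = seed + 11L),
      mode = "top_fraction", top_fraction = config$top_fraction)
    list(table = ct, comparisons = compare_costs(ct, rank_classes))
  })
  if (!is.null(cost)) {
    emit(cost$table, "cost.tsv")
    report$cost <- cost$comparisons
  }

  tissue <- stage("tissue", {
    if (is.null(inputs$mt)) return(NULL)
    tissues <- inputs$mt$tissues
    rhythm_by_tissue <- purrr::map(tissues, function(ts) {
      detect_rhythm(ts$expr, ts$meta, detector = config$detector,
                    seed = seed + 12L) |>
        classify_rhythm(p_rhythmic = config$p_rhythmic,
                        p_flat = config$p_flat)
    })
    profile <- tissue_profile(tissues, rhythm_by_tissue,
                              blacklist = config$tissue_blacklist)
    deltas <- delta_expression(profile)
    taus <- tau_index(profile)
    list(profile = profile, deltas = deltas, taus = taus,
         delta_test = test_delta(deltas),
         tau_cor = tau_vs_rhythmic_breadth(taus, profile,
                                           p_rhythmic = config$p_rhythmic),
         gene_sets = expression_rhythm_correlation(profile, taus))
  })
  if (!is.null(tissue)) {
    emit(inner_join(tissue$deltas, tissue$taus, by = "gene_id"),
         "tissue.tsv")
  }

  noise <- stage("noise", {
    if (is.null(inputs$sc)) return(NULL)
    sc <- filter_cell_types(inputs$sc, min_cells = config$min_cells)
    sc <- filter_expressed(sc, threshold = config$noise_filter)
    nt <- fstar(noise_stats(sc), degree = config$degree)
    comps <- purrr::map_dfr(config$noise_categories, function(cc) {
      tryCatch(compare_noise(nt, rhythm_rna, rhythm_prot, category = cc),
               error = function(e) tibble(category = paste0("noise_", cc)))
    })
    list(table = nt, comparisons = comps)
  })
  if (!is.null(noise)) {
    emit(tibble::as_tibble(unclass(noise$table)), "noise.tsv")
    report$noise <- noise$comparisons
  }

  selection <- stage("selection", {
    if (is.null(inputs$dnds)) return(NULL)
    expr_cov <- tibble(
      gene_id = inputs$rna$expr$gene_id,
      expression = apply(as.matrix(inputs$rna$expr[, -1]), 1,
                         mean_abundance))
    comps <- purrr::map_dfr(config$selection_categories, function(cc) {
      bind_rows(
        tryCatch(compare_dnds(inputs$dnds, rhythm_rna, rhythm_prot,
                              category = cc, controlled = FALSE),
                 error = function(e) tibble(category = paste0("dnds_", cc))),
        tryCatch(compare_dnds(inputs$dnds, rhythm_rna, rhythm_prot,
                              category = cc, controlled = TRUE,
                              expression = expr_cov),
                 error = function(e) tibble(category = paste0("dnds_", cc)))
      )
    })
    sets <- if (!is.null(tissue)) {
      a <- tissue$gene_sets$gene_id[tissue$gene_sets$set %in% "A"]
      b <- tissue$gene_sets$gene_id[tissue$gene_sets$set %in% "B"]
      if (length(a) >= 2 && length(b) >= 2) {
        tryCatch(compare_dnds_sets(a, b, inputs$dnds),
                 error = function(e) NULL)
      }
    }
    list(comparisons = comps, set_comparison = sets)
  })
  if (!is.null(selection)) {
    emit(selection$comparisons, "selection.tsv")
    report$selection <- selection$comparisons
    if (!is.null(selection$set_comparison)) {
      report$sets <- selection$set_comparison
    }
  }

  report_tbl <- bind_rows(report)
  if (nrow(report_tbl) > 0 && "p_value" %in% names(report_tbl)) {
    # raw p-values are the primary presentation; BH column is advisory
    report_tbl$p_bh <- p.adjust(report_tbl$p_value, method = "BH")
  }
  if (!is.null(tissue)) {
    report_tbl <- bind_rows(
      report_tbl,
      tibble(category = "delta_vs_zero",
             n_rhythmic = tissue$delta_test$n, n_other = NA_integer_,
             mean_rhythmic = tissue$delta_test$mean_delta,
             mean_other = 0,
             statistic = tissue$delta_test$statistic,
             df = tissue$delta_test$df,
             p_value = tissue$delta_test$p_value,
             direction = ifelse(tissue$delta_test$mean_delta > 0,
                                "higher", "lower"),
             log_scale = FALSE))
  }
  emit(report_tbl, "report.tsv")

  manifest <- list(
    package = "rhythmecon",
    version = as.character(utils::packageVersion("rhythmecon")),
    seed = config$seed,
    detector = config$detector,
    thresholds = list(
      p_rhythmic = config$p_rhythmic, p_flat = config$p_flat,
      protein_p_rhythmic = config$protein_p_rhythmic,
      protein_p_flat = config$protein_p_flat,
      top_fraction = config$top_fraction,
      noise_filter = config$noise_filter, min_cells = config$min_cells
    ),
    counts = list(
      genes_input = nrow(inputs$rna$expr),
      rna_rhythmic = sum(rhythm_rna$class == "rhythmic", na.rm = TRUE),
      rna_non_rhythmic = sum(rhythm_rna$class == "non_rhythmic",
                             na.rm = TRUE),
      rna_ambiguous = sum(rhythm_rna$class == "ambiguous", na.rm = TRUE),
      protein_rhythmic = if (!is.null(rhythm_prot)) {
        sum(rhythm_prot$class == "rhythmic", na.rm = TRUE)
      },
      genes_delta = if (!is.null(tissue)) nrow(tissue$deltas),
      genes_noise = if (!is.null(noise)) nrow(noise$table),
      noise_degree_selected = if (!is.null(noise)) {
        noise$table$degree_selected[1]
      },
      genes_dnds = if (!is.null(inputs$dnds)) nrow(inputs$dnds)
    ),
    files = basename(written)
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)

  invisible(list(inputs = inputs, rhythm_rna = rhythm_rna,
                 rhythm_protein = rhythm_prot, cost = cost,
                 tissue = tissue, noise = noise, selection = selection,
                 report = report_tbl, manifest = manifest,
                 files = written))
}
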