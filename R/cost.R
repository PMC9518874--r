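#' Average amino-acid synthesis cost of a protein
#'
#' Mean per-residue biosynthetic cost over the sequence. Residues without a
#' defined cost (ambiguity codes B, Z, X, U, etc.) are skipped in the
#' average, while the reported protein length still counts them: no cost is
#' defined for an ambiguous residue, but it does occupy a position.
#'
#' @param sequence amino-acid sequence string.
#' @param costs an [aa_costs()] table.
#' @return Mean cost per residue (bonds/residue).
#' @examples
#' avg_aa_cost("GA", aa_costs("wagner"))
#' @export
avg_aa_cost <- function(sequence, costs) {
  if (!inherits(costs, "aa_cost_table")) costs <- new_aa_cost_table(costs, "custom")
  if (!nzchar(sequence)) abort("Empty sequence.")
  residues <- strsplit(toupper(sequence), "")[[1]]
  cost_vec <- setNames(costs$cost, costs$aa)[residues]
  if (all(is.na(cost_vec))) {
    abort("Sequence contains no residue with a defined cost.")
  }
  mean(cost_vec, na.rm = TRUE)
}

#' Abundance summaries of a time series
#'
#' `mean_abundance` is the arithmetic mean over time points.
#' `max_abundance` is the mean of the two highest *distinct* values — a
#' single-point maximum is sensitive to one-off spikes, so the top two
#' distinct observations are averaged. A series whose values are all equal
#' has no two distinct values; by continuity its maximum is the constant
#' value itself. All time points (cycles and replicates pooled) enter.
#'
#' @param x numeric abundance series; missing values are dropped.
#' @return A scalar; `NA` if no finite values remain.
#' @examples
#' max_abundance(c(5, 3, 5, 2))  # (5 + 3) / 2 = 4
#' @export
mean_abundance <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' @rdname mean_abundance
#' @export
max_abundance <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  u <- sort(unique(x), decreasing = TRUE)
  if (length(u) == 1) return(u)
  (u[1] + u[2]) / 2
}

#' Protein expression cost
#'
#' `C_p = N * L_p * cbar_AA`: abundance times length times mean per-residue
#' synthesis cost, in high-energy phosphate bonds. Computed under both the
#' mean-abundance and max-abundance conventions by [cost_table()], because
#' the "sufficient constant level" a rhythmic protein would otherwise need
#' is bracketed by its mean and its maximum.
#'
#' @param n abundance (mean or max convention).
#' @param l_p protein length, residues.
#' @param cbar_aa mean per-residue cost.
#' @return Cost in bonds.
#' @export
expression_cost <- function(n, l_p, cbar_aa) {
  if (any(c(n, l_p, cbar_aa) < 0, na.rm = TRUE)) {
    abort("Cost inputs must be non-negative.")
  }
  n * l_p * cbar_aa
}

#' Per-protein cost table
#'
#' Joins sequences and an abundance time series into the full cost table:
#' length, mean per-residue cost, mean and max abundance, and the expression
#' cost under both conventions.
#'
#' @param proteins tibble `protein_id`, `sequence` (from [read_fasta()] or
#'   [simulate_proteome()]).
#' @param expr abundance tibble (`gene_id` + sample columns) at the protein
#'   level; `gene_id` is matched against `protein_id`.
#' @param costs an [aa_costs()] table.
#' @return A tibble `protein_id`, `l_p`, `cbar_aa`, `mean_n`, `max_n`,
#'   `c_p_mean`, `c_p_max`, `cost_source`.
#' @export
cost_table <- function(proteins, expr, costs = aa_costs("wagner")) {
  value_cols <- setdiff(names(expr), c("gene_id", "probe_id"))
  joined <- inner_join(proteins, expr, by = c(protein_id = "gene_id"))
  if (nrow(joined) == 0) abort("No proteins matched the expression table.")
  m <- as.matrix(joined[, value_cols])
  tibble(
    protein_id = joined$protein_id,
    l_p = nchar(joined$sequence),
    cbar_aa = vapply(joined$sequence, avg_aa_cost, numeric(1), costs = costs,
                     USE.NAMES = FALSE),
    mean_n = apply(m, 1, mean_abundance),
    max_n = apply(m, 1, max_abundance)
  ) |>
    mutate(
      c_p_mean = expression_cost(.data$mean_n, .data$l_p, .data$cbar_aa),
      c_p_max = expression_cost(.data$max_n, .data$l_p, .data$cbar_aa),
      cost_source = attr(costs, "source") %||% "custom"
    )
}

#' Compare cost components between rhythm classes
#'
#' Welch tests of each cost component (total cost, mean per-residue cost,
#' length, abundance) between rhythmic and non-rhythmic proteins.
#' Everything is compared on the log scale except `cbar_aa`, which is
#' already a bounded per-residue average.
#'
#' @param costs a [cost_table()].
#' @param classes a classified rhythm table (`gene_id`, `class`); ambiguous
#'   genes are excluded.
#' @param components which columns of the cost table to compare.
#' @return A `rhythm_comparison` tibble, one row per component.
#' @export
compare_costs <- function(costs, classes,
                          components = c("c_p_mean", "c_p_max", "cbar_aa",
                                         "l_p", "mean_n", "max_n")) {
  joined <- costs |>
    inner_join(select(classes, "gene_id", "class"),
               by = c(protein_id = "gene_id")) |>
    filter(.data$class %in% c("rhythmic", "non_rhythmic"))
  n_by_class <- table(factor(joined$class,
                             c("rhythmic", "non_rhythmic")))
  if (any(n_by_class < 2)) {
    abort(sprintf("Need >= 2 genes per class (rhythmic: %d, non-rhythmic: %d).",
                  n_by_class[1], n_by_class[2]))
  }
  res <- purrr::map_dfr(components, function(comp) {
    welch_compare(joined[[comp]], joined$class == "rhythmic",
                  category = comp, log_transform = comp != "cbar_aa")
  })
  class(res) <- c("rhythm_comparison", class(res))
  res
}
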