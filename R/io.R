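#' Read an expression time series from TSV
#'
#' The matrix TSV has a `gene_id` column and one column per sample; the
#' metadata TSV maps `sample_id` to `time_h` and `replicate`. Samples are
#' reordered by (replicate, time). Gzip-compressed files are handled
#' transparently.
#'
#' @param path matrix TSV (genes as rows).
#' @param metadata_path metadata TSV with columns `sample_id`, `time_h`,
#'   `replicate`.
#' @return A list with `expr` (tibble) and `meta` (tibble).
#' @export
read_expression_tsv <- function(path, metadata_path) {
  expr <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  if (!"gene_id" %in% names(expr)) {
    abort("The expression TSV must have a `gene_id` column.")
  }
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    sample_id = readr::col_character(), time_h = readr::col_double(),
    .default = readr::col_character()))
  check_expr_meta(expr, meta)
  meta <- arrange(meta, .data$replicate, .data$time_h)
  expr <- expr[, c("gene_id", meta$sample_id)]
  list(expr = expr, meta = meta)
}

check_expr_meta <- function(expr, meta) {
  samples <- setdiff(names(expr), "gene_id")
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("Duplicate sample ids in metadata: %s",
                  paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                        collapse = ", ")))
  }
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing)) {
    abort(sprintf("Samples missing from metadata: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(meta$time_h))) {
    abort("Every sample needs a finite `time_h`.")
  }
  invisible(TRUE)
}

#' Write an expression time series to TSV
#'
#' @param ts a list with `expr` and `meta` as returned by
#'   [read_expression_tsv()] or [simulate_timeseries()].
#' @param path matrix TSV destination.
#' @param metadata_path metadata TSV destination.
#' @return `ts`, invisibly.
#' @export
write_expression_tsv <- function(ts, path, metadata_path) {
  readr::write_tsv(ts$expr, path)
  readr::write_tsv(ts$meta, metadata_path)
  invisible(ts)
}

#' Apply the standard pre-processing filters to an expression matrix
#'
#' Mirrors the cleaning applied to published circadian datasets before
#' rhythm detection: probes assigned to several genes are removed (their
#' signal is ambiguous), rows with too many missing values are dropped, and
#' non-protein-coding rows are excluded when a biotype is available.
#' Remaining missing values are left in place — the detectors tolerate them.
#' The function is idempotent.
#'
#' @param expr expression tibble (`gene_id` + sample columns). `gene_id`
#'   here may be a probe identifier when `id_map` is supplied.
#' @param id_map optional tibble `probe_id`, `gene_id` and (optionally)
#'   `biotype`; probes mapping to more than one gene are dropped.
#' @param max_missing rows with more than this many missing values are
#'   dropped (the published rule for the Ostreococcus series used 7).
#' @param keep_biotype biotype value retained when `id_map$biotype` exists.
#' @return A tibble like `expr`, with a `gene_id` column (mapped through
#'   `id_map` when given; the original probe id is kept as `probe_id`).
#' @export
preprocess_expression <- function(expr, id_map = NULL, max_missing = 7,
                                  keep_biotype = "protein_coding") {
  out <- expr
  if (!is.null(id_map)) {
    if (!all(c("probe_id", "gene_id") %in% names(id_map))) {
      abort("`id_map` needs columns `probe_id` and `gene_id`.")
    }
    multi <- id_map |>
      distinct(.data$probe_id, .data$gene_id) |>
      count(.data$probe_id) |>
      filter(.data$n > 1)
    map <- id_map |>
      filter(!.data$probe_id %in% multi$probe_id)
    if ("biotype" %in% names(map)) {
      map <- filter(map, .data$biotype %in% keep_biotype)
    }
    out <- out |>
      rename(probe_id = "gene_id") |>
      inner_join(distinct(map, .data$probe_id, .data$gene_id),
                 by = "probe_id") |>
      relocate("gene_id", "probe_id")
  }
  value_cols <- setdiff(names(out), c("gene_id", "probe_id"))
  n_missing <- rowSums(is.na(out[, value_cols]))
  out <- out[n_missing <= max_missing, ]
  if (nrow(out) == 0) warn("Pre-processing removed every row.")
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A tibble `protein_id`, `sequence`, `length`. `length` counts all
#'   residues including ambiguity codes; cost averaging skips residues
#'   without a defined cost (see [avg_aa_cost()]).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort("No records in FASTA file.")
  ids <- sub("\\s.*$", "", names(seqs))
  tibble(protein_id = ids,
         sequence = unname(as.character(seqs)),
         length = Biostrings::width(seqs))
}

#' Write protein sequences to FASTA
#'
#' @param proteins tibble with `protein_id` and `sequence`.
#' @param path destination.
#' @return `proteins`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                           proteins$protein_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(proteins)
}

#' Read a single-cell expression matrix
#'
#' Accepts either a dense TSV (`gene_id` + one column per cell) or a
#' MatrixMarket triplet (`.mtx` plus `genes`/`cells` sidecar TSVs). The
#' cells table carries the `cell_type` labels used by
#' [filter_cell_types()].
#'
#' @param path dense TSV or `.mtx` file.
#' @param genes_path,cells_path sidecar TSVs for the MTX route: one
#'   `gene_id` per row; `cell_id` (+ optional `cell_type`) per row.
#' @return A list with `values` (tibble) and `cells` (tibble: `cell_id`,
#'   `cell_type`).
#' @export
read_single_cell <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      abort("MTX input needs `genes_path` and `cells_path` sidecars.")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readr::read_tsv(genes_path, col_types = readr::cols(
      gene_id = readr::col_character()))
    cells <- readr::read_tsv(cells_path, col_types = readr::cols(
      .default = readr::col_character()))
    if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
      abort(sprintf(
        "MTX dimensions (%d x %d) do not match sidecars (%d genes, %d cells).",
        nrow(m), ncol(m), nrow(genes), nrow(cells)))
    }
    values <- bind_cols(tibble(gene_id = genes$gene_id),
                        as_tibble(`colnames<-`(m, cells$cell_id)))
  } else {
    values <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(), .default = readr::col_double()))
    cell_ids <- setdiff(names(values), "gene_id")
    cells <- if (!is.null(cells_path)) {
      readr::read_tsv(cells_path, col_types = readr::cols(
        .default = readr::col_character()))
    } else {
      tibble(cell_id = cell_ids, cell_type = "unlabelled")
    }
  }
  if (!"cell_type" %in% names(cells)) cells$cell_type <- "unlabelled"
  list(values = values, cells = cells)
}

#' Write a single-cell matrix as a MatrixMarket triplet
#'
#' @param sc list with `values` and `cells`.
#' @param path `.mtx` destination.
#' @param genes_path,cells_path sidecar TSV destinations.
#' @return `sc`, invisibly.
#' @export
write_single_cell_mtx <- function(sc, path, genes_path, cells_path) {
  m <- Matrix::Matrix(as.matrix(sc$values[, -1]), sparse = TRUE)
  Matrix::writeMM(m, path)
  readr::write_tsv(tibble(gene_id = sc$values$gene_id), genes_path)
  readr::write_tsv(sc$cells, cells_path)
  invisible(sc)
}

#' Keep only sufficiently sampled cell types
#'
#' Noise estimates from a handful of cells are unstable, so cell
#' (sub)types observed in fewer than `min_cells` cells are discarded — 100
#' for the large FACS atlases; small dedicated datasets (e.g. 20 root
#' quiescent-centre cells) pass with a lower threshold.
#'
#' @param sc list with `values` and `cells` (see [read_single_cell()]).
#' @param min_cells minimum number of cells per retained cell type.
#' @return `sc` restricted to retained cell types.
#' @export
filter_cell_types <- function(sc, min_cells = 100) {
  counts <- count(sc$cells, .data$cell_type)
  keep_types <- counts$cell_type[counts$n >= min_cells]
  if (length(keep_types) == 0) {
    abort(sprintf("No cell type reaches min_cells = %d (largest: %d).",
                  min_cells, max(counts$n)))
  }
  cells <- filter(sc$cells, .data$cell_type %in% keep_types)
  list(values = sc$values[, c("gene_id", cells$cell_id)], cells = cells)
}

#' Read a per-gene dN/dS table from TSV
#'
#' @param path TSV with columns `gene_id`, `dnds`. Genes appearing several
#'   times (multiple orthologue pairs) are collapsed to their median.
#' @return A tibble `gene_id`, `dnds` with finite, non-negative values.
#' @export
read_dnds <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), dnds = readr::col_double()))
  tbl <- filter(tbl, is.finite(.data$dnds), .data$dnds >= 0)
  tbl |>
    group_by(.data$gene_id) |>
    summarise(dnds = median(.data$dnds), .groups = "drop")
}
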