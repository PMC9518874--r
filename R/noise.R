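#' Filter genes by single-cell expression level
#'
#' Keeps genes whose expression reaches `log10(FPKM + 1) > threshold` in at
#' least one cell. Noise estimates for genes never expressed above
#' background are dominated by technical dropout, so they are excluded
#' before computing F*.
#'
#' @param sc list with `values` (`gene_id` + cell columns) and `cells`.
#' @param threshold on the `log10(FPKM + 1)` scale; `-Inf` disables the
#'   filter.
#' @return `sc` restricted to passing genes.
#' @export
filter_expressed <- function(sc, threshold = 1.5) {
  m <- as.matrix(sc$values[, -1])
  keep <- apply(log10(m + 1), 1, max, na.rm = TRUE) > threshold
  if (!any(keep)) abort("No gene passes the expression filter.")
  list(values = sc$values[keep, ], cells = sc$cells)
}

#' Per-gene mean and variance across cells
#'
#' With `mode = "pooled"` all retained cells enter one estimate per gene.
#' With `mode = "by_cell_type"` the moments are computed within each cell
#' type and then averaged per gene, weighting by the type's cell count —
#' this keeps a dominant cell type from swamping composition differences
#' between types.
#'
#' @param sc list with `values` and `cells`.
#' @param mode `"pooled"` or `"by_cell_type"`.
#' @return A tibble `gene_id`, `mu`, `sigma2`, `n_cells_used`.
#' @export
noise_stats <- function(sc, mode = c("pooled", "by_cell_type")) {
  mode <- match.arg(mode)
  m <- as.matrix(sc$values[, -1])
  if (mode == "pooled" || length(unique(sc$cells$cell_type)) == 1) {
    return(tibble(
      gene_id = sc$values$gene_id,
      mu = rowMeans(m, na.rm = TRUE),
      sigma2 = apply(m, 1, var, na.rm = TRUE),
      n_cells_used = rowSums(is.finite(m))
    ))
  }
  types <- split(sc$cells$cell_id, sc$cells$cell_type)
  per_type <- purrr::map(types, function(ids) {
    mt <- m[, colnames(m) %in% ids, drop = FALSE]
    list(mu = rowMeans(mt, na.rm = TRUE),
         s2 = apply(mt, 1, var, na.rm = TRUE),
         w = ncol(mt))
  })
  w <- vapply(per_type, `[[`, numeric(1), "w")
  mu <- rowSums(vapply(per_type, function(x) x$mu * x$w,
                       numeric(nrow(m)))) / sum(w)
  s2 <- rowSums(vapply(per_type, function(x) x$s2 * x$w,
                       numeric(nrow(m)))) / sum(w)
  tibble(gene_id = sc$values$gene_id, mu = mu, sigma2 = s2,
         n_cells_used = as.integer(sum(w)))
}

#' Mean-decorrelated expression noise F*
#'
#' Raw single-cell variance tracks the mean, so comparing variances across
#' genes mostly compares expression levels. F* removes the trend: a
#' polynomial of `log(sigma2)` on `log(mu)` is fitted across genes and
#' `F* = sigma2 / exp(fit)`, the gene's variance relative to the
#' mean-variance trend. Genes on the trend get `F* = 1`. With
#' `degree = "auto"` the lowest degree in `1..max_degree` whose F* passes
#' the decorrelation diagnostics (see [select_degree()]) is used.
#'
#' @param stats a [noise_stats()] table (or any tibble with `gene_id`,
#'   `mu`, `sigma2`); genes with `mu <= 0` or `sigma2 <= 0` are dropped.
#' @param degree polynomial degree, or `"auto"`.
#' @param max_degree largest degree tried under `"auto"`.
#' @param kendall_threshold,slope_threshold decorrelation criteria passed to
#'   [select_degree()].
#' @return A tibble of class `fstar_fit`: `gene_id`, `mu`, `sigma2`,
#'   `fstar`, `degree_selected` (+ `n_cells_used` if present), with the
#'   degree diagnostics in `attr(, "diagnostics")`.
#' @export
fstar <- function(stats, degree = "auto", max_degree = 5,
                  kendall_threshold = 0.05, slope_threshold = 0.05) {
  d <- filter(stats, is.finite(.data$mu), .data$mu > 0,
              is.finite(.data$sigma2), .data$sigma2 > 0)
  if (nrow(d) < 20) abort("Need >= 20 genes with positive mu and sigma2.")
  log_mu <- log(d$mu)
  log_s2 <- log(d$sigma2)

  fstar_at <- function(deg) {
    fit <- lm(log_s2 ~ poly(log_mu, deg, raw = TRUE))
    if (any(!is.finite(coef(fit)))) {
      abort(sprintf("Singular polynomial fit at degree %d.", deg))
    }
    d$sigma2 / exp(unname(fitted(fit)))
  }

  if (identical(degree, "auto")) {
    cand <- seq_len(max_degree)
    fs_list <- lapply(cand, fstar_at)
    sel <- select_degree(cand, fs_list, d$mu,
                         kendall_threshold = kendall_threshold,
                         slope_threshold = slope_threshold)
    deg <- sel$degree
    fs <- fs_list[[which(cand == deg)]]
    diagnostics <- sel$diagnostics
  } else {
    deg <- as.integer(degree)
    fs <- fstar_at(deg)
    diagnostics <- degree_diagnostics(fs, d$mu, deg)
  }
  out <- mutate(d, fstar = fs, degree_selected = deg)
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("fstar_fit", class(out))
  out
}

degree_diagnostics <- function(fs, mu, degree) {
  if (sd(fs) == 0) {  # constant F*: trivially decorrelated
    return(tibble(degree = degree, kendall = 0, slope = 0, r_squared = 0))
  }
  lf <- log(fs)
  lmu <- log(mu)
  fit <- lm(lf ~ lmu)
  kendall <- suppressWarnings(cor(fs, mu, method = "kendall"))
  tibble(
    degree = degree,
    kendall = ifelse(is.na(kendall), 0, kendall),
    slope = unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared
  )
}

#' Choose the lowest polynomial degree that decorrelates F* from the mean
#'
#' For each candidate degree, reports Kendall's tau between F* and the
#' mean, and the slope and R-squared of `log(F*) ~ log(mu)`. The selected
#' degree is the lowest whose absolute Kendall tau and absolute slope both
#' fall below their thresholds; if none qualifies, the degree minimizing
#' the absolute Kendall tau wins (ties: lowest degree).
#'
#' @param degrees integer candidate degrees.
#' @param fstar_list list of F* vectors, one per degree.
#' @param mu per-gene means.
#' @param kendall_threshold,slope_threshold decorrelation criteria.
#' @return A list: `degree` (selected) and `diagnostics` (tibble with one
#'   row per degree and a `selected` flag).
#' @export
select_degree <- function(degrees, fstar_list, mu,
                          kendall_threshold = 0.05, slope_threshold = 0.05) {
  if (length(degrees) < 1) abort("Need at least one candidate degree.")
  diag <- purrr::map2_dfr(fstar_list, degrees, degree_diagnostics, mu = mu)
  pass <- abs(diag$kendall) < kendall_threshold &
    abs(diag$slope) < slope_threshold
  sel <- if (any(pass)) {
    degrees[which(pass)[1]]
  } else {
    degrees[which.min(abs(diag$kendall))]
  }
  diag$selected <- degrees == sel
  list(degree = sel, diagnostics = diag)
}

#' Compare expression noise between rhythm classes
#'
#' Welch tests of `log(F*)` between gene groups defined by RNA- and
#' protein-level rhythm classes. The five designs mirror the standard
#' contrast table:
#' \describe{
#'   \item{a}{rhythmic vs non-rhythmic transcripts, all genes.}
#'   \item{b}{rhythmic vs non-rhythmic proteins, all genes.}
#'   \item{c}{rhythmic vs non-rhythmic transcripts among rhythmic
#'     proteins.}
#'   \item{d}{rhythmic vs non-rhythmic transcripts among non-rhythmic
#'     proteins.}
#'   \item{e}{rhythmic vs non-rhythmic proteins among genes with constant
#'     (non-rhythmic) transcripts.}
#' }
#'
#' @param noise an [fstar()] table.
#' @param rna_classes,protein_classes classified rhythm tables (`gene_id`,
#'   `class`). `protein_classes` may be `NULL` for category `a`.
#' @param category one of `"a"`–`"e"`.
#' @return A one-row `rhythm_comparison` tibble.
#' @export
compare_noise <- function(noise, rna_classes, protein_classes = NULL,
                          category = c("a", "b", "c", "d", "e")) {
  category <- match.arg(category)
  d <- noise |>
    left_join(select(rna_classes, "gene_id", rna_class = "class"),
              by = "gene_id")
  if (!is.null(protein_classes)) {
    d <- left_join(d, select(protein_classes, "gene_id",
                             prot_class = "class"), by = "gene_id")
  } else if (category != "a") {
    abort(sprintf("Category '%s' needs protein classes.", category))
  }
  spec <- switch(category,
    a = list(cond = TRUE, by = "rna_class"),
    b = list(cond = TRUE, by = "prot_class"),
    c = list(cond = quote(prot_class == "rhythmic"), by = "rna_class"),
    d = list(cond = quote(prot_class == "non_rhythmic"), by = "rna_class"),
    e = list(cond = quote(rna_class == "non_rhythmic"), by = "prot_class")
  )
  if (!isTRUE(spec$cond)) {
    d <- filter(d, !is.na(eval(spec$cond, d)) & eval(spec$cond, d))
  }
  d <- filter(d, .data[[spec$by]] %in% c("rhythmic", "non_rhythmic"))
  if (nrow(d) == 0 || length(unique(d[[spec$by]])) < 2) {
    abort(sprintf("Empty conditioning set for noise category '%s'.",
                  category))
  }
  welch_compare(d$fstar, d[[spec$by]] == "rhythmic",
                category = paste0("noise_", category), log_transform = TRUE)
}

#' @export
tidy.fstar_fit <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.fstar_fit <- function(x, ...) {
  diag <- attr(x, "diagnostics")
  sel <- diag[diag$degree == x$degree_selected[1], ]
  tibble(degree_selected = x$degree_selected[1], n_genes = nrow(x),
         kendall = sel$kendall, slope = sel$slope,
         r_squared = sel$r_squared)
}
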