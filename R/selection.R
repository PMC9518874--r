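#' Residualize dN/dS on expression level
#'
#' Highly expressed genes are under stronger purifying selection, and
#' rhythmic genes are enriched in highly expressed genes — so a raw
#' rhythmic-vs-non-rhythmic dN/dS contrast is confounded. The control is an
#' ordinary least-squares fit of `log(dN/dS)` on `log(expression)`; its
#' residuals carry the part of constraint not explained by expression.
#' Genes with `dN/dS = 0` or non-positive expression are excluded before
#' the log (counted in the `n_excluded` attribute).
#'
#' @param dnds tibble `gene_id`, `dnds`.
#' @param expression tibble `gene_id`, `expression` (strictly positive
#'   level, e.g. mean abundance at the matching level).
#' @return A tibble `gene_id`, `residual`, with attributes `slope`,
#'   `intercept`, `n_excluded`.
#' @export
residualize_dnds <- function(dnds, expression) {
  d <- inner_join(dnds, expression, by = "gene_id")
  usable <- filter(d, is.finite(.data$dnds), .data$dnds > 0,
                   is.finite(.data$expression), .data$expression > 0)
  if (nrow(usable) < 3) abort("Need >= 3 genes with positive dN/dS and expression.")
  fit <- lm(log(dnds) ~ log(expression), data = usable)
  out <- tibble(gene_id = usable$gene_id, residual = unname(resid(fit)))
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "intercept") <- unname(coef(fit)[1])
  attr(out, "n_excluded") <- nrow(d) - nrow(usable)
  out
}

#' Compare dN/dS between rhythm classes
#'
#' Welch tests of evolutionary constraint between gene groups, on
#' `log(dN/dS)` (uncontrolled) or on expression-residualized values
#' (controlled; see [residualize_dnds()]). The four designs:
#' \describe{
#'   \item{a}{rhythmic vs non-rhythmic transcripts, all genes.}
#'   \item{b}{rhythmic vs non-rhythmic proteins, all genes.}
#'   \item{c}{rhythmic vs non-rhythmic transcripts among rhythmic
#'     proteins.}
#'   \item{d}{rhythmic vs non-rhythmic proteins among genes with rhythmic
#'     transcripts.}
#' }
#' Ambiguous genes are excluded from both sides of every contrast.
#'
#' @param dnds tibble `gene_id`, `dnds`.
#' @param rna_classes,protein_classes classified rhythm tables.
#' @param category one of `"a"`–`"d"`.
#' @param controlled residualize on expression first?
#' @param expression tibble `gene_id`, `expression`; required when
#'   `controlled = TRUE`.
#' @return A one-row `rhythm_comparison` tibble with a `controlled` column.
#' @export
compare_dnds <- function(dnds, rna_classes, protein_classes = NULL,
                         category = c("a", "b", "c", "d"),
                         controlled = FALSE, expression = NULL) {
  category <- match.arg(category)
  if (controlled) {
    if (is.null(expression)) abort("`expression` is required when controlled = TRUE.")
    res <- residualize_dnds(dnds, expression)
    d <- tibble(gene_id = res$gene_id, value = res$residual)
    log_transform <- FALSE
  } else {
    d <- dnds |>
      filter(is.finite(.data$dnds), .data$dnds > 0) |>
      transmute(gene_id = .data$gene_id, value = .data$dnds)
    log_transform <- TRUE
  }
  d <- left_join(d, select(rna_classes, "gene_id", rna_class = "class"),
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
    d = list(cond = quote(rna_class == "rhythmic"), by = "prot_class")
  )
  if (!isTRUE(spec$cond)) {
    d <- filter(d, !is.na(eval(spec$cond, d)) & eval(spec$cond, d))
  }
  d <- filter(d, .data[[spec$by]] %in% c("rhythmic", "non_rhythmic"))
  if (nrow(d) == 0 || length(unique(d[[spec$by]])) < 2) {
    abort(sprintf("Empty group for dN/dS category '%s'.", category))
  }
  out <- welch_compare(d$value, d[[spec$by]] == "rhythmic",
                       category = paste0("dnds_", category),
                       log_transform = log_transform)
  out$controlled <- controlled
  out
}

#' Compare dN/dS between two explicit gene sets
#'
#' Two-sample test of `log(dN/dS)` between the correlation-sign-defined
#' sets from [expression_rhythm_correlation()]: set A (rhythmic where
#' highly expressed) versus set B (rhythmic where lowly expressed).
#'
#' @param set_a,set_b disjoint character vectors of gene ids.
#' @param dnds tibble `gene_id`, `dnds`.
#' @param var_equal pooled-variance Student test (the classic choice for
#'   this contrast) instead of Welch.
#' @return A one-row `rhythm_comparison` tibble (set A plays the "rhythmic"
#'   role).
#' @export
compare_dnds_sets <- function(set_a, set_b, dnds, var_equal = TRUE) {
  if (length(intersect(set_a, set_b)) > 0) {
    abort("Gene sets A and B must be disjoint.")
  }
  d <- dnds |>
    filter(.data$gene_id %in% c(set_a, set_b),
           is.finite(.data$dnds), .data$dnds > 0)
  welch_compare(d$dnds, d$gene_id %in% set_a, category = "dnds_sets_AB",
                log_transform = TRUE, var_equal = var_equal)
}
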