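#' Welch two-sample comparison between gene groups
#'
#' The pipeline's common currency: every cost, noise and dN/dS contrast is a
#' Welch two-sample t-test between a "rhythmic" and a "non-rhythmic" gene
#' set, usually on a log scale. Zeros are floored at half the smallest
#' positive value before logging, the usual pseudo-floor for abundance data.
#'
#' @param values numeric vector of the quantity compared.
#' @param group logical vector, `TRUE` for the first (rhythmic) group.
#' @param category free-text label carried into the result.
#' @param log_transform log the values first (natural log)?
#' @param var_equal use the pooled-variance Student test instead of Welch.
#'
#' @return A one-row tibble of class `rhythm_comparison`: `category`,
#'   `n_rhythmic`, `n_other`, `mean_rhythmic`, `mean_other` (on the analysis
#'   scale), `statistic`, `df`, `p_value`, `direction` (`"lower"` /
#'   `"higher"` for the rhythmic group), `log_scale`.
#' @examples
#' welch_compare(c(rnorm(20, 1), rnorm(20, 2)), rep(c(TRUE, FALSE), each = 20),
#'               log_transform = FALSE)
#' @export
welch_compare <- function(values, group, category = "comparison",
                          log_transform = TRUE, var_equal = FALSE) {
  if (length(values) != length(group)) {
    abort("`values` and `group` must have the same length.")
  }
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- group[keep]
  n1 <- sum(group)
  n2 <- sum(!group)
  if (n1 < 2 || n2 < 2) {
    abort(sprintf(
      "Each group needs >= 2 values for '%s' (rhythmic: %d, other: %d).",
      category, n1, n2))
  }
  if (log_transform) {
    if (any(values < 0)) abort("Negative values cannot be log-transformed.")
    pos_min <- suppressWarnings(min(values[values > 0]))
    if (!is.finite(pos_min)) abort("All values are zero; nothing to compare.")
    values <- log(pmax(values, pos_min / 2))
  }
  ht <- t.test(values[group], values[!group], var.equal = var_equal)
  out <- tibble(
    category = category,
    n_rhythmic = n1,
    n_other = n2,
    mean_rhythmic = unname(ht$estimate[1]),
    mean_other = unname(ht$estimate[2]),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    direction = unname(ifelse(ht$estimate[1] < ht$estimate[2],
                              "lower", "higher")),
    log_scale = log_transform
  )
  class(out) <- c("rhythm_comparison", class(out))
  out
}

#' @export
tidy.rhythm_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.rhythm_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         n = x$n_rhythmic + x$n_other)
}
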