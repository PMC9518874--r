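AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Akashi & Gojobori (2002): biosynthetic cost per molecule in E. coli,
# high-energy phosphate bonds (~P).
AKASHI_GOJOBORI <- c(
  A = 11.7, R = 27.3, N = 14.7, D = 12.7, C = 24.7,
  Q = 16.3, E = 15.3, G = 11.7, H = 38.3, I = 32.3,
  L = 27.3, K = 30.3, M = 34.3, F = 52.0, P = 20.3,
  S = 11.7, T = 21.3, W = 74.3, Y = 50.0, V = 23.3
)

# Wagner (2005): biosynthetic cost per molecule under respiration, ATP.
WAGNER <- c(
  A = 14.5, R = 20.5, N = 18.5, D = 15.5, C = 26.5,
  Q = 10.5, E = 9.5,  G = 14.5, H = 29.0, I = 38.0,
  L = 37.0, K = 36.0, M = 36.5, F = 61.0, P = 14.5,
  S = 14.5, T = 21.5, W = 75.5, Y = 59.0, V = 29.0
)

#' Amino-acid biosynthetic cost tables
#'
#' Per-residue energetic costs (high-energy phosphate bonds per molecule)
#' used to compute protein expression costs. Two built-in tables are
#' provided: `"wagner"` (Wagner 2005, respiration) and `"akashi_gojobori"`
#' (Akashi & Gojobori 2002, E. coli). The two are strongly linearly
#' correlated, so either supports the same comparisons; biosynthetic
#' pathways are nearly universal, making the E. coli-derived values usable
#' across species.
#'
#' @param source `"wagner"`, `"akashi_gojobori"`, or a path to a two-column
#'   TSV (`aa`, `cost`) with exactly the 20 standard one-letter codes.
#' @return A tibble of class `aa_cost_table`: `aa`, `cost`, with a `source`
#'   attribute.
#' @examples
#' aa_costs("wagner")
#' @export
aa_costs <- function(source = c("wagner", "akashi_gojobori")) {
  if (length(source) == 1 && !source[1] %in% c("wagner", "akashi_gojobori")) {
    return(read_aa_costs(source))
  }
  source <- match.arg(source)
  costs <- switch(source, wagner = WAGNER, akashi_gojobori = AKASHI_GOJOBORI)
  new_aa_cost_table(tibble(aa = names(costs), cost = unname(costs)), source)
}

#' Read a custom amino-acid cost table from TSV
#'
#' @param path TSV with columns `aa` (one-letter code) and `cost` (> 0).
#' @return A tibble of class `aa_cost_table`.
#' @export
read_aa_costs <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    aa = readr::col_character(), cost = readr::col_double()))
  new_aa_cost_table(tbl, "custom")
}

new_aa_cost_table <- function(tbl, source) {
  if (!all(c("aa", "cost") %in% names(tbl))) {
    abort("An AA cost table needs columns `aa` and `cost`.")
  }
  if (!setequal(tbl$aa, AA_CODES) || nrow(tbl) != 20) {
    abort("An AA cost table must contain exactly the 20 standard one-letter codes.")
  }
  if (any(!is.finite(tbl$cost)) || any(tbl$cost <= 0)) {
    abort("All AA costs must be finite and > 0.")
  }
  tbl <- tbl[match(AA_CODES, tbl$aa), c("aa", "cost")]
  attr(tbl, "source") <- source
  class(tbl) <- c("aa_cost_table", class(tbl))
  tbl
}
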