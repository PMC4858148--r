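#' Published chicken serum DE screen: the 40 most-changed miRNAs
#'
#' The worked-example dataset shipped with the package: the 40 chicken serum
#' miRNAs whose expression changed more than two-fold (|log2 fold-change| >=
#' 1.0, Fisher p < 0.05) between before and after puberty onset, as printed
#' in the originating screen. Columns: `mirna`, `fold_change` (AO/BO, 2
#' decimals), `log2_fc` (2 decimals), `p_label`. Values are rounded display
#' values, useful for arithmetic cross-checks of [de_table()]'s reporting and
#' as the input of [screen_top()] examples.
#'
#' @return A tibble with 40 rows.
#' @export
#' @examples
#' tbl <- chicken_serum_de_top40()
#' sum(tbl$log2_fc >= 1)   # up-regulated more than two-fold
chicken_serum_de_top40 <- function() {
  path <- system.file("extdata", "chicken_serum_de_top40.tsv",
                      package = "circamir", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Check rounded fold-change / log2 fold-change pairs for consistency
#'
#' Printed DE tables round both the fold-change and its log2 to two decimals,
#' so recomputing `log2(fold_change)` from the printed fold-change need not
#' reproduce the printed log2 exactly. A pair is *consistent* when some
#' fold-change within half a printing unit (+/- 0.005) of the printed value
#' rounds to the printed log2.
#'
#' @param fold_change,log2_fc Numeric vectors of printed (2-decimal) values.
#' @return Tibble with `recomputed` (`round(log2(fold_change), 2)`) and
#'   `consistent`.
#' @export
check_log2_consistency <- function(fold_change, log2_fc) {
  lo <- log2(fold_change - 0.005)
  hi <- log2(fold_change + 0.005)
  tibble::tibble(
    recomputed = round(log2(fold_change), 2),
    consistent = round(lo, 2) <= log2_fc & log2_fc <= round(hi, 2)
  )
}
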