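#' Reads-per-million normalisation
#'
#' Expression is normalised to the total number of reads in the library that
#' matched the genome: `RPM = 1e6 * count / total`.
#'
#' @param count Raw read count(s).
#' @param total Genome-matched read total of the library (> 0).
#' @return RPM value(s).
#' @export
#' @examples
#' rpm(50, 1e6)
rpm <- function(count, total) {
  if (any(total <= 0)) stop("genome-matched total must be positive", call. = FALSE)
  if (any(count > total)) stop("count cannot exceed the library total", call. = FALSE)
  1e6 * count / total
}

#' Fisher's exact and chi-square tests on a 2x2 count table
#'
#' Tests whether a miRNA's share of the library differs between conditions,
#' on the table `[[count_bo, total_bo - count_bo], [count_ao, total_ao -
#' count_ao]]`. The Fisher p-value is the two-sided exact probability (sum of
#' hypergeometric probabilities no larger than the observed table's); the
#' chi-square p-value is Pearson's statistic on 1 df without continuity
#' correction.
#'
#' @param count_bo,count_ao Raw counts in each condition.
#' @param total_bo,total_ao Genome-matched totals of each library.
#' @return Tibble with columns `fisher_p` and `chisq_p` (one row per input).
#' @export
fisher_chisq_test <- function(count_bo, total_bo, count_ao, total_ao) {
  n <- length(count_bo)
  cells <- cbind(count_bo, total_bo - count_bo, count_ao, total_ao - count_ao)
  if (any(cells < 0)) stop("negative table cells: counts exceed totals",
                           call. = FALSE)
  out <- vapply(seq_len(n), function(i) {
    m <- matrix(cells[i, ], nrow = 2, byrow = TRUE)
    fp <- fisher.test(m)$p.value
    cp <- if (sum(m) == 0) 1 else suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    c(fp, if (is.na(cp)) 1 else cp)
  }, numeric(2))
  tibble::tibble(fisher_p = pmin(out[1, ], 1), chisq_p = out[2, ])
}

#' Differential expression table between pubertal stages
#'
#' Normalises counts to RPM, computes AO/BO fold-changes and log2
#' fold-changes, and tests each miRNA with Fisher's exact test (primary) and
#' the chi-square test. When either raw count is zero, the ratio (only) is
#' computed with a 0.5-read pseudocount in both conditions so fold-changes
#' stay finite; the tests always use the raw counts. No multiple-testing
#' correction is applied by default; `adjust = "BH"` flags on
#' Benjamini-Hochberg-adjusted Fisher p-values instead (the flagged set is
#' then a subset of the unadjusted one).
#'
#' @param counts Tibble with columns `mirna`, `count_bo`, `count_ao`.
#' @param totals Named numeric vector `c(bo = ..., ao = ...)` of
#'   genome-matched totals.
#' @param alpha Significance level for the DE flag (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `mir_de` with columns `mirna`, `count_bo`,
#'   `count_ao`, `rpm_bo`, `rpm_ao`, `fold_change`, `log2_fc`, `fisher_p`,
#'   `chisq_p`, `direction` (`up`/`down`/`flat`), `de_flag`. Fold-changes are
#'   kept at full precision; round for display as needed.
#' @export
de_table <- function(counts, totals, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("mirna", "count_bo", "count_ao") %in% names(counts)),
            all(c("bo", "ao") %in% names(totals)))
  out <- tibble::as_tibble(counts[c("mirna", "count_bo", "count_ao")])
  out$rpm_bo <- rpm(out$count_bo, totals[["bo"]])
  out$rpm_ao <- rpm(out$count_ao, totals[["ao"]])
  zero <- out$count_bo == 0 | out$count_ao == 0
  num <- ifelse(zero, out$count_ao + 0.5, out$count_ao) / totals[["ao"]]
  den <- ifelse(zero, out$count_bo + 0.5, out$count_bo) / totals[["bo"]]
  out$fold_change <- num / den
  out$log2_fc <- log2(out$fold_change)
  tests <- fisher_chisq_test(out$count_bo, totals[["bo"]],
                             out$count_ao, totals[["ao"]])
  out$fisher_p <- tests$fisher_p
  out$chisq_p <- tests$chisq_p
  out$direction <- dplyr::case_when(
    out$fold_change > 1 ~ "up",
    out$fold_change < 1 ~ "down",
    TRUE ~ "flat"
  )
  p_gate <- if (adjust == "BH") p.adjust(out$fisher_p, "BH") else out$fisher_p
  out$de_flag <- p_gate < alpha
  new_mir_tbl(out, "mir_de", totals = totals, alpha = alpha, adjust = adjust)
}

#' Screen a DE table for the most-changed miRNAs
#'
#' Keeps DE-flagged miRNAs with `|log2 fold-change| >= min_abs_log2fc`
#' (inclusive boundary), sorted by decreasing log2 fold-change. Comparisons
#' use full precision, not the rounded display values.
#'
#' @param de A [de_table()] result.
#' @param min_abs_log2fc Minimum absolute log2 fold-change (default 1.0, i.e.
#'   a two-fold change).
#' @return Filtered and sorted tibble.
#' @export
screen_top <- function(de, min_abs_log2fc = 1.0) {
  de |>
    dplyr::filter(.data$de_flag, abs(.data$log2_fc) >= min_abs_log2fc) |>
    dplyr::arrange(dplyr::desc(.data$log2_fc))
}

#' Reproduction-associated annotation keywords
#'
#' The default vocabulary used to judge "association with reproduction
#' events" when selecting RT-qPCR candidates.
#'
#' @return Character vector of keywords.
#' @export
reproduction_keywords <- function() {
  c("gonad development", "muscle development", "glucose metabolism",
    "fat metabolism", "insulin metabolism",
    "sex hormone synthesis and secretion")
}

#' Select RT-qPCR candidate miRNAs from a DE table
#'
#' A miRNA is a candidate iff (1) it is DE-flagged, (2) it has at least
#' middle expression, `max(count_bo, count_ao) >= min_raw_reads`, and (3) at
#' least one of its annotation terms is among `keywords`.
#'
#' @param de A [de_table()] result.
#' @param annotations Named list (miRNA -> character vector of terms) or a
#'   tibble with columns `mirna`, `term`. Missing miRNAs have no terms.
#' @param keywords Keyword vocabulary (default [reproduction_keywords()]).
#' @param min_raw_reads Minimum raw reads in either condition (inclusive,
#'   default 40).
#' @return The candidate rows of `de`, with a `terms` list-column.
#' @export
select_candidates <- function(de, annotations,
                              keywords = reproduction_keywords(),
                              min_raw_reads = 40) {
  if (is.data.frame(annotations)) {
    annotations <- split(annotations$term, annotations$mirna)
  }
  terms <- annotations[de$mirna]
  has_kw <- vapply(terms, function(tt) {
    !is.null(tt) && length(intersect(tolower(tt), tolower(keywords))) > 0
  }, logical(1))
  out <- de |>
    dplyr::mutate(terms = unname(terms), has_keyword = unname(has_kw)) |>
    dplyr::filter(.data$de_flag,
                  pmax(.data$count_bo, .data$count_ao) >= min_raw_reads,
                  .data$has_keyword)
  out
}

#' @describeIn de_table Broom-style one-row summary: totals tested, DE counts
#'   by direction, and the size of the `|log2FC| >= 1` screen.
#' @param x A `mir_de` object.
#' @param ... Unused.
#' @method glance mir_de
#' @export
glance.mir_de <- function(x, ...) {
  top <- screen_top(x)
  tibble::tibble(
    n_mirna = nrow(x),
    n_de = sum(x$de_flag),
    n_up = sum(x$de_flag & x$direction == "up"),
    n_down = sum(x$de_flag & x$direction == "down"),
    n_top = nrow(top),
    alpha = attr(x, "alpha")
  )
}

#' @describeIn de_table Return the DE table as a plain tibble (display
#'   columns rounded to 2 decimals as conventionally reported).
#' @method tidy mir_de
#' @export
tidy.mir_de <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(fold_change = round(.data$fold_change, 2),
                  log2_fc = round(.data$log2_fc, 2))
}

#' @describeIn de_table Volcano plot of the DE table.
#' @param object A `mir_de` object.
#' @method autoplot mir_de
#' @export
autoplot.mir_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, -log10(pmax(.data$fisher_p, 1e-300)),
                                   colour = .data$de_flag)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "log2 fold-change (AO/BO)", y = "-log10 Fisher p",
                  colour = "DE") +
    ggplot2::theme_minimal()
}
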