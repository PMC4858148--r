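#' Clean raw small-RNA reads
#'
#' Reproduces the standard small-RNA cleaning cascade: (i) discard reads whose
#' mean Phred quality is below `min_mean_q` ("poor quality reads"); (ii) trim
#' at the leftmost exact match of the first `adapter_match_len` nt of the 3'
#' adapter; (iii) discard reads with no adapter hit ("adaptor pollution",
#' which also covers adapter dimers, i.e. inserts of length zero), trimmed
#' inserts outside `[min_len, max_len]`, or inserts containing N. The discard
#' tally partitions `raw - clean` exactly.
#'
#' @param reads A tibble with columns `seq` and `qual` (Phred+33), e.g. from
#'   [read_fastq_tbl()], or a path to a FASTQ file.
#' @param adapter 3' adapter sequence (>= `adapter_match_len` nt).
#' @param min_mean_q Minimum mean Phred quality (default 20).
#' @param min_len,max_len Insert length window kept after trimming
#'   (defaults 18 and 35, the gel-excision window of the assay).
#' @param adapter_match_len Number of leading adapter nt that must match
#'   exactly (default 8; no mismatches are tolerated).
#' @param require_adapter Discard reads without an adapter hit (default).
#'   With `FALSE`, adapter-free reads are kept untrimmed and only
#'   length-filtered.
#' @return A tibble of clean reads (`seq`, `length`) of class `mir_clean`,
#'   carrying attributes `n_raw` and `tally` (per-filter discard counts);
#'   see [glance.mir_clean()].
#' @export
clean_reads <- function(reads, adapter, min_mean_q = 20,
                        min_len = 18, max_len = 35,
                        adapter_match_len = 8, require_adapter = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq_tbl(reads)
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (nchar(adapter) < adapter_match_len) {
    stop("adapter must be at least ", adapter_match_len, " nt", call. = FALSE)
  }
  bad_pair <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_pair)) {
    stop("malformed FASTQ record at index ", which(bad_pair)[1],
         ": sequence and quality lengths differ", call. = FALSE)
  }
  n_raw <- nrow(reads)
  seqs <- toupper(reads$seq)

  reason <- rep(NA_character_, n_raw)
  reason[mean_phred(reads$qual) < min_mean_q] <- "low_quality"

  key <- substr(adapter, 1, adapter_match_len)
  pos <- as.integer(regexpr(key, seqs, fixed = TRUE))
  insert <- ifelse(pos > 0, substr(seqs, 1, pos - 1L), seqs)
  todo <- is.na(reason)
  reason[todo & pos == 1L] <- "adaptor_pollution"          # adapter dimer
  if (require_adapter) {
    reason[todo & pos < 0L] <- "adaptor_pollution"          # no adapter found
  }
  todo <- is.na(reason)
  len <- nchar(insert)
  reason[todo & len < min_len] <- "too_short"
  todo <- is.na(reason)
  reason[todo & len > max_len] <- "too_long"
  todo <- is.na(reason)
  reason[todo & grepl("N", insert, fixed = TRUE)] <- "ambiguous_base"

  keep <- is.na(reason)
  tally <- tibble::tibble(reason = reason[!keep]) |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  out <- tibble::tibble(seq = insert[keep], length = len[keep])
  new_mir_tbl(out, "mir_clean", n_raw = n_raw, tally = tally)
}

#' Per-filter discard tally of a cleaned read set
#'
#' @param x A [clean_reads()] result.
#' @return Tibble with columns `reason`, `n`.
#' @export
discard_tally <- function(x) {
  attr(x, "tally") %||% tibble::tibble(reason = character(), n = integer())
}

#' @describeIn clean_reads One-row summary: raw reads, clean reads and
#'   per-filter discard counts.
#' @param x A `mir_clean` object.
#' @param ... Unused.
#' @method glance mir_clean
#' @export
glance.mir_clean <- function(x, ...) {
  tally <- discard_tally(x)
  wide <- if (nrow(tally)) tidyr::pivot_wider(tally, names_from = "reason",
                                              values_from = "n")
          else tibble::tibble()
  dplyr::bind_cols(
    tibble::tibble(n_raw = attr(x, "n_raw"), n_clean = nrow(x)),
    wide
  )
}

#' Collapse clean reads to unique tags with counts
#'
#' @param clean A tibble with a `seq` column ([clean_reads()] output) or a
#'   character vector of sequences.
#' @return A tibble (`seq`, `count`, `length`) sorted by decreasing count,
#'   class `mir_tags`; total counts equal the number of input reads.
#' @export
collapse_tags <- function(clean) {
  seqs <- if (is.character(clean)) clean else clean$seq
  if (!length(seqs)) {
    return(new_mir_tbl(tibble::tibble(seq = character(), count = integer(),
                                      length = integer()), "mir_tags"))
  }
  out <- tibble::tibble(seq = seqs) |>
    dplyr::count(.data$seq, name = "count") |>
    dplyr::mutate(length = nchar(.data$seq)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq)
  new_mir_tbl(out, "mir_tags")
}

#' Read-length histogram of a clean read set
#'
#' @param x A [clean_reads()] result, a [collapse_tags()] result (counts are
#'   used as weights), or a character vector of sequences.
#' @return Tibble `length`, `n`, `pct`; percentages sum to 100.
#' @export
length_histogram <- function(x) {
  if (is.character(x)) x <- tibble::tibble(seq = x)
  w <- if ("count" %in% names(x)) x$count else rep(1L, nrow(x))
  if (!nrow(x)) stop("cannot compute a length histogram of an empty read set",
                     call. = FALSE)
  tibble::tibble(length = nchar(x$seq), w = w) |>
    dplyr::count(.data$length, wt = .data$w, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Plot a read-length distribution
#'
#' @param x Input accepted by [length_histogram()].
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(x) {
  h <- length_histogram(x)
  ggplot2::ggplot(h, ggplot2::aes(.data$length, .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read length (nt)", y = "% of reads") +
    ggplot2::theme_minimal()
}
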