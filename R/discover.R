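#' Extract candidate precursor windows around a genome-matched tag
#'
#' For each locus two windows are taken: one with the tag as the 5' arm
#' (`[tag_start, tag_end + flank)`) and one with the tag as the 3' arm
#' (`[tag_start - flank, tag_end)`), truncated at chromosome ends. For
#' minus-strand loci the reverse complement is used and the mature offset
#' refers to the reverse-complemented window.
#'
#' @param locus A one-row tibble or list with `chrom`, `start0`, `end0`
#'   (0-based half-open), `strand`.
#' @param genome Named character vector of chromosomes (or `mir_reference`).
#' @param flank Flanking context in nt (default 100).
#' @return Tibble with one row per window: `arm` (`"5p"`/`"3p"`), `win_start0`,
#'   `win_end0`, `seq`, `mature_start` (1-based within `seq`), `mature_len`.
#' @export
extract_candidates <- function(locus, genome, flank = 100) {
  if (inherits(genome, "mir_reference")) genome <- genome$genome
  chrom_seq <- genome[[locus$chrom]]
  n <- nchar(chrom_seq)
  s <- locus$start0; e <- locus$end0
  stopifnot(s >= 0, e <= n, e > s)
  tag_len <- e - s

  windows <- tibble::tibble(
    arm = c("5p", "3p"),
    win_start0 = c(s, max(0L, s - flank)),
    win_end0 = c(min(n, e + flank), e)
  )
  windows$seq <- substr(rep(chrom_seq, 2), windows$win_start0 + 1L, windows$win_end0)
  windows$mature_start <- s - windows$win_start0 + 1L
  windows$mature_len <- tag_len
  if (identical(locus$strand, "-")) {
    windows$seq <- revcomp(windows$seq)
    # position of the tag from the other end; 5p/3p labels swap with strand
    windows$mature_start <- windows$win_end0 - e + 1L
    windows$arm <- rev(windows$arm)
  }
  windows
}

#' Call novel miRNAs from unannotated genome-matched tags
#'
#' A tag is called novel iff at least one extracted precursor window folds
#' into a hairpin passing all eleven criteria of [evaluate_criteria()] and its
#' raw read count reaches `min_reads` in at least one library. Among passing
#' windows the one with the lowest energy is reported (ties go to the window
#' with the tag as 5' arm).
#'
#' @param tags Tibble of unannotated genome-matched tags: columns `seq`,
#'   per-library counts (`count_*` columns or a single `count`), and a `loci`
#'   list-column from [match_genome()] (computed here when absent).
#' @param genome Named character vector of chromosomes (or `mir_reference`).
#' @param min_reads Minimum raw reads in at least one library (inclusive,
#'   default 10).
#' @param flank Window flank passed to [extract_candidates()].
#' @param thresholds Criterion thresholds ([criteria_thresholds()]).
#' @param fold_file Optional path to a TSV of precomputed folds (columns
#'   `seq`, `structure`, `energy`) from an external folding engine; windows
#'   found there use the supplied structure and energy instead of
#'   [fold_rna()].
#' @return Tibble of called novel miRNAs: tag sequence, locus, strand, chosen
#'   window (`precursor`, `structure`, `energy`, `arm`, mature placement),
#'   `max_reads`, and the eleven criterion flags of the chosen window.
#' @export
call_novel <- function(tags, genome, min_reads = 10, flank = 100,
                       thresholds = criteria_thresholds(), fold_file = NULL) {
  if (!nrow(tags)) return(tibble::tibble())
  count_cols <- grep("^count", names(tags), value = TRUE)
  stopifnot(length(count_cols) >= 1L)
  if (!"loci" %in% names(tags)) tags <- match_genome(tags, genome)

  ext <- NULL
  if (!is.null(fold_file)) {
    ext <- utils::read.delim(fold_file, stringsAsFactors = FALSE)
    stopifnot(all(c("seq", "structure", "energy") %in% names(ext)))
  }
  fold_one <- function(s) {
    if (!is.null(ext)) {
      hit <- match(as_dna(s), as_dna(ext$seq))
      if (!is.na(hit)) {
        return(tibble::tibble(structure = ext$structure[hit],
                              energy = ext$energy[hit]))
      }
    }
    f <- fold_rna(s)
    tibble::tibble(structure = f$structure, energy = f$energy)
  }

  rows <- lapply(seq_len(nrow(tags)), function(i) {
    max_reads <- max(unlist(tags[i, count_cols]))
    if (max_reads < min_reads) return(NULL)
    loci <- tags$loci[[i]]
    if (!nrow(loci)) return(NULL)
    best <- NULL
    for (l in seq_len(nrow(loci))) {
      cands <- extract_candidates(loci[l, ], genome, flank = flank)
      for (k in seq_len(nrow(cands))) {
        cand <- cands[k, ]
        f <- fold_one(cand$seq)
        rep_k <- evaluate_criteria(cand$seq, f$structure, f$energy,
                                   cand$mature_start, cand$mature_len,
                                   thresholds)
        if (!rep_k$pass) next
        row <- dplyr::bind_cols(
          tibble::tibble(
            seq = tags$seq[i], chrom = loci$chrom[l],
            start0 = loci$start0[l], end0 = loci$end0[l],
            strand = loci$strand[l], arm = cand$arm,
            precursor = cand$seq, structure = f$structure,
            mature_start = cand$mature_start, mature_len = cand$mature_len,
            max_reads = max_reads
          ),
          rep_k[setdiff(names(rep_k), "reason")]
        )
        if (is.null(best) || row$energy < best$energy ||
            (row$energy == best$energy && best$arm == "3p" && row$arm == "5p")) {
          best <- row
        }
      }
    }
    best
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::mutate(out, id = sprintf("novel-call-%02d",
                                                        dplyr::row_number()),
                                      .before = 1)
  out
}
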