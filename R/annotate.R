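#' Identify conserved miRNAs by perfect catalog match
#'
#' A tag counts toward a catalog miRNA if and only if its sequence equals the
#' mature sequence exactly (T/U equivalent, case-insensitive); one mismatch is
#' enough to exclude it. Counts are raw read counts, not unique-tag counts.
#'
#' @param tags A [collapse_tags()] result (columns `seq`, `count`), optionally
#'   with a `library` column for multi-library input.
#' @param catalog Tibble with columns `id` and `seq` (mature sequences,
#'   unique per id), e.g. from [read_fasta_tbl()].
#' @return The input tags with added columns `mirna` (catalog id or `NA`) and
#'   `conserved` (logical).
#' @export
match_catalog <- function(tags, catalog) {
  stopifnot(all(c("seq", "count") %in% names(tags)),
            all(c("id", "seq") %in% names(catalog)))
  cat_seq <- as_dna(catalog$seq)
  check_alphabet(cat_seq, arg = "catalog sequence")
  dup <- duplicated(cat_seq) | duplicated(cat_seq, fromLast = TRUE)
  if (any(dup)) {
    coll <- split(catalog$id[dup], cat_seq[dup])
    stop("catalog contains duplicate mature sequences shared by: ",
         paste(vapply(coll, paste, "", collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(as_dna(tags$seq), cat_seq)
  tags$mirna <- catalog$id[idx]
  tags$conserved <- !is.na(idx)
  tags
}

#' Per-miRNA raw read counts from matched tags
#'
#' @param matched A [match_catalog()] result.
#' @param catalog The catalog used for matching; miRNAs without any matching
#'   tag are reported with count 0.
#' @return Tibble `mirna`, `count` (plus `library` when present in the input).
#' @export
conserved_counts <- function(matched, catalog) {
  grp <- intersect("library", names(matched))
  got <- matched |>
    dplyr::filter(.data$conserved) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "mirna")))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  if (length(grp)) {
    tidyr::expand_grid(library = unique(matched$library), mirna = catalog$id) |>
      dplyr::left_join(got, by = c("library", "mirna")) |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  } else {
    tibble::tibble(mirna = catalog$id) |>
      dplyr::left_join(got, by = "mirna") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  }
}

#' Match tags to a genome by exact search on both strands
#'
#' A tag is genome-matched iff its sequence occurs exactly (no mismatches) on
#' either strand. All loci are recorded as 0-based half-open intervals on the
#' plus strand; a minus-strand hit is the locus whose reverse complement
#' equals the tag. A tag matching several loci still contributes its read
#' count once to the genome-matched total, which is the denominator of the
#' differential-expression normalisation.
#'
#' @param tags Tibble with columns `seq` and `count`.
#' @param genome Named character vector of chromosome sequences (or a
#'   `mir_reference`).
#' @return The input tags with added columns `genome_matched`, `n_loci`, and
#'   a list-column `loci` of tibbles (`chrom`, `start0`, `end0`, `strand`).
#' @export
match_genome <- function(tags, genome) {
  if (inherits(genome, "mir_reference")) genome <- genome$genome
  stopifnot("seq" %in% names(tags))
  subjects <- lapply(genome, Biostrings::DNAString)
  seqs <- as_dna(tags$seq)
  loci <- lapply(seqs, function(s) {
    hits <- purrr::imap_dfr(subjects, function(subj, chrom) {
      fwd <- Biostrings::matchPattern(s, subj)
      rev <- Biostrings::matchPattern(revcomp(s), subj)
      dplyr::bind_rows(
        tibble::tibble(chrom = chrom,
                       start0 = BiocGenerics::start(fwd) - 1L,
                       end0 = BiocGenerics::end(fwd), strand = "+"),
        tibble::tibble(chrom = chrom,
                       start0 = BiocGenerics::start(rev) - 1L,
                       end0 = BiocGenerics::end(rev), strand = "-")
      )
    })
    hits
  })
  tags$genome_matched <- vapply(loci, nrow, 0L) > 0L
  tags$n_loci <- vapply(loci, nrow, 0L)
  tags$loci <- loci
  tags
}

#' Genome-matched read total of a library
#'
#' @param matched A [match_genome()] result (single library or with a
#'   `library` column).
#' @return Tibble with the genome-matched read total (per library when a
#'   `library` column is present).
#' @export
genome_matched_total <- function(matched) {
  grp <- intersect("library", names(matched))
  matched |>
    dplyr::filter(.data$genome_matched) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}

#' Annotate tags against catalog, genome and an optional exclusion set
#'
#' Convenience wrapper combining [match_catalog()] and [match_genome()] and
#' assigning each tag a status: `conserved` (perfect catalog match),
#' `excluded` (perfect match to a user-supplied exclusion catalog of other
#' non-coding RNAs — these never enter novel discovery), `genome_matched_unannotated`, or
#' `unmatched`.
#'
#' @inheritParams match_catalog
#' @inheritParams match_genome
#' @param exclude Optional tibble (`id`, `seq`) of small RNAs to exclude
#'   (rRNA/tRNA/sn(o)RNA fragments and similar).
#' @return Tags with `mirna`, `conserved`, `genome_matched`, `n_loci`, `loci`
#'   and `status` columns.
#' @export
annotate_tags <- function(tags, catalog, genome, exclude = NULL) {
  out <- match_catalog(tags, catalog)
  out <- match_genome(out, genome)
  excluded <- rep(FALSE, nrow(out))
  if (!is.null(exclude)) {
    excluded <- as_dna(out$seq) %in% as_dna(exclude$seq) & !out$conserved
  }
  out$status <- dplyr::case_when(
    out$conserved ~ "conserved",
    excluded ~ "excluded",
    out$genome_matched ~ "genome_matched_unannotated",
    TRUE ~ "unmatched"
  )
  out
}

#' Classify fluid presence of miRNAs with the reads > 10 rule
#'
#' A miRNA is detected in a fluid iff its raw read count exceeds `min_reads`
#' (strictly) in at least one condition of that fluid; miRNAs are then
#' classified as common to serum and plasma, fluid-specific, or not detected.
#'
#' @param serum,plasma Tibbles with columns `mirna`, `count_bo`, `count_ao`
#'   (raw read counts in the BO and AO libraries of that fluid).
#' @param min_reads Detection threshold; strictly greater-than (default 10,
#'   so a count of 10 does not qualify).
#' @return Tibble `mirna`, `detected_serum`, `detected_plasma`, `class` with
#'   `class` in `common`, `serum_specific`, `plasma_specific`, `not_detected`.
#' @export
classify_presence <- function(serum, plasma, min_reads = 10) {
  stopifnot(setequal(serum$mirna, plasma$mirna))
  det <- function(x) x$count_bo > min_reads | x$count_ao > min_reads
  out <- tibble::tibble(
    mirna = serum$mirna,
    detected_serum = det(serum),
    detected_plasma = det(plasma)[match(serum$mirna, plasma$mirna)]
  )
  out$class <- dplyr::case_when(
    out$detected_serum & out$detected_plasma ~ "common",
    out$detected_serum ~ "serum_specific",
    out$detected_plasma ~ "plasma_specific",
    TRUE ~ "not_detected"
  )
  out
}
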