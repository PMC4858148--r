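#' Reverse complement of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as plain character vectors.
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# T/U equivalence: everything internal works in DNA space.
as_dna <- function(x) {
  toupper(gsub("U", "T", toupper(x), fixed = TRUE))
}

as_rna <- function(x) {
  gsub("T", "U", toupper(x), fixed = TRUE)
}

check_alphabet <- function(x, extra = "", arg = "sequence") {
  ok <- grepl(paste0("^[ACGT", extra, "]+$"), as_dna(x))
  if (!all(ok)) {
    stop(arg, " contains characters outside the ACGU/ACGT alphabet: ",
         paste(head(x[!ok], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header) and `seq`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id  = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L),
    seq = unname(as.character(x))
  )
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `id` and `seq`, or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path) {
  if (is.character(x)) x <- tibble::tibble(id = names(x), seq = unname(x))
  set <- Biostrings::DNAStringSet(as_dna(x$seq))
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to a FASTQ file (Phred+33 qualities).
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq_tbl <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  tibble::tibble(
    id   = names(x),
    seq  = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads to FASTQ
#'
#' @param reads A tibble with columns `id`, `seq`, `qual` (Phred+33).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_tbl <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(set) <- reads$id
  Biostrings::writeQualityScaledXStringSet(set, path)
  invisible(path)
}

# Phred+33 mean quality per read, vectorised over a character vector.
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

new_mir_tbl <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
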