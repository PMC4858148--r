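#' Default thresholds for the eleven hairpin criteria
#'
#' The structural filter used to accept a candidate precursor as a novel
#' miRNA. All bounds are inclusive. The criteria are:
#' 1. nucleotides in one stem bulge `<= 12`;
#' 2. base pairs in the stem `>= 16`;
#' 3. energy `<= -15` (kcal/mol with a thermodynamic folder; the built-in
#'    folder's score is a calibrated stand-in, see [fold_rna()]);
#' 4. hairpin length (both stems + terminal loop, i.e. the outermost-pair
#'    span) `>= 50`;
#' 5. terminal-loop length `<= 20`;
#' 6. nucleotides in one bulge in the mature region `<= 8`;
#' 7. biased errors in one bulge in the mature region `<= 4`;
#' 8. biased bulges in the mature region `<= 2`;
#' 9. errors (unpaired positions) in the mature region `<= 7`;
#' 10. base pairs in the mature region `>= 12`;
#' 11. percent of the mature sequence inside the stem `>= 80`.
#'
#' @return Named list of the eleven thresholds.
#' @export
criteria_thresholds <- function() {
  list(
    max_stem_bulge_nt   = 12,
    min_stem_pairs      = 16,
    max_energy          = -15,
    min_hairpin_len     = 50,
    max_loop_len        = 20,
    max_mature_bulge_nt = 8,
    max_biased_errors   = 4,
    max_biased_bulges   = 2,
    max_mature_errors   = 7,
    min_mature_pairs    = 12,
    min_mature_stem_pct = 80
  )
}

#' Evaluate the eleven structural criteria on a hairpin candidate
#'
#' Feature definitions: the *terminal loop* is the unpaired run enclosed by
#' the innermost pair; the *stem* is every position inside the outermost pair
#' that is not in the terminal loop; a *bulge* is a maximal run of unpaired
#' stem positions between two consecutive stem pairs, its size counting
#' unpaired nucleotides on both arms; a *biased bulge* has unpaired
#' nucleotides on one arm only; *errors* in the mature region are its unpaired
#' positions; *biased errors in one bulge* is the arm asymmetry
#' `|unpaired 5' - unpaired 3'|` of a bulge touching the mature region.
#' Structures with more than one terminal loop are not hairpins and fail
#' outright.
#'
#' @param sequence Precursor sequence.
#' @param structure Dot-bracket structure of the same length.
#' @param energy Energy/stability score of the structure (more negative =
#'   more stable).
#' @param mature_start 1-based start of the mature miRNA within the precursor.
#' @param mature_len Length of the mature miRNA.
#' @param thresholds Criterion thresholds, see [criteria_thresholds()].
#' @return A one-row tibble: measured values (`stem_pairs`, `loop_len`,
#'   `hairpin_len`, `max_stem_bulge`, `mature_errors`, `mature_pairs`,
#'   `mature_stem_pct`, ...), the eleven criterion flags `c1`..`c11`, the
#'   overall `pass`, and a `reason` (`"ok"`, `"not_a_hairpin"`, `"no_pairs"`).
#' @export
evaluate_criteria <- function(sequence, structure, energy,
                              mature_start, mature_len,
                              thresholds = criteria_thresholds()) {
  n <- nchar(structure)
  if (nchar(sequence) != n) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  if (mature_start < 1 || mature_start + mature_len - 1 > n) {
    stop("mature interval lies outside the precursor", call. = FALSE)
  }
  pt <- pair_table(structure)
  mpos <- mature_start:(mature_start + mature_len - 1L)
  th <- thresholds

  fail_row <- function(reason) {
    crit <- as.list(setNames(rep(FALSE, 11), paste0("c", 1:11)))
    tibble::tibble(
      stem_pairs = sum(pt > seq_along(pt)), loop_len = NA_integer_,
      hairpin_len = NA_integer_, max_stem_bulge = NA_integer_,
      max_mature_bulge = NA_integer_, max_biased_errors = NA_integer_,
      n_biased_bulges = NA_integer_, mature_errors = NA_integer_,
      mature_pairs = NA_integer_, mature_stem_pct = NA_real_,
      energy = energy, !!!crit, pass = FALSE, reason = reason
    )
  }

  paired <- which(pt > 0)
  if (!length(paired)) return(fail_row("no_pairs"))

  # innermost (hairpin-loop-closing) pairs: i paired downstream with nothing
  # paired strictly between
  closing <- integer(0)
  for (i in which(pt > seq_along(pt))) {
    j <- pt[i]
    if (j - i > 1 && all(pt[(i + 1):(j - 1)] == 0)) closing <- c(closing, i)
  }
  if (length(closing) != 1L) return(fail_row("not_a_hairpin"))

  ii <- closing; jj <- pt[closing]
  loop_pos <- if (jj - ii > 1) (ii + 1L):(jj - 1L) else integer(0)
  loop_len <- length(loop_pos)
  oi <- min(paired); oj <- max(paired)
  hairpin_len <- oj - oi + 1L
  stem_pos <- setdiff(oi:oj, loop_pos)
  pairs5 <- sort(intersect(which(pt > seq_along(pt)), oi:ii))
  stem_pairs <- length(pairs5)

  # bulges between consecutive stem pairs, outer -> inner
  bulges <- list()
  if (stem_pairs > 1) {
    for (k in seq_len(stem_pairs - 1L)) {
      a <- pairs5[k];     b <- pt[a]
      cc <- pairs5[k + 1L]; d <- pt[cc]
      left  <- if (cc - a > 1) (a + 1L):(cc - 1L) else integer(0)
      right <- if (b - d > 1) (d + 1L):(b - 1L) else integer(0)
      if (length(left) + length(right) > 0) {
        bulges[[length(bulges) + 1L]] <- list(
          size = length(left) + length(right),
          left = left, right = right,
          biased = xor(length(left) == 0, length(right) == 0),
          asymmetry = abs(length(left) - length(right))
        )
      }
    }
  }

  max_stem_bulge <- if (length(bulges)) max(vapply(bulges, `[[`, 0, "size")) else 0L
  in_mature <- function(bg) length(intersect(c(bg$left, bg$right), mpos)) > 0
  mat_bulges <- Filter(in_mature, bulges)
  max_mature_bulge <- if (length(mat_bulges)) max(vapply(mat_bulges, `[[`, 0, "size")) else 0L
  max_biased_err <- if (length(mat_bulges)) max(vapply(mat_bulges, `[[`, 0, "asymmetry")) else 0L
  n_biased_bulges <- sum(vapply(mat_bulges, `[[`, FALSE, "biased"))
  mature_errors <- sum(pt[mpos] == 0)
  mature_pairs <- sum(pt[mpos] > 0)
  mature_stem_pct <- 100 * sum(mpos %in% stem_pos) / mature_len

  crit <- c(
    c1  = max_stem_bulge   <= th$max_stem_bulge_nt,
    c2  = stem_pairs       >= th$min_stem_pairs,
    c3  = energy           <= th$max_energy,
    c4  = hairpin_len      >= th$min_hairpin_len,
    c5  = loop_len         <= th$max_loop_len,
    c6  = max_mature_bulge <= th$max_mature_bulge_nt,
    c7  = max_biased_err   <= th$max_biased_errors,
    c8  = n_biased_bulges  <= th$max_biased_bulges,
    c9  = mature_errors    <= th$max_mature_errors,
    c10 = mature_pairs     >= th$min_mature_pairs,
    c11 = mature_stem_pct  >= th$min_mature_stem_pct
  )

  tibble::tibble(
    stem_pairs = stem_pairs, loop_len = loop_len, hairpin_len = hairpin_len,
    max_stem_bulge = as.integer(max_stem_bulge),
    max_mature_bulge = as.integer(max_mature_bulge),
    max_biased_errors = as.integer(max_biased_err),
    n_biased_bulges = as.integer(n_biased_bulges),
    mature_errors = as.integer(mature_errors),
    mature_pairs = as.integer(mature_pairs),
    mature_stem_pct = mature_stem_pct,
    energy = energy,
    !!!as.list(crit),
    pass = all(crit), reason = "ok"
  )
}
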