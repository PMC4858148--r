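#' Fold an RNA/DNA sequence into a nested secondary structure
#'
#' A dynamic-programming maximiser over pseudoknot-free (nested) base pairings
#' in the Nussinov style, with weighted pairs and a minimum hairpin-loop size.
#' The score rewards G:C pairs twice as much as A:U and G:U pairs; the reported
#' `energy` is the negated score, so more negative means more stable. This is a
#' deliberately simple stability score, not a nearest-neighbour thermodynamic
#' free energy; precomputed structures and energies from an external folder can
#' be supplied downstream wherever a `structure`/`energy` pair is accepted
#' (see [evaluate_criteria()] and the `fold_file` argument of [call_novel()]).
#'
#' @param sequence A single sequence (ACGU/ACGT; T and U are equivalent).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param weights Named numeric vector of pair weights, names `gc`, `au`, `gu`.
#' @return A one-row tibble with columns `seq`, `structure` (dot-bracket),
#'   `score`, `energy` (`-score`) and `n_pairs`.
#' @export
#' @examples
#' fold_rna("GGGAAACCC")
fold_rna <- function(sequence, min_loop = 3,
                     weights = c(gc = 2, au = 1, gu = 1)) {
  stopifnot(length(sequence) == 1L)
  seq_dna <- as_dna(sequence)
  check_alphabet(seq_dna)
  n <- nchar(seq_dna)
  if (n < 2) stop("cannot fold an empty or single-base sequence", call. = FALSE)
  b <- strsplit(seq_dna, "")[[1]]
  W <- pair_weight_matrix(b, weights)      # n x n, 0 where unpairable
  h <- min_loop

  # M is padded by one row/col so M[k + 1, j] is safe at k = j
  M <- matrix(0, n + 1L, n + 1L)
  for (span in seq_len(n - 1L)) {
    if (span <= h) next
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]
      ks <- (i + h + 1L):j
      w <- W[i, ks]
      ok <- w > 0
      if (any(ok)) {
        ks <- ks[ok]
        cand <- w[ok] + M[i + 1L, ks - 1L] + M[ks + 1L, j]
        best <- max(best, cand)
      }
      M[i, j] <- best
    }
  }

  structure_chr <- rep(".", n)
  # iterative traceback; prefers leaving i unpaired, then the leftmost best partner
  stack <- list(c(1L, n))
  n_pairs <- 0L
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= h) next
    if (M[i, j] == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    ks <- (i + h + 1L):j
    w <- W[i, ks]
    cand <- ifelse(w > 0, w + M[i + 1L, ks - 1L] + M[ks + 1L, j], -Inf)
    k <- ks[which(cand == M[i, j])[1]]
    structure_chr[i] <- "("
    structure_chr[k] <- ")"
    n_pairs <- n_pairs + 1L
    stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
    if (k + 1L < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
  }

  score <- M[1, n]
  tibble::tibble(
    seq = seq_dna,
    structure = paste(structure_chr, collapse = ""),
    score = score,
    energy = -score,
    n_pairs = n_pairs
  )
}

pair_weight_matrix <- function(bases, weights) {
  n <- length(bases)
  code <- match(bases, c("A", "C", "G", "T"))
  wm <- matrix(0, 4, 4)
  wm[2, 3] <- wm[3, 2] <- weights[["gc"]]   # C:G
  wm[1, 4] <- wm[4, 1] <- weights[["au"]]   # A:U(T)
  wm[3, 4] <- wm[4, 3] <- weights[["gu"]]   # G:U(T)
  matrix(wm[cbind(rep(code, n), rep(code, each = n))], n, n)
}

#' Parse a dot-bracket structure into a pair table
#'
#' @param structure Dot-bracket string (characters `.`, `(`, `)`).
#' @return Integer vector `pt` with `pt[i]` the partner of position `i`
#'   (0 if unpaired).
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c(".", "(", ")"))) {
    stop("structure may only contain '.', '(' and ')'", call. = FALSE)
  }
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets in structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets in structure", call. = FALSE)
  pt
}
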