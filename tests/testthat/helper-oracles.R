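`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used by the tests. These deliberately take different
# algorithmic routes from the package implementation.

# Two-sided Fisher p by full hypergeometric enumeration over the table
# support, from first principles with choose().
enum_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# All nested-structure scores of a sequence by explicit enumeration:
# decomposition on what the first position does (unpaired, or paired with
# each admissible k) enumerates every pseudoknot-free structure exactly once.
# Returns the full score vector; max(.) is the exhaustive-search optimum.
enum_fold_scores <- function(seq, min_loop = 3,
                             weights = c(gc = 2, au = 1, gu = 1)) {
  b <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  w <- function(x, y) {
    p <- paste0(sort(c(b[x], b[y])), collapse = "")
    switch(p, CG = weights[["gc"]], AT = weights[["au"]], GT = weights[["gu"]], 0)
  }
  rec <- function(i, j) {
    if (i > j || j - i <= min_loop) return(0)
    out <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (w(i, k) > 0) {
        left <- rec(i + 1, k - 1)
        right <- rec(k + 1, j)
        out <- c(out, as.vector(outer(left, right, "+")) + w(i, k))
      }
    }
    out
  }
  rec(1, length(b))
}

# Textbook one-way ANOVA p from sums of squares, computed by hand.
naive_anova_p <- function(values, groups) {
  g <- split(values, groups)
  n <- length(values); k <- length(g)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Dot-bracket hairpin builder for criteria tests. `arm` is a list of segments
# read outer -> inner: list(p = n) adds n stem pairs, list(b = c(left, right))
# adds a bulge with that many unpaired nt on the 5'/3' arm. `loop` is the
# terminal loop length; `flank` adds external unpaired bases on each side.
build_hairpin <- function(arm, loop, flank = c(0L, 0L)) {
  left <- right <- character(0)
  for (seg in arm) {
    if (!is.null(seg$p)) {
      left <- c(left, strrep("(", seg$p))
      right <- c(strrep(")", seg$p), right)
    } else {
      left <- c(left, strrep(".", seg$b[1]))
      right <- c(strrep(".", seg$b[2]), right)
    }
  }
  structure_chr <- paste0(strrep(".", flank[1]), paste(left, collapse = ""),
                          strrep(".", loop), paste(right, collapse = ""),
                          strrep(".", flank[2]))
  list(structure = structure_chr,
       seq = strrep("A", nchar(structure_chr)),
       n = nchar(structure_chr))
}

random_table_n200 <- function() {
  n <- sample(20:200, 1)
  n1 <- sample(5:(n - 5), 1)
  n2 <- n - n1
  a <- sample(0:n1, 1)
  c_ <- sample(0:n2, 1)
  c(a = a, b = n1 - a, c = c_, d = n2 - c_)
}
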