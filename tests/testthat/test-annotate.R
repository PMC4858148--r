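mk_catalog <- function(seqs) tibble::tibble(id = sprintf("gga-miR-x%02d",
                                                         seq_along(seqs)),
                                            seq = seqs)

test_that("match_catalog requires exact sequence identity (T/U equivalent)", {
  cat <- mk_catalog(c("ACGTACGTACGTACGTACGTAC", "GGGTTTCCCAAAGGGTTTCCCA"))
  tags <- tibble::tibble(
    seq = c("ACGTACGTACGTACGTACGTAC",          # exact
            "ACGUACGUACGUACGUACGUAC",          # same in RNA alphabet
            "ACGTACGTACGTACGTACGTAA",          # 1 mismatch
            "TTTTTTTTTTTTTTTTTTTT"),
    count = c(57L, 10L, 99L, 5L)
  )
  m <- match_catalog(tags, cat)
  expect_equal(m$mirna[1:2], rep("gga-miR-x01", 2))
  expect_true(all(is.na(m$mirna[3:4])))
  cts <- conserved_counts(m, cat)
  expect_equal(cts$count[cts$mirna == "gga-miR-x01"], 67L)
  expect_equal(cts$count[cts$mirna == "gga-miR-x02"], 0L)
})

test_that("duplicate catalog sequences are an error naming the collision", {
  cat <- tibble::tibble(id = c("a", "b"), seq = rep("ACGTACGTACGTACGTACGT", 2))
  tags <- tibble::tibble(seq = "ACGTACGTACGTACGTACGT", count = 1L)
  expect_error(match_catalog(tags, cat), "a/b")
})

test_that("match_catalog equals a brute-force string comparison oracle", {
  set.seed(21)
  cat <- mk_catalog(random_dna(15, 22))
  tags <- tibble::tibble(
    seq = c(sample(cat$seq, 10, replace = TRUE), random_dna(10, 22)),
    count = sample.int(50, 20, replace = TRUE)
  )
  m <- match_catalog(tags, cat)
  for (i in seq_len(nrow(tags))) {
    hit <- NA_character_
    for (j in seq_len(nrow(cat))) {
      if (identical(tags$seq[i], cat$seq[j])) hit <- cat$id[j]
    }
    expect_identical(m$mirna[i], hit)
  }
})

test_that("match_genome finds exact hits on both strands with 0-based loci", {
  genome <- c(chr1 = paste0(strrep("A", 50), "GGCCGGTTAACCGGAACCGGTT",
                            strrep("A", 50)))
  tag <- "GGCCGGTTAACCGGAACCGGTT"
  tags <- tibble::tibble(seq = c(tag, revcomp(tag), random_dna(1, 25)),
                         count = c(5L, 3L, 2L))
  m <- match_genome(tags, genome)
  expect_equal(m$genome_matched, c(TRUE, TRUE, FALSE))
  expect_equal(m$loci[[1]]$start0, 50L)
  expect_equal(m$loci[[1]]$end0, 72L)
  expect_equal(m$loci[[1]]$strand, "+")
  # the reverse complement matches the same interval on the minus strand
  expect_equal(m$loci[[2]]$start0, 50L)
  expect_equal(m$loci[[2]]$strand, "-")
  expect_equal(genome_matched_total(m)$total, 8L)
})

test_that("multi-locus tags count once in the genome-matched denominator", {
  locus <- "GGCCGGTTAACCGGAACCGGTT"
  genome <- c(chr1 = paste0(strrep("A", 30), locus, strrep("T", 30), locus,
                            strrep("A", 30)))
  m <- match_genome(tibble::tibble(seq = locus, count = 10L), genome)
  expect_equal(m$n_loci, 2L)
  expect_equal(genome_matched_total(m)$total, 10L)
})

test_that("annotate_tags assigns exclusive statuses and honours exclusions", {
  cfg <- sim_config(seed = 17, n_conserved = 6, n_novel_true = 1,
                    n_novel_decoy = 1, depth_per_library = 3000,
                    genome_size = 20000)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  tags <- collapse_tags(clean_reads(sim$reads$plasma_AO, cfg$adapter))
  ann <- annotate_tags(tags, ref$catalog, ref$genome)
  expect_true(all(ann$status %in% c("conserved", "excluded",
                                    "genome_matched_unannotated", "unmatched")))
  expect_true(all(ann$status[ann$conserved] == "conserved"))
  # conserved implies genome-matched: catalog sequences are genomic
  expect_true(all(ann$genome_matched[ann$conserved]))

  novel_seq <- ref$truth$mature[ref$truth$class == "novel_true"][1]
  excl <- tibble::tibble(id = "rRNA-frag", seq = novel_seq)
  ann2 <- annotate_tags(tags, ref$catalog, ref$genome, exclude = excl)
  expect_true(all(ann2$status[ann2$seq == novel_seq] == "excluded"))
})

test_that("with no junk and no novels, conserved counts equal the clean total", {
  cfg <- sim_config(seed = 19, n_conserved = 8, n_novel_true = 0,
                    n_novel_decoy = 0, junk_fraction = 0,
                    depth_per_library = 2000, genome_size = 20000)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  cl <- clean_reads(sim$reads$serum_AO, cfg$adapter)
  ann <- match_catalog(collapse_tags(cl), ref$catalog)
  expect_equal(sum(conserved_counts(ann, ref$catalog)$count), nrow(cl))
})

test_that("classify_presence applies the strict reads > 10 rule", {
  serum <- tibble::tibble(mirna = c("m1", "m2", "m3"),
                          count_bo = c(12L, 10L, 0L),
                          count_ao = c(3L, 10L, 100L))
  plasma <- tibble::tibble(mirna = c("m1", "m2", "m3"),
                           count_bo = c(4L, 10L, 100L),
                           count_ao = c(8L, 10L, 0L))
  pc <- classify_presence(serum, plasma)
  expect_equal(pc$class, c("serum_specific", "not_detected", "common"))
  # detected set is partitioned by the three detected classes
  detected <- sum(pc$class != "not_detected")
  expect_equal(sum(pc$class %in% c("common", "serum_specific",
                                   "plasma_specific")), detected)
})
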