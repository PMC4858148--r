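cfg_small <- function(...) {
  sim_config(seed = 11, n_conserved = 8, n_novel_true = 2, n_novel_decoy = 2,
             depth_per_library = 4000, genome_size = 30000, ...)
}

test_that("the simulator is deterministic under a fixed seed", {
  a <- make_reference(cfg_small())
  b <- make_reference(cfg_small())
  expect_identical(a$genome, b$genome)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$truth, b$truth)

  ra <- simulate_reads(a)
  rb <- simulate_reads(b)
  expect_identical(ra$reads, rb$reads)

  qa <- simulate_qpcr(cfg_small())
  qb <- simulate_qpcr(cfg_small())
  expect_identical(qa, qb)

  # and a different seed changes the genome
  expect_false(identical(make_reference(sim_config(seed = 12, n_conserved = 8,
                                                   n_novel_true = 2,
                                                   n_novel_decoy = 2,
                                                   genome_size = 30000))$genome,
                         a$genome))
})

test_that("planted matures sit at their recorded loci in the genome", {
  ref <- make_reference(cfg_small())
  chr <- ref$genome[["chr1"]]
  expect_equal(nchar(chr), 30000)
  for (i in seq_len(nrow(ref$truth))) {
    tr <- ref$truth[i, ]
    expect_identical(substr(chr, tr$start0 + 1, tr$end0), tr$mature)
  }
})

test_that("read counts conserve the library depth and junk budget", {
  cfg <- cfg_small()
  sim <- simulate_reads(make_reference(cfg))
  for (lib in names(sim$reads)) {
    expect_equal(nrow(sim$reads[[lib]]), cfg$depth_per_library)
    n_junk <- sum(sim$reads[[lib]]$origin == "junk")
    expect_equal(n_junk, round(cfg$junk_fraction * cfg$depth_per_library))
    cc <- sim$counts[sim$counts$library == lib, ]
    expect_equal(sum(cc$count), cfg$depth_per_library - n_junk)
  }
})

test_that("with junk_fraction 0 every read maps to a planted mature", {
  cfg <- cfg_small(junk_fraction = 0)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  inserts <- sub("TGGAATTC.*$", "", sim$reads$serum_BO$seq)
  expect_true(all(inserts %in% ref$truth$mature))
})

test_that("truth round-trip: planted hairpins pass, decoys fail as recorded", {
  ref <- make_reference(sim_config(seed = 3, n_conserved = 5, n_novel_true = 3,
                                   n_novel_decoy = 5, genome_size = 30000))
  novel <- ref$truth[ref$truth$class != "conserved", ]
  for (i in seq_len(nrow(novel))) {
    tr <- novel[i, ]
    cand <- extract_candidates(tr[c("start0", "end0", "strand")] |>
                                 transform(chrom = "chr1"), ref$genome)
    reports <- lapply(seq_len(nrow(cand)), function(k) {
      f <- fold_rna(cand$seq[k])
      evaluate_criteria(cand$seq[k], f$structure, f$energy,
                        cand$mature_start[k], cand$mature_len[k])
    })
    any_pass <- any(vapply(reports, function(r) r$pass, TRUE))
    if (tr$class == "novel_true") {
      expect_true(any_pass, label = tr$id)
    } else {
      expect_false(any_pass, label = tr$id)
      # the designed window (tag as 5' arm) violates exactly the recorded
      # criterion; other windows merely fail
      rp <- reports[[which(cand$arm == "5p")]]
      flags <- unlist(rp[paste0("c", 1:11)])
      expect_false(flags[[paste0("c", tr$violated_criterion)]], label = tr$id)
      expect_equal(sum(!flags), 1L, label = tr$id)
    }
  }
})

test_that("fold-change truth: unit ratios recover 1.0 and AO scales by fc", {
  cfg <- sim_config(seed = 5, n_conserved = 10, n_novel_true = 0,
                    n_novel_decoy = 0, genome_size = 30000,
                    fold_changes = setNames(rep(1, 10),
                                            sprintf("gga-miR-s%03d", 1:10)),
                    dispersion = 0.002, depth_per_library = 200000L)
  ref <- make_reference(cfg)
  expect_true(all(ref$truth$effective_log2fc == 0))
  cts <- simulate_counts(ref, cfg)
  wide <- tapply(cts$count, list(cts$id, cts$condition), sum)
  ratio <- (wide[, "AO"] / sum(wide[, "AO"])) / (wide[, "BO"] / sum(wide[, "BO"]))
  expect_true(all(abs(log2(ratio)) < 0.35))
  expect_lt(abs(mean(log2(ratio))), 0.1)
})

test_that("qPCR generator reproduces the programmed temporal shapes", {
  pat <- c(a = "panel", b = "transient", c = "flat")
  cfg <- sim_config(seed = 2, qpcr_patterns = pat, qpcr_noise_sd = 0,
                    qpcr_step = 2, qpcr_drift = 0)
  cq <- simulate_qpcr(cfg)
  dc <- delta_cq(cq)
  prof <- rel_expression(dc, baseline_stage = 10)

  flat <- prof[prof$mirna == "c", ]
  expect_true(all(abs(flat$level - 1) < 1e-12))

  panel <- prof[prof$mirna == "a", ]
  expect_equal(panel$level[panel$stage_week == 13], 4)     # step of 2 cycles
  expect_equal(panel$level[panel$stage_week == 10], 1)
  expect_equal(panel$level[panel$stage_week == 16], 4)

  trans <- prof[prof$mirna == "b", ]
  expect_equal(trans$level[trans$stage_week == 13], 4)
  expect_equal(trans$level[trans$stage_week == 16], 1)
})

test_that("qPCR U6 reference stays within the 0.6-cycle bound", {
  ok <- vapply(1:200, function(s) {
    cq <- simulate_qpcr(sim_config(seed = s, qpcr_noise_sd = 0.15))
    validate_reference(cq)$valid
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("a written simulation round-trips through the plain-text formats", {
  cfg <- cfg_small()
  ref <- make_reference(cfg)
  outdir <- withr::local_tempdir()
  sim <- simulate_reads(ref, outdir = outdir)
  genome <- read_fasta_tbl(file.path(outdir, "genome.fa"))
  expect_equal(genome$seq, unname(ref$genome))
  catalog <- read_fasta_tbl(file.path(outdir, "catalog.fa"))
  expect_equal(catalog, ref$catalog)
  fq <- read_fastq_tbl(file.path(outdir, "serum_BO.fastq"))
  expect_equal(fq$seq, sim$reads$serum_BO$seq)
})

test_that("config validation catches bad inputs", {
  expect_error(sim_config(junk_fraction = 1.5))
  expect_error(sim_config(fold_changes = c(a = -1)), "positive")
  expect_error(sim_config(decoy_criteria = 3L), "decoy_criteria")
  expect_error(simulate_qpcr(sim_config(), replicates = 1), "replicates")
  cfg <- sim_config(seed = 1, n_conserved = 8, depth_per_library = 5L,
                    genome_size = 30000)
  ref <- make_reference(cfg_small())
  expect_error(simulate_counts(ref, cfg), "below the number")
})
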