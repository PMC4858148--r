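#' Simulation configuration
#'
#' Bundles every tunable of the ground-truth simulator. Defaults emulate the
#' study conditions of a two-stage (BO = before puberty onset, AO = after
#' puberty onset), two-fluid (serum, plasma) circulating small-RNA experiment:
#' pooled libraries without biological replicates, read length mode between 20
#' and 24 nt, planted conserved miRNAs whose AO/BO fold-changes span 0.09 to
#' 16.5, planted novel hairpins that satisfy (or violate, for decoys) the
#' eleven structural criteria, adapter-dimer and sub-18 nt junk reads, and
#' weekly (10-16) Cq profiles with panel/transient/flat temporal shapes.
#' Library depth defaults to a desk-scale 20,000 reads; the sequenced study
#' ran at 10^6-10^7 reads and `depth_per_library` can be raised accordingly.
#'
#' @param seed Integer seed; a fixed seed makes every simulator output
#'   byte-identical on re-run.
#' @param n_conserved Number of catalog (known) miRNAs planted in the genome.
#' @param n_novel_true Number of planted hairpins satisfying all eleven
#'   criteria.
#' @param n_novel_decoy Number of planted hairpins violating exactly one
#'   recorded criterion each.
#' @param depth_per_library Raw reads per library.
#' @param read_length Raw read length in nt (reads run through the 3' adapter).
#' @param length_mode_range Interval (nt) in which the clean-read length mode
#'   must fall; mature lengths are drawn from it with a peak at 22 nt.
#' @param junk_fraction Proportion of junk reads per library; half are
#'   adapter dimers, half 10-17 nt fragments, exercising both cleaning filters.
#' @param dispersion Negative-binomial dispersion of per-species counts
#'   (variance `mu + dispersion * mu^2`). The study pooled animals into single
#'   libraries so no replicate variance is observable; 0.1 is a conventional
#'   bulk-RNA value.
#' @param fold_changes Optional named numeric vector, catalog miRNA id ->
#'   true AO/BO expression ratio. `NULL` assigns defaults spanning 0.09-16.5
#'   to the first twelve conserved miRNAs and 1 to the rest.
#' @param adapter 3' adapter sequence (Illumina TruSeq small RNA).
#' @param decoy_criteria Integer vector recycled over decoys; which criterion
#'   each decoy violates (supported: 1, 2, 4, 5, 11).
#' @param qpcr_patterns Optional named character vector, miRNA -> temporal
#'   pattern (`"panel"`, `"transient"`, `"flat"`). `NULL` uses the nine
#'   candidate serum miRNAs with seven `"panel"` and two `"transient"`.
#' @param qpcr_noise_sd Additive Gaussian noise on Cq values (cycles).
#' @param qpcr_step Cq decrease (cycles) at the onset week; a doubling of
#'   expression is exactly one cycle, so a step of 2 is a 4-fold rise.
#' @param qpcr_drift Further Cq decrease per week after onset for the
#'   `"panel"` pattern (levels keep or gain after onset).
#' @param genome_size Synthetic genome length (nt).
#' @param spacer Spacer length (nt) between planted loci.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_conserved = 20L,
                       n_novel_true = 8L,
                       n_novel_decoy = 6L,
                       depth_per_library = 20000L,
                       read_length = 50L,
                       length_mode_range = c(20L, 24L),
                       junk_fraction = 0.1,
                       dispersion = 0.1,
                       fold_changes = NULL,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       decoy_criteria = c(5L, 2L, 4L, 11L, 1L),
                       qpcr_patterns = NULL,
                       qpcr_noise_sd = 0.2,
                       qpcr_step = 2,
                       qpcr_drift = 0.15,
                       genome_size = 100000L,
                       spacer = 200L) {
  cfg <- list(
    seed = as.integer(seed), n_conserved = as.integer(n_conserved),
    n_novel_true = as.integer(n_novel_true),
    n_novel_decoy = as.integer(n_novel_decoy),
    depth_per_library = as.integer(depth_per_library),
    read_length = as.integer(read_length),
    length_mode_range = as.integer(length_mode_range),
    junk_fraction = junk_fraction, dispersion = dispersion,
    fold_changes = fold_changes, adapter = toupper(adapter),
    decoy_criteria = as.integer(decoy_criteria),
    qpcr_patterns = qpcr_patterns, qpcr_noise_sd = qpcr_noise_sd,
    qpcr_step = qpcr_step, qpcr_drift = qpcr_drift,
    genome_size = as.integer(genome_size), spacer = as.integer(spacer)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_conserved >= 1L, cfg$n_novel_true >= 0L, cfg$n_novel_decoy >= 0L,
    cfg$depth_per_library >= 1L,
    cfg$junk_fraction >= 0, cfg$junk_fraction <= 1,
    cfg$dispersion >= 0, cfg$qpcr_noise_sd >= 0,
    length(cfg$length_mode_range) == 2L,
    cfg$length_mode_range[1] <= cfg$length_mode_range[2],
    nchar(cfg$adapter) >= 8L
  )
  if (!is.null(cfg$fold_changes) && any(cfg$fold_changes <= 0)) {
    stop("fold_changes must be strictly positive", call. = FALSE)
  }
  if (!all(cfg$decoy_criteria %in% c(1L, 2L, 4L, 5L, 11L))) {
    stop("decoy_criteria must be drawn from {1, 2, 4, 5, 11}", call. = FALSE)
  }
  invisible(cfg)
}

# AO/BO expression ratios spanning the 0.09-16.5 range of the study's
# most-changed serum miRNAs.
default_fold_changes <- function(n) {
  fc <- c(16.48, 5.83, 4.25, 3.14, 2.32, 2.00, 0.50, 0.45, 0.33, 0.24, 0.15, 0.09)
  out <- rep(1, n)
  out[seq_len(min(n, length(fc)))] <- fc[seq_len(min(n, length(fc)))]
  out
}

#' The nine RT-qPCR candidate miRNAs and their default temporal patterns
#'
#' Seven members behave as sustained puberty-onset markers (`"panel"`) and two
#' rise at onset but fall back (`"transient"`).
#'
#' @return Named character vector, miRNA id -> pattern label.
#' @export
default_qpcr_patterns <- function() {
  c("gga-miR-29c-3p" = "panel",  "gga-miR-375"     = "panel",
    "gga-miR-215-5p" = "panel",  "gga-miR-217-5p"  = "panel",
    "gga-miR-19b-3p" = "panel",  "gga-miR-133a-3p" = "panel",
    "gga-let-7a"     = "panel",  "gga-miR-155"     = "transient",
    "gga-miR-9-5p"   = "transient")
}

# ---- reference construction ------------------------------------------------

gc_dna <- function(len) paste(sample(c("G", "C"), len, replace = TRUE), collapse = "")

# one hairpin design per class; arms are G/C-only and loops/bulges/pads
# A-only so the planted structure is the strict fold optimum (A cannot pair
# without U, and every G/C base is paired in the design)
design_novel <- function(kind, criterion = NA_integer_) {
  loopA <- function(n) strrep("A", n)
  if (kind == "true") {
    mature <- gc_dna(22); arm1 <- paste0(mature, gc_dna(8))
    list(precursor = paste0(arm1, loopA(8), revcomp(arm1)),
         mature = mature, mature_start = 1L)
  } else if (criterion == 5L) {
    mature <- gc_dna(22); arm1 <- paste0(mature, gc_dna(8))
    list(precursor = paste0(arm1, loopA(21), revcomp(arm1)),
         mature = mature, mature_start = 1L)
  } else if (criterion == 2L) {
    arm1 <- gc_dna(15)
    pre <- paste0(arm1, loopA(20), revcomp(arm1))
    list(precursor = pre, mature = substr(pre, 1, 18), mature_start = 1L)
  } else if (criterion == 4L) {
    arm1 <- gc_dna(18)
    pre <- paste0(arm1, loopA(8), revcomp(arm1))
    list(precursor = pre, mature = substr(pre, 1, 22), mature_start = 1L)
  } else if (criterion == 11L) {
    arm1 <- gc_dna(30)
    pre <- paste0(loopA(6), arm1, loopA(8), revcomp(arm1))
    list(precursor = pre, mature = substr(pre, 1, 20), mature_start = 1L)
  } else if (criterion == 1L) {
    # 13 nt bulge (7 + 6) in the stem, downstream of a fully paired mature
    mature <- gc_dna(20); seg2 <- gc_dna(10)
    pre <- paste0(mature, loopA(7), seg2, loopA(8),
                  revcomp(seg2), loopA(6), revcomp(mature))
    list(precursor = pre, mature = mature, mature_start = 1L)
  } else {
    stop("unsupported decoy criterion: ", criterion, call. = FALSE)
  }
}

# fold the extraction window the discovery stage will see (mature + 100 nt of
# downstream context) and evaluate the criteria on it
verify_design <- function(design, flank = 100) {
  win <- paste0(substr(design$precursor, design$mature_start,
                       nchar(design$precursor)),
                strrep("A", 130))
  win <- substr(win, 1, nchar(design$mature) + flank)
  f <- fold_rna(win)
  evaluate_criteria(win, f$structure, f$energy,
                    mature_start = 1L, mature_len = nchar(design$mature))
}

#' Build the synthetic reference: genome, catalog and ground truth
#'
#' Embeds each catalog mature sequence in a hairpin context at a recorded
#' genomic locus, plants `n_novel_true` hairpins that satisfy all eleven
#' criteria of [evaluate_criteria()] by construction (verified through the
#' folding and criteria engines at build time), and `n_novel_decoy` hairpins
#' that each violate exactly one recorded criterion. Sequence collisions (a
#' mature sequence occurring at an unplanned locus) trigger regeneration with
#' perturbed flanks; construction fails after bounded retries.
#'
#' @param config A [sim_config()].
#' @param max_tries Retries for collision-free genome assembly and for each
#'   planted-hairpin design.
#' @return A list of class `mir_reference` with elements `genome` (named
#'   character vector of chromosomes), `catalog` (tibble `id`, `seq`),
#'   `truth` (one row per planted entity: id, class, locus, base RPM, nominal
#'   fold-change, effective log2 fold-change after renormalisation,
#'   compliance flag, violated criterion), `hairpins` (planted precursor
#'   details) and `config`.
#' @export
make_reference <- function(config = sim_config(), max_tries = 25L) {
  validate_sim_config(config)
  set.seed(config$seed)

  for (try in seq_len(max_tries)) {
    ref <- try_build_reference(config, max_tries)
    if (!is.null(ref)) return(ref)
  }
  stop("could not assemble a collision-free reference after ", max_tries,
       " attempts", call. = FALSE)
}

try_build_reference <- function(config, max_tries) {
  n_c <- config$n_conserved
  lens <- config$length_mode_range[1]:config$length_mode_range[2]
  len_prob <- stats::dnorm(lens, mean = 22, sd = 1.2)

  catalog <- tibble::tibble(
    id = sprintf("gga-miR-s%03d", seq_len(n_c)),
    seq = random_dna(n_c, 1)  # placeholder, filled below with varied lengths
  )
  catalog$seq <- vapply(seq_len(n_c), function(i) {
    random_dna(1, sample(lens, 1, prob = len_prob))
  }, character(1))
  if (anyDuplicated(catalog$seq)) return(NULL)

  # planted novel hairpins, verified through fold + criteria at construction
  kinds <- c(rep("true", config$n_novel_true), rep("decoy", config$n_novel_decoy))
  crits <- c(rep(NA_integer_, config$n_novel_true),
             rep_len(config$decoy_criteria, config$n_novel_decoy))
  designs <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      d <- design_novel(kinds[i], crits[i])
      rep_i <- verify_design(d)
      flags <- unlist(rep_i[paste0("c", 1:11)])
      ok <- if (kinds[i] == "true") {
        isTRUE(rep_i$pass)
      } else {
        !rep_i$pass && !flags[crits[i]] && sum(!flags) == 1L
      }
      if (ok) break
    }
    if (!ok) return(NULL)
    designs[[i]] <- d
  }

  # genome assembly: random filler between blocks; adenine-only pads around
  # novel hairpins keep the +/-100 nt extraction windows pairing-inert
  blocks <- character(0)
  loci <- list()
  pos <- 0L
  add <- function(s) { blocks[[length(blocks) + 1L]] <<- s; pos <<- pos + nchar(s) }
  for (i in seq_len(n_c)) {
    add(random_dna(1, config$spacer))
    m <- catalog$seq[i]
    start0 <- pos
    add(paste0(m, "CAACAAC", revcomp(m)))
    loci[[length(loci) + 1L]] <- tibble::tibble(
      id = catalog$id[i], class = "conserved", mature = m,
      start0 = start0, end0 = start0 + nchar(m), strand = "+",
      precursor = NA_character_, violated_criterion = NA_integer_
    )
  }
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    cls <- if (kinds[i] == "true") "novel_true" else "novel_decoy"
    id <- sprintf("novel-%s-%02d", if (kinds[i] == "true") "t" else "d", i)
    add(random_dna(1, config$spacer))
    add(strrep("A", 120))
    start0 <- pos + d$mature_start - 1L
    add(d$precursor)
    add(strrep("A", 120))
    loci[[length(loci) + 1L]] <- tibble::tibble(
      id = id, class = cls, mature = d$mature,
      start0 = start0, end0 = start0 + nchar(d$mature), strand = "+",
      precursor = d$precursor, violated_criterion = crits[i]
    )
  }
  genome1 <- paste(blocks, collapse = "")
  if (nchar(genome1) < config$genome_size) {
    genome1 <- paste0(genome1, random_dna(1, config$genome_size - nchar(genome1)))
  }
  truth <- dplyr::bind_rows(loci)

  # collision check: every planted mature occurs forward exactly once (its
  # planned locus). A second, minus-strand occurrence at the hairpin's own
  # star arm is inherent to planting a hairpin and is not a collision.
  subj <- Biostrings::DNAString(genome1)
  fwd_hits <- vapply(truth$mature, Biostrings::countPattern, 0L, subject = subj)
  if (any(fwd_hits != 1L)) return(NULL)

  # expression truth: base abundance and effective (renormalised) fold-change
  fc <- config$fold_changes
  if (is.null(fc)) fc <- setNames(default_fold_changes(n_c), catalog$id)
  truth$fold_change <- ifelse(truth$id %in% names(fc), fc[truth$id], 1)
  n_nov <- length(designs)
  base <- c(
    ifelse(truth$fold_change[seq_len(n_c)] != 1,
           10^runif(n_c, 2.3, 3.3),         # DE-planted: RPM ~200-2000
           10^runif(n_c, 2.9, 3.6)),        # flat background: RPM ~800-4000
    10^runif(n_nov, 3.2, 3.5)               # novel: abundant enough to call
  )
  truth$base_rpm <- base
  w_bo <- sum(truth$base_rpm)
  w_ao <- sum(truth$base_rpm * truth$fold_change)
  truth$effective_log2fc <- log2(truth$fold_change) + log2(w_bo / w_ao)
  truth$compliant <- dplyr::case_when(
    truth$class == "novel_true" ~ TRUE,
    truth$class == "novel_decoy" ~ FALSE,
    TRUE ~ NA
  )

  structure(
    list(genome = c(chr1 = genome1), catalog = catalog, truth = truth,
         config = config),
    class = "mir_reference"
  )
}

#' @export
print.mir_reference <- function(x, ...) {
  cat("<mir_reference> genome", nchar(x$genome[[1]]), "nt |",
      nrow(x$catalog), "catalog miRNAs |",
      sum(x$truth$class == "novel_true"), "novel +",
      sum(x$truth$class == "novel_decoy"), "decoy hairpins\n")
  invisible(x)
}

# ---- read/count simulation -------------------------------------------------

sim_libraries <- function() {
  tidyr::expand_grid(fluid = c("serum", "plasma"), condition = c("BO", "AO")) |>
    dplyr::mutate(library = paste(.data$fluid, .data$condition, sep = "_"))
}

#' Simulate per-species read counts for every library
#'
#' The count model is hierarchical: each species receives a Gamma multiplier
#' with unit mean and variance `dispersion`, and library counts are drawn
#' multinomially with probabilities proportional to
#' `base_rpm * fold_change^(condition == "AO") * multiplier`. Marginally each
#' count is negative-binomial-like with variance `mu + dispersion * mu^2`,
#' while totals are exactly `depth * (1 - junk_fraction)` per library.
#'
#' @param reference A [make_reference()] result.
#' @param config Defaults to the reference's config.
#' @param depth Reads per library before junk; defaults to
#'   `depth_per_library`.
#' @return Tibble with columns `library`, `fluid`, `condition`, `id`, `class`,
#'   `count`.
#' @export
simulate_counts <- function(reference, config = reference$config,
                            depth = config$depth_per_library) {
  set.seed(config$seed + 3L)
  truth <- reference$truth
  n_junk <- round(config$junk_fraction * depth)
  t_reads <- depth - n_junk
  if (t_reads < nrow(truth)) {
    stop("library depth (", t_reads, " non-junk reads) is below the number ",
         "of planted species (", nrow(truth), ")", call. = FALSE)
  }
  libs <- sim_libraries()
  purrr::pmap_dfr(libs, function(fluid, condition, library) {
    mu <- truth$base_rpm * if (condition == "AO") truth$fold_change else 1
    g <- if (config$dispersion > 0) {
      rgamma(length(mu), shape = 1 / config$dispersion, scale = config$dispersion)
    } else rep(1, length(mu))
    counts <- as.integer(rmultinom(1, t_reads, prob = mu * g))
    tibble::tibble(library = library, fluid = fluid, condition = condition,
                   id = truth$id, class = truth$class, count = counts)
  })
}

#' Simulate raw FASTQ-style reads for all four libraries
#'
#' Builds raw reads (insert + 3' adapter, padded to `read_length`) for each of
#' the four libraries (serum/plasma x BO/AO) from [simulate_counts()], plus
#' the configured junk fraction: half adapter-dimer reads and half 10-17 nt
#' fragments.
#'
#' @inheritParams simulate_counts
#' @param outdir Optional directory; when given, one FASTQ per library plus
#'   `genome.fa`, `catalog.fa` and `truth.tsv` are written there.
#' @return A list of class `mir_simulation`: `reads` (named list of tibbles
#'   `id`, `seq`, `qual`), `counts` (the per-library truth counts), and
#'   `reference`.
#' @export
simulate_reads <- function(reference, config = reference$config, outdir = NULL) {
  set.seed(config$seed + 1L)
  counts <- simulate_counts(reference, config)
  truth <- reference$truth
  adapter <- config$adapter
  rl <- config$read_length
  pad_to <- function(x) {
    out <- substr(paste0(x, strrep("A", rl)), 1, rl)
    out
  }

  reads <- lapply(split(counts, counts$library), function(cc) {
    seqs <- rep(truth$mature[match(cc$id, truth$id)], cc$count)
    origin <- rep(cc$id, cc$count)
    n_junk <- round(config$junk_fraction * config$depth_per_library)
    n_dimer <- floor(n_junk / 2)
    n_frag <- n_junk - n_dimer
    junk_seqs <- rep(strrep(adapter, 3), n_dimer)
    if (n_frag > 0) {
      frag_len <- sample(10:17, n_frag, replace = TRUE)
      frags <- vapply(frag_len, function(l) random_dna(1, l), character(1))
      junk_seqs <- c(junk_seqs, paste0(frags, adapter))
    }
    all_seq <- pad_to(c(paste0(seqs, adapter), junk_seqs))
    origin <- c(origin, rep("junk", length(junk_seqs)))
    ord <- sample.int(length(all_seq))
    lib <- cc$library[1]
    tibble::tibble(
      id = sprintf("%s_%06d", lib, seq_along(ord)),
      seq = all_seq[ord],
      qual = strrep("I", rl),
      origin = origin[ord]
    )
  })

  sim <- structure(list(reads = reads, counts = counts, reference = reference),
                   class = "mir_simulation")
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' Write a simulation to disk as plain-text FASTA/FASTQ/TSV
#'
#' @param sim A [simulate_reads()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim$reference
  write_fasta_tbl(ref$genome, file.path(outdir, "genome.fa"))
  write_fasta_tbl(ref$catalog, file.path(outdir, "catalog.fa"))
  utils::write.table(ref$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (lib in names(sim$reads)) {
    write_fastq_tbl(sim$reads[[lib]][c("id", "seq", "qual")],
                    file.path(outdir, paste0(lib, ".fastq")))
  }
  invisible(outdir)
}

# ---- qPCR simulation -------------------------------------------------------

#' Simulate a weekly RT-qPCR Cq table
#'
#' Generates replicate Cq values for each candidate miRNA across weekly stages
#' plus the U6 reference. Pattern shapes: `"panel"` is flat before the onset
#' week, steps down by `qpcr_step` cycles at onset (higher expression) and
#' then keeps or gains (drifts down by `qpcr_drift` cycles/week); `"transient"`
#' shows the same onset step but returns to the early level by week 15;
#' `"flat"` never steps. U6 is constant across stages up to noise. A Cq
#' decrease of exactly 1 corresponds to an expression doubling.
#'
#' @param config A [sim_config()]; `qpcr_patterns`, `qpcr_noise_sd`,
#'   `qpcr_step` and `qpcr_drift` are used.
#' @param stages Integer vector of sampled weeks.
#' @param replicates Replicates per miRNA and stage (>= 2).
#' @param onset_week Week of the expression step.
#' @return Tibble `mirna`, `stage_week`, `replicate`, `cq`; U6 rows carry
#'   `mirna = "U6"`.
#' @export
simulate_qpcr <- function(config = sim_config(), stages = 10:16,
                          replicates = 6L, onset_week = 13L) {
  if (replicates < 2L) {
    stop("at least 2 replicates are required (ANOVA is undefined otherwise)",
         call. = FALSE)
  }
  patterns <- config$qpcr_patterns
  if (is.null(patterns)) patterns <- default_qpcr_patterns()
  set.seed(config$seed + 2L)
  base_cq <- setNames(runif(length(patterns), 22, 28), names(patterns))

  mean_cq <- function(pattern, base, week) {
    s <- config$qpcr_step
    switch(pattern,
      panel = if (week < onset_week) base
              else base - s - config$qpcr_drift * (week - onset_week),
      transient = if (week >= onset_week && week < onset_week + 2) base - s
                  else base,
      flat = base,
      stop("unknown qPCR pattern: ", pattern, call. = FALSE)
    )
  }

  grid <- tidyr::expand_grid(
    mirna = c(names(patterns), "U6"),
    stage_week = as.integer(stages),
    replicate = seq_len(replicates)
  )
  grid$mu <- purrr::map2_dbl(grid$mirna, grid$stage_week, function(m, w) {
    if (m == "U6") 15 else mean_cq(patterns[[m]], base_cq[[m]], w)
  })
  grid$cq <- grid$mu + rnorm(nrow(grid), sd = config$qpcr_noise_sd)
  grid[c("mirna", "stage_week", "replicate", "cq")]
}
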