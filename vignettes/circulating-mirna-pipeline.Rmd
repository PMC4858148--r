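---
title: "Methods: circulating miRNA biomarker discovery with circamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulating miRNA biomarker discovery with circamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`circamir` re-implements a serum/plasma small-RNA biomarker screen as
composable, tested functions: read cleaning, conserved/novel miRNA
identification, count-based differential expression between two pubertal
stages (BO/AO), candidate screening, and RT-qPCR relative quantification
with a temporal panel rule. This vignette documents the statistical model
behind each stage, the defaults and why they were chosen, what the
ground-truth simulator does and does not emulate, and the design decisions
taken where the underlying procedure left genuine freedom.

## Read cleaning

Raw reads are assumed to run through the insert into the 3' adapter.
Cleaning applies, in order: a mean-Phred quality gate, adapter trimming at
the leftmost exact match of the adapter's first 8 nt, and an 18–35 nt insert
length window with an N filter. Reads whose adapter prefix starts at
position 1 are adapter dimers; together with adapter-absent reads they are
tallied as `adaptor_pollution`. The per-filter tally always partitions
`raw − clean` exactly, which the tests assert.

Choices the procedure leaves open, and the defaults here:

* **"Poor quality"** is not defined upstream; the default is mean Phred ≥ 20
  (`min_mean_q`), a conventional small-RNA cut, and it is flag-controlled.
* **Adapter matching** is an exact 8-mer prefix match with no mismatch
  tolerance (`adapter_match_len`). At desk scale this is transparent and
  deterministic; a mismatch-tolerant trimmer would change counts only for
  sequencing-error-bearing reads, which the simulator does not generate.
* **Adapter-absent reads** are discarded by default (`require_adapter =
  TRUE`); a lenient mode keeps them untrimmed, since an assay that gel-cuts
  18–35 nt fragments cannot guarantee every read reaches the adapter.
  Cleaning is idempotent only in the lenient mode — re-cleaning already
  trimmed reads finds no adapter — and the tests assert both behaviours.
* The 35 nt **upper bound** is enforced at cleaning, mirroring the gel
  excision window of the assay.

## Annotation and the presence rule

A tag is a *conserved* miRNA iff it equals a catalog mature sequence
exactly, with T/U treated as identical; one mismatch disqualifies.
Counts credited to a miRNA are raw read counts, not unique-tag counts.
Duplicate mature sequences under different catalog ids are refused as an
error: silently crediting both would double-count, and the ambiguity is the
caller's to resolve. Genome matching is exact substring search on both
strands; a tag matching several loci contributes its reads **once** to the
per-library genome-matched total, which is the normalisation denominator
downstream (how multi-locus reads enter the denominator is not specified
upstream; this choice is explicit and local to `genome_matched_total()`).
Annotation of other non-coding RNA classes against external databases is
out of scope; an optional user-supplied exclusion FASTA marks tags
`excluded` so they never enter novel discovery.

Fluid presence uses the strict rule: detected iff raw reads **> 10** (i.e.
≥ 11) in at least one condition of that fluid, and miRNAs are classified
common / serum-specific / plasma-specific / not detected.

## Novel miRNA discovery

Unannotated genome-matched tags seed two precursor windows per locus: the
tag as 5' arm (`[start, end + 100)`) and the tag as 3' arm
(`[start − 100, end)`), reverse-complemented for minus-strand loci and
truncated at chromosome ends. The 100 nt flank bounds precursor length
comfortably above the ≥ 50 nt span criterion.

**Folding.** The built-in folder is a dynamic-programming maximiser over
pseudoknot-free nested pairings in the Nussinov style: pair weights
G:C = 2, A:U = 1, G:U = 1, minimum hairpin loop 3 nt, and the reported
energy is the negated score. This is a *stability score*, not a
nearest-neighbour free energy; the −15 threshold of criterion 3 is applied
to whichever energy is supplied, and every entry point accepts precomputed
structures and energies from an external thermodynamic folder
(`fold_file`), in which case −15 has its usual kcal/mol meaning. The tests
prove the DP equal to exhaustive enumeration of all nested structures for
lengths ≤ 16. Traceback prefers leaving a base unpaired and then the
leftmost best partner, making results deterministic under ties.

**The eleven criteria.** Feature definitions on the dot-bracket structure:
the *terminal loop* is the unpaired run enclosed by the innermost pair; the
*stem* is everything inside the outermost pair that is not terminal loop; a
*bulge* is a maximal unpaired run between consecutive stem pairs, its size
counting both arms; a *biased bulge* has unpaired bases on one arm only;
*errors* in the mature region are its unpaired positions; *biased errors in
one bulge* is the per-bulge arm asymmetry `|unpaired 5' − unpaired 3'|`
(the most common reading of this otherwise undefined quantity, and
configurable); criterion 4's "hairpin length" is the outermost-pair span,
not the window length. All eleven bounds are inclusive, and the tests pin
each boundary with hand-built structures that pass at the bound and fail
one unit past it. Structures with more than one terminal loop are rejected
as "not a hairpin" rather than re-folded under constraints. A tag is called
novel iff some window passes all eleven criteria and its raw reads reach 10
in at least one library; among passing windows the lowest energy wins, ties
going to the 5'-arm window.

## Differential expression

With per-library genome-matched totals `N`, expression is
`RPM = 10^6 · count / N`. Each miRNA is tested on the 2×2 table
`[[c_BO, N_BO − c_BO], [c_AO, N_AO − c_AO]]` with Fisher's exact test
(two-sided, sum of hypergeometric probabilities ≤ the observed table's) and
Pearson's chi-square without continuity correction. The procedure names
both tests without saying which gates significance; Fisher is primary here
(exact at any count) and the chi-square is reported alongside — the tests
check their asymptotic agreement on well-filled tables.

Fold-change is computed on RPM. When either raw count is zero, a 0.5-read
pseudocount enters both conditions *for the ratio only*, keeping reported
fold-changes finite without perturbing the tests. Display values are
conventionally rounded to 2 decimals (`tidy()`), but screening always uses
full precision; the inclusive |log2FC| ≥ 1.0 boundary is asserted exactly.
No multiple-testing correction is applied by default, matching the
single-pass screen the pipeline reproduces; with `adjust = "BH"` the
flagged set is provably a subset of the unadjusted one, which is asserted
as a monotonicity property. RT-qPCR candidates additionally require raw
reads ≥ 40 in some condition ("more than middle expression") and an
annotation term from the reproduction vocabulary (gonad/muscle development,
glucose/fat/insulin metabolism, sex hormone synthesis and secretion).

The package ships the published 40-row fold-change table of the chicken
serum screen (`chicken_serum_de_top40()`) as a worked example. Both printed
columns are rounded to 2 decimals, so recomputing `log2(fold_change)` can
only be expected to match where rounding leaves room:
`check_log2_consistency()` calls a row consistent when *some* fold-change
within ±0.005 of the printed value reproduces the printed log2. 39 of the
40 rows are consistent; the one exception (0.15 / −2.80) cannot arise from
any fold-change that rounds to 0.15 and is treated as a printing artefact.

## RT-qPCR quantification and the panel rule

ΔCq = Cq(miRNA) − Cq(U6), with U6 paired per replicate by default. The
pairing choice deserves a word: subtracting the *stage-mean* U6 (also
available, `pairing = "stage_mean"`) leaves the stage means — and therefore
every 2^−ΔΔCq level — unchanged, but it hides the shared U6 measurement
error from the within-stage replicate variance. Every stage-wise test then
sees a common reference fluctuation as if it were a real stage difference,
and becomes anticonservative; across a seven-member panel those excess
false rejections compound into unreliable panel recovery. Per-replicate
pairing folds the reference noise into the replicate variance, giving
correctly sized tests, and is the default for that reason. ΔΔCq is referenced to week 10, the earliest sampled
stage, so the baseline level is exactly 1; levels are 2^−ΔΔCq and are
invariant to any global Cq shift, which is asserted as a property. U6 is
accepted as reference only when the largest between-stage difference of its
mean Cq is below 0.6 cycles. Stage comparisons use classic one-way
fixed-effects ANOVA on replicate ΔCq (two stages ⇒ F = t²); the degenerate
all-equal case returns p = 1 by convention.

The panel rule encodes the temporal signature of a puberty-onset marker:

* `early_ok` — low and stable expression before onset;
* `onset_jump` — a significant (P < 0.01) rise from week 12 to 13;
* `sustained` — for every later week, the level stays at or above the
  week-13 level, or any decrease is not significant at 0.05 ("kept or
  further increased until first egg", mapped to the last sampled week).

The "low and stable (P < 0.05)" phrasing admits two readings, and both are
implemented behind `early_rule`. The default, `"low_level"`, tests that the
pooled pre-onset ΔCq is significantly *higher* (lower expression) than at
onset — a power-based criterion that is essentially always correct when a
real onset step exists. The alternative, `"stability"`, requires the
weeks-10–12 ANOVA to be non-significant; being a pure test-size criterion
it falsely rejects a truly stable miRNA 5 % of the time, so across a
seven-member panel the probability that *all* members pass is only about
0.95⁷ ≈ 0.70 — an operating characteristic that makes exact panel recovery
unreliable no matter how clean the data. That arithmetic, not a data fit,
is why `"low_level"` is the default.

## The ground-truth simulator

The simulator emulates the study conditions: two conditions × two fluids
(pooled libraries, no biological replicates, as in the original design —
per-library replicates are a config option), clean-read length mode inside
20–24 nt, 3' adapter read-through, 10 % junk split between adapter dimers
and 10–17 nt fragments (exercising both cleaning filters), planted
conserved miRNAs with AO/BO fold-changes spanning 0.09–16.5, planted novel
hairpins, and weekly Cq profiles.

**Counts.** Each species gets a Gamma multiplier with unit mean and
variance `dispersion` (default 0.1, a conventional bulk value — the pooled
design exposes no replicate variance to estimate it from); library counts
are then multinomial with probabilities ∝ base abundance × fold-change ×
multiplier. Marginally each count is negative-binomial-like with variance
`μ + 0.1 μ²`, while totals are exactly depth × (1 − junk). Because AO
reweighting renormalises the composition, the *effective* expected RPM
ratio differs slightly from the nominal fold-change; the truth table
records both, and accuracy is always judged against the effective value.
One consequence worth stating plainly: with dispersion 0.1 the per-seed
log2FC estimate carries an irreducible sd of ≈ 0.65 *regardless of depth*,
so accuracy claims are made about across-seed mean estimates, not single
libraries.

**Genome.** Default 100 kb, planted loci separated by 200 nt spacers.
Novel-hairpin stems are G/C-only with A-only loops and bulges, and each
novel locus is padded by 120 adenines on both sides. This composition is
deliberate: adenines cannot pair without uracil, and in a G/C stem every
base is paired in the designed structure, so the designed hairpin is the
strict optimum of the max-pairing folder within the tag ± 100 nt extraction
window — planted compliant hairpins are recoverable *by construction*, and
`make_reference()` verifies every planted hairpin through the actual
`fold_rna()` + `evaluate_criteria()` engines at build time (with bounded
retries, regenerating on the rare tie or sequence collision). Decoys each
violate exactly one recorded criterion, drawn from {5, 2, 4, 11, 1}; a
decoy violating only the energy criterion is impossible under the built-in
score (16 stem pairs already imply energy ≤ −16), and single-violation
constructions for the mature-region criteria are over-constrained at
precursor scale, so those boundaries are covered by the hand-built
structure tests instead. Conserved-miRNA regions and remaining filler are
ordinary random ACGT.

**Cq tables.** Expression doubling is exactly one Cq cycle; noise is
additive Gaussian (default sd 0.2 cycles). The `"panel"` shape is flat to
week 12, steps down `qpcr_step` = 2 cycles at week 13, and then drifts a
further 0.15 cycles/week — levels "keep or show further increment" after
onset. The drift default is not cosmetic: with an exactly flat post-onset
truth, the `sustained` test falsely rejects a true panel member ≈ 2.5 % per
late week (a significant wrong-sign fluctuation), which compounds across
seven members into a materially imperfect panel recovery; a mild true
increment makes the wrong-sign event vanishingly rare. `"transient"` steps
at 13–14 and returns to baseline by week 15 (the rise-then-drop shape that
the panel rule must reject); `"flat"` never steps; U6 is constant at Cq 15
up to noise. The default nine-candidate fixture has seven `"panel"` and two
`"transient"` members.

**What the simulator does not emulate:** sequencing errors and quality
decay, ligation/hexamer bias, isomiRs, fluid-specific exosome biology,
cross-mapping families, or genome-scale repeat structure. Passing the
recovery suites therefore demonstrates that the *pipeline logic* is
correct under its stated model — not that real libraries are free of the
biases above.

## Numerical and reproducibility notes

* All simulator entry points derive their RNG stream from `config$seed`
  (with small fixed offsets per stage), so identical configs give
  byte-identical outputs; the tests assert this.
* Genomic loci are 0-based half-open externally; R-internal mature offsets
  are 1-based and documented as such.
* ANOVA degenerate cases: both variances ≈ 0 ⇒ p = 1; zero within-group
  variance with distinct means ⇒ p = 0.
* Problem sizes in the shipped tests and acceptance script — 20 simulation
  seeds at 10⁶ reads/library for the DE recovery study, desk-scale
  (2 × 10⁴ reads) for read-level runs, 200 random sequences for the folding
  oracle, 300 random 2×2 tables for the exact-test oracle, 100 seeds for
  the qPCR panel study — were chosen as the smallest sizes at which the
  binomial uncertainty of the checked rates is clearly below the asserted
  margins.

## Known limitations

The folder's weighted pair score is a calibrated stand-in for free energy;
criterion 3 is only as thermodynamic as the energies you feed it. Exact
(mismatch-free) matching everywhere means isomiRs and SNP-bearing tags fall
into the unannotated pool. Fisher's exact test on pooled libraries treats
reads as independent draws and so understates biological variance — the
screen is a candidate generator, and the qPCR stage with replicates is the
arbiter, exactly as in the original workflow.
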