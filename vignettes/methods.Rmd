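---
title: "Methods: diet metabarcoding, alignment stringency, and resource selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet metabarcoding, alignment stringency, and resource selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices made where the design was genuinely open, and the known
limitations.

## Read processing

Demultiplexed read pairs pass through three operations before
quantification.

**Exogenous trimming** removes primers and adapters by k-mer matching:
any read window equal to a length-`k = 15` subsequence of an exogenous
sequence (either strand) is removed together with everything outward of
it (toward the nearer read end); at read ends, shorter exact matches down
to `mink = 11` are honored, because a primer can hang partially off a
read. A complete exogenous sequence at a read end is additionally matched
tolerating up to `hdist = 2` substitutions. The tolerance exists because a
sequencing error inside a primer would otherwise leave the primer behind,
and the downstream aligner would soft-clip it — a 20-base clip fails the
end-skip rule, so an untrimmed primer silently becomes a rejected read.
With a 20-mer primer, a Hamming-2 match to a random sequence has
probability around 1.6e-9, so the tolerance is effectively free.

**Quality trimming** removes the maximal 3' suffix of bases below Phred
`q`; internal low-quality bases are never touched. The first merge attempt
trims at `q1 = 10`; pairs that fail to merge are re-trimmed at `q2 = 15`
and merged once more (`merge_pass` records which attempt succeeded).
Whether quality trimming runs once or per attempt was an open choice; it
runs once before each attempt at that attempt's threshold, which keeps the
first attempt maximally informative and the retry strictly stricter.

**Overlap merging** reverse-complements the second mate and scans overlap
lengths from longest to shortest, accepting the longest overlap with
mismatch rate at most `max_mismatch_rate = 0.1` (at least
`min_overlap = 12` bases). Disagreements resolve to the higher-quality
base (first mate on ties); merged quality is the columnwise maximum,
which is simple and monotone. When the innie scan fails, the scan is
repeated with the mates' roles swapped and only the overlap consensus is
kept: this is the read-through ("outie") geometry that arises whenever
the amplicon is shorter than the read plus a sub-`mink` primer remnant,
and without it those amplicon lengths would be systematically lost.
Merged reads of 200–450 bp inclusive are retained; the bounds are
inclusive because the retention window was stated as a range without
open/closed qualification.

On error-free synthetic reads with exact primers the full stage returns
the original amplicon sequences exactly; the tests assert this.

## Alignment and the stringency filter

Merged reads are aligned locally to the reference with an affine-gap
Smith–Waterman (Rcpp), scores match = 2, mismatch = −6, gap open = −5,
gap extend = −3 — the conventions of a sensitive local short-read aligner
— and a score floor of `80 + 8·ln(read length)` below which a read is
unmapped. The traceback emits a SAM CIGAR (soft clips at unaligned query
ends) and an MD string, with deterministic tie-breaking (diagonal over
insertion over deletion), so repeated runs are byte-identical. A plain-R
dynamic-programming oracle validates the compiled aligner on random
query/reference pairs in the tests, and the traceback is checked by
reconstructing the score from the CIGAR/MD summary.

The filter itself parses CIGAR + MD into: matched columns *m*, mismatches
*x*, gap positions *g* (sum of I and D lengths — per-position counting,
so a length-2 deletion is two gap positions), and the two end skips. The
rule, with defaults `min_identity = 0.98`, `max_gap_positions = 3`,
`max_end_skip = 5`:

1. reject if either end skip exceeds 5;
2. identity `m / (m + x + g)` must be at least 0.98 — the denominator
   includes gap columns, the stricter and more common reading of
   "identical over aligned length";
3. effective gaps `g + [left skip > 0] + [right skip > 0]` must not
   exceed 3 — each nonzero end skip counts as one gap of size 1
   regardless of its length (1–5).

Consequently an alignment with allowable skips at both ends can afford at
most one more internal gap position. The comparison is inclusive (`>=`
98%), reading "at least" literally. `accept()` is monotone — worsening
identity, gaps or skips can never turn a rejection into an acceptance —
and the tests verify this along every axis.

**Best-hit policy.** When several references pass the filter, the read
goes to the highest-scoring one, ties broken by lexicographically
smallest accession. The multi-hit policy is not derivable from the
analysis being implemented; best-score-then-lexicographic was chosen for
determinism and is recorded per read in the decision table. For speed,
reads are dereplicated and shortlisted against the top-5 candidate
references by shared 12-mer counts (exact substring hits skip the DP
entirely); with references whose between-genus identity is far below the
98% acceptance bar, the shortlist is not a practical restriction.

External SAM (for example from a real aligner run) is filtered
identically: records must carry MD tags, and records lacking them are
recomputed against the reference when it is supplied, otherwise reading
fails naming the record.

## Quantification

The chain order is fixed and asserted by tests: species-rank tabulation →
genus aggregation → bait removal → prevalence threshold → flora filter →
RRA/FOO. Two choices deserve explanation:

* The 1% screen retains a genus iff its within-sample proportion reaches
  `min_frac = 0.01` in **at least one** sample. The alternative reading
  (drop when below 1% in *some* sample) would discard almost everything;
  the retain-if-ever-≥1% reading matches how retained-taxon counts are
  described downstream. Proportions are computed on post-bait-removal row
  totals, because bait is removed first, and at genus rank, because the
  screen follows aggregation. CPM versus raw proportions is immaterial
  here (the screen is scale-free), so proportions are used.
* Congeners expected to differ ecologically can be kept separate via
  `split_species`; the genus column of a split genus holds only its
  non-split congeners.

## Community statistics

All statistics operate on RRA expressed on the 0–100 scale.

* **Zero-adjusted Bray–Curtis**: a dummy taxon of constant value
  `dummy_value = 1` (same scale as the matrix, i.e. 1% RRA) is appended
  to every sample before computing
  `100 · Σ|y_ij − y_ik| / Σ(y_ij + y_ik)`. The dummy magnitude is not
  fixed by the method's name; 1 on the percent scale is the conventional
  choice and is configurable.
* **ANOSIM**: midranks, `R = (r̄_B − r̄_W)/(M/2)` with `M = n(n−1)/2`,
  so perfectly separated groups give R = 1 and fully tied data give 0.
  Significance by seeded label permutations with the `(b+1)/(m+1)`
  estimator — p can never be exactly 0, matching how permutation
  software reports "p ≤ 1/(m+1)"-style bounds. Default 9999 permutations.
* **SIMPER** runs on the raw (non-dummy) matrix so that per-taxon Av.Diss
  sums exactly to the total average between-group dissimilarity; the
  zero-adjustment applies only to resemblance matrices used by
  ANOSIM/nMDS/RELATE. Diss.SD is reported as the ratio Av.Diss / SD of
  per-pair contributions (the PRIMER convention behind that column name).
* **Chao2** uses the classic estimator with the bias-corrected form when
  no duplicates exist. "Randomized" confidence intervals are percentile
  bootstrap over samples (1000 draws, seeded); an analytic log-normal CI
  is available behind a flag since the randomization scheme is not
  otherwise pinned down.
* **nMDS** is iterative majorization (Guttman transform) alternated with
  monotone regression on the dissimilarity order (ties averaged within
  blocks), Kruskal stress-1, 50 seeded random restarts, stopping at
  stress change < 1e-6 or stress < 0.01. Stress is non-increasing within
  a restart up to numerical jitter; an all-equal dissimilarity matrix is
  flagged degenerate and returned with stress 0 rather than iterated.
* **Paired t-test**: all-zero differences return t = 0, p = 1 (identical
  inputs are evidence of no difference, not an error); nonzero constant
  differences are a hard error since the statistic is undefined.

## Seed availability and selection

Availability per (grid, session, taxon) is the cover-weighted sum over
plots of the flowering + set seed + seeded + newly-dead state fractions.
"Newly dead" means dead this session but not dead in the previous session
of the same year — seed from a plant that senesced between sessions is
still on offer; a taxon dead in consecutive sessions contributes only in
the first. The first session of a year has no previous session and
contributes no newly-dead fraction. Cover-weighting (state fractions
multiplied by the taxon's percent cover before summing to the grid) is a
design choice: availability should scale with how much of the grid the
taxon occupies, not only with its phenological state.

Diet is standardized by summing read counts over the fecal samples of a
grid-session and renormalizing over the taxon universe restricted to taxa
ever observed in survey plots; availability is renormalized over the same
universe. Fall sessions are removed (surveys cover spring and summer),
and the matching unit is the grid-session. Selection is reported as
diet − availability — positive means overrepresented in diet — with a
flag to flip the sign. Fold flags: overrepresented iff
diet > 10 × availability, underrepresented symmetric, and diet with zero
availability flagged "overrepresented (unavailable)" instead of an
infinite fold.

## The synthetic-data generator

The generator emulates: a plant ITS2-like reference (independent random
genus ancestors, congeners at 2% divergence, inserts 250–420 bp so the
200–450 retention window is only exercised by explicit out-of-range
spike-ins in tests); 2×300 paired reads with fixed synthetic 20-mer
primers, per-base substitution (default 0.002) and optional indel errors,
and Phred qualities decaying linearly (mean 38 down by 18 across the
read, Gaussian jitter sd 3, floored at 2 — enough to exercise Q10/Q15
trimming); multinomial read counts per genus; bait contamination as a
dedicated genus labeled *Panicum* mixed at a configurable level into a
configurable fraction of samples (defaults 10% of reads in 25% of
samples); mock communities in known ratios; and phenology surveys whose
cover is proportional to availability with lognormal plot noise (sd
0.15) and constant seed-state fractions.

The diet–availability link is constructed so the planted selection
coefficient is the *exact* per-taxon log fold: given a base composition
`b` and weights `w = exp(coef)`, availability `a ∝ b·w^(−t)` and diet
`d ∝ b·w^(1−t)` share a normalizer when `t` solves
`Σ b·w^(−t)(w−1) = 0` (monotone in `t`, root found by uniroot), giving
`d_i/a_i = w_i` exactly. Because both vectors sum to one, such a pair
only exists for mixed-sign coefficients; one-sided coefficient sets fall
back to a plain exponential tilt, which preserves signs but shrinks
folds.

What the generator does **not** emulate: ITS2 secondary structure or
phylogenetic realism, chimeras, PCR amplification bias, quality-dependent
error rates, or length variation within a genus. Passing tests therefore
demonstrate that the pipeline's logic is correct under controlled
conditions — multinomial sampling, independent substitution errors, known
truth — not that real fecal samples are free of the biases those
processes introduce.

## Problem sizes and determinism

The test suite runs the full read pipeline at 50,000 pairs for the mock
community, 100 seeded replicates for selection recovery, 500 null
datasets (199 permutations each) for ANOSIM calibration, and exhaustive
permutation enumeration at n ≤ 6 — sizes chosen so every stochastic claim
has comfortable Monte-Carlo resolution while the suite completes in a few
minutes on one core. Every source of randomness flows through an explicit
seed; generators save and restore the caller's RNG state, and the
orchestrated pipeline records parameters, seed, and per-artifact
checksums in its manifest, refusing to resume over a checksum mismatch.

## Limitations

* The read processor approximates the behavior of the usual external
  trimming/merging tools functionally (same decisions on the cases that
  matter), not bit-for-bit; acceptance is defined on synthetic data.
* The built-in aligner is exact but O(nm) per pair; it exists so the
  filter is testable without external binaries. For large real datasets,
  run an external local aligner and filter its SAM here.
* Availability estimation inherits the survey design: taxa absent from
  survey plots are invisible to selection analysis even if eaten, and the
  newly-dead rule depends on session spacing.
* The ANOSIM/RELATE implementations are one-way; nested or crossed
  designs are out of scope.
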