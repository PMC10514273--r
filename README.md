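# ppmdiet

Diet analysis by fecal metabarcoding for a granivorous heteromyid rodent
(the Pacific pocket mouse), implemented as a tested, fully synthetic-data-
verifiable R package plus a numbered analysis workflow. The pipeline takes
paired-end ITS2 plant amplicon reads through trimming, overlap merging with
a stricter-retrim retry, local alignment to a plant reference database, a
CIGAR/MD-derived alignment stringency filter, genus-level relative read
abundance (RRA) quantification with bait removal and prevalence/flora
filtering, PRIMER-style community statistics, and a diet-versus-seed-
availability resource-selection analysis driven by plant phenology surveys.

## The problem

Granivorous pocket mice eat seeds whose availability shifts week to week
with plant phenology. Fecal metabarcoding reads out *what* was eaten
(proportions of plant taxa among ITS2 amplicons in scat), and standardized
cover/phenology surveys read out *what was on offer* (the fraction of each
taxon flowering, setting seed, seeded, or newly dead, weighted by percent
cover). Comparing the two, per trapping grid and session, yields resource
selection: which taxa are over- or underrepresented in diet relative to
their above-ground seed availability.

## The methods at the core

* **Alignment stringency filter.** For each local alignment the CIGAR and
  MD fields give matched columns *m*, mismatches *x*, gap positions *g*
  (sum of I/D lengths) and end soft-clips. An alignment is kept iff
  identity `m / (m + x + g) >= 0.98`, no end skip exceeds 5 positions, and
  effective gaps `g + [left skip > 0] + [right skip > 0] <= 3`. The same
  rule applies to SAM from any external local aligner (`read_sam()` +
  `filter_sam_records()`).
* **Quantification chain** (fixed order): tabulate species counts ->
  aggregate to genus (with an explicit split list for congeners analyzed
  separately, e.g. *Croton californicus* vs *C. setiger*) -> remove bait
  (*Panicum*, the millet trap bait) -> drop genera never reaching 1% of
  reads in any single sample -> keep only taxa with local botanical
  records -> RRA and FOO.
* **Community statistics**, written from scratch and cross-checked against
  vegan in the tests: zero-adjusted Bray–Curtis (dissimilarity
  `100 * sum|y_ij - y_ik| / sum(y_ij + y_ik)` with a dummy taxon), one-way
  ANOSIM (`R = (r̄_B - r̄_W) / (M/2)`, 9999 permutations), SIMPER, Chao2
  (`S_est = S_obs + ((m-1)/m) Q1² / (2 Q2)`) with bootstrap CIs,
  species-accumulation curves, Shannon `H' = -Σ p ln p` and Pielou
  `J' = H'/ln S`, RELATE (Spearman rho between resemblance matrices), nMDS
  by majorization with isotonic regression, and paired t-tests.
* **Selection analysis.** Availability per (grid, session, taxon) is the
  cover-weighted sum of flowering + set seed + seeded + newly-dead state
  fractions; diet is summed per grid-session and both are renormalized
  over the surveyed taxon universe (spring/summer only). Selection is
  reported as diet − availability, with >10× fold-representation flags.
* **Synthetic data with known truth.** A reference generator (congeners by
  mutation of a genus ancestor), a MiSeq-like 2×300 read simulator with
  primers, quality decay and substitution/indel errors, mock communities
  in known ratios, bait contamination, and phenology surveys constructed
  so that diet equals availability tilted by planted per-genus selection
  coefficients (`diet_i / avail_i = exp(coef_i)` exactly).

## Worked example

A 23-taxon mock community in staggered known ratios (1.8%–7.1%), 20,000
read pairs at substitution rate 0.002, through the full pipeline
(`analysis/05_mock_validation.R`):

```
mock recovery over 23 taxa at 20k pairs:
  Pearson r = 0.9982, max |obs - expected| = 0.0031
  false detections above 1%: 0; missed taxa: 0
```

Pearson r compares observed RRA with the known input proportions; a false
detection would be any taxon absent from the mock but quantified above the
1% threshold. The synthetic field study (`analysis/01`–`04`) ends with,
e.g.:

```
matched grid-sessions (spring/summer): 12 over 7 taxa
RELATE diet vs availability: rho = 0.961, p = 0.0010
```

i.e. with neutral planted selection, diet composition tracks availability
closely — the rank correlation between the two resemblance structures is
strong and significant. `analysis/06_selection_recovery.R` repeats the
experiment with planted coefficients {−log 10, 0, +log 2, +log 10} and
recovers every sign in 20/20 replicates, flagging the tenfold genera as
over-/underrepresented.

## Layout

```
R/                 package code (one file per pipeline stage)
src/               Rcpp: affine-gap local aligner with CIGAR/MD traceback,
                   overlap merger, trimming/k-mer scans
analysis/01..06    numbered workflow drivers (write under results/)
inst/extdata/      published summary tables used as printed inputs
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette (model, parameters, design choices)
```
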