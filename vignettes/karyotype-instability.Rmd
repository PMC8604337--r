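---
title: "Quantifying chromosomal instability from single cells, and a spectral-count interactome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosomal instability from single cells, and a spectral-count interactome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CINspect)
```

CINspect bundles the quantitative machinery used to characterize
chromosomal instability (CIN) in aneuploid tumors — pediatric high-grade
glioma with the H3.3K27M oncohistone being the motivating system — together
with a label-free interactome classifier and a cohort-level burden
comparison. This vignette explains the models, the defaults, and the design
decisions; it is the package's methods documentation.

## The single-cell copy-number model

Shallow single-cell whole-genome sequencing gives, per cell, read counts
over a genome bin map (here ~1 Mb bins). The expected count in bin $b$ of
cell $i$ is

$$\mu_{ib} = c_{ib} \cdot r \cdot f(\mathrm{gc}_b) \cdot \frac{w_b}{\bar w},$$

where $c_{ib}$ is the integer copy number, $r$ the library's reads per bin
per copy, $f$ a smooth multiplicative GC-bias factor, and $w_b$ the bin
width. The caller inverts this model in four steps:

1. **GC correction** (`gc_correct`). Bins are stratified into GC deciles;
   each cell's counts are rescaled by the ratio of the cell's global median
   to the stratum median. Strata under 10 bins (and bins with unknown GC)
   are left uncorrected; blacklisted bins are dropped. A median-ratio
   correction is deliberately crude-but-robust: it makes no assumption
   about the functional form of the bias beyond smoothness in GC.
2. **Dual segmentation** (`segment_binary`, `segment_edivisive`). Two
   independent change-point detectors are run per cell and chromosome: a
   CBS-style detector maximizing the two-sample *t* statistic, and an
   e-divisive detector maximizing the energy distance
   $\frac{mn}{m+n}\bigl(2\,\mathbb{E}|X-Y| - \mathbb{E}|X-X'| -
   \mathbb{E}|Y-Y'|\bigr)$. Both scan *two-boundary* candidate segments
   (an inner run of bins against its complement, single splits being the
   edge cases). This matters: a plain binary split has essentially no power
   against a short interior event — a 5-bin homozygous deletion inside a
   134-bin chromosome yields a best-split *t* around 1.4 when the
   segment-versus-complement *t* exceeds 9 — and interior segmental events
   are precisely what the structural score counts. Significance is assessed
   by permutation (1,000 shuffles of the segment under test, seeded from
   the run configuration, with sequential early stopping once
   non-significance is certain). Change points are never placed at
   chromosome boundaries.
3. **Integerization** (`assign_copy_numbers`). A reads-per-copy scale $s$
   is grid-searched over every segment mean divided by every copy number up
   to `max_copy`, minimizing the width-weighted squared read-space error
   $\sum_s w_s (m_s - s\,c_s)^2$ with $c_s$ the nearest non-negative
   integer. Harmonic scales ($r, r/2, r/3, \dots$ of a good $r$) fit
   equally well up to sampling noise, so all scales within the noise floor
   of the best fit (estimated from within-segment variance) are treated as
   tied, and ties resolve toward the scale whose genome-wide median copy is
   closest to 2 — the euploid-reference assumption — then toward the larger
   scale (lower ploidy). Read-space error is essential: a copy-space error
   $\sum_s w_s (m_s/s - c_s)^2$ shrinks as $1/s^2$ and would always prefer
   the largest scale. The euploid tie-break means a genuinely
   near-tetraploid cell with no odd-copy segments will be reported at half
   its true ploidy; this mirrors the euploid-reference analysis choice and
   is the documented limit of scale identification from coverage alone.
4. **Curation** (`call_and_curate`). A cell is kept only if (a) the two
   detectors' integer profiles agree on at least 90% of bins (bin-wise
   concordance; the threshold is `concordance_threshold`), and (b) its mean
   reads per bin per copy — raw reads over retained bins divided by the sum
   of called copies, so the denominator scales with ploidy — is at least 5.
   Both boundaries are exact: a cell at precisely 5.0 or 0.90 passes
   ("less than" is discarded). The e-divisive profile is the reported call,
   recorded as such in the QC table so the choice is auditable.

**Significance level.** `caller_params(alpha = 0.003)` balances two failure
modes of the structural score, which counts every copy-number transition.
With two detectors scanning ~22 chromosomes per cell, a looser level
(0.01) admits enough spurious change points to inflate the structural score
by tens of percent; a tighter one (0.001) misses real arm-scale events near
the power floor of shallow coverage — gains on already-amplified
chromosomes are the weakest signals, since the same +1 copy step rides on a
larger variance. Concordance curation does not remove such errors: both
kinds perturb well under 10% of bins.

## The three instability scores

For a curated population with profiles $c_{ib}$, widths $w_b$, and
euploid expectation $e$ (default 2; X/Y bins are excluded by default,
matching the autosomal framing of the cohort analysis):

* **Aneuploidy** (per cell, then averaged over cells):
  $\sum_b w_b\,|c_{ib} - e| \,/\, \sum_b w_b$. A static measure: how far
  from euploid the karyotype sits.
* **Heterogeneity** (per bin, then width-averaged): the proportion of the
  $n(n-1)/2$ unordered cell pairs that differ in copy number. This is the
  signature of *ongoing* instability — a clonal but aneuploid tumor scores
  zero.
* **Structural** (per cell, then averaged): copy-number transitions between
  consecutive bins of the same chromosome, divided by the genome length in
  Mb. The denominator is the union span of the scored (non-blacklisted)
  bins, recorded in the output as `genome_mb`; whole-chromosome events
  contribute no transitions.

Identities worth knowing: unordered versus ordered pair counting cancels in
the heterogeneity proportion; doubling every bin width leaves aneuploidy
and heterogeneity unchanged and halves the structural score (its
denominator is physical length). Overlapping (sliding-window) bin maps are
accepted, but transitions are then counted between overlapping neighbours,
inflating the structural score — the generator therefore emits
non-overlapping bins, and sliding maps should only be scored with that
caveat in mind.

```{r scores-example}
bm <- bin_map(c("chr1", "chr2"), c(0, 0), c(10e6, 90e6))
profiles <- matrix(2L, 2, 40)
profiles[1, 1:10] <- 3L   # 10 of 40 cells gain the 10%-of-genome chromosome
score_sample(cell_population(bm, profiles))
```

The closed forms for this construction are heterogeneity
$0.10 \times 600/1560 \approx 0.0385$ and aneuploidy $0.025$; the package
reproduces them exactly, and the test suite checks all three scores against
a brute-force pair-enumeration oracle on a thousand random populations.

## What the synthetic generator emulates — and what it does not

`simulate_population` produces: a founder karyotype (base ploidy, a number
of clonal whole-chromosome gains/losses, optionally a whole-genome
duplication applied *after* the clonal events, so later per-cell losses
read as "losses relative to a tetraploid founder"); optional discrete
subclones defined by explicit event lists; and per-cell Poisson-distributed
whole-chromosome missegregations and segmental events. Copy numbers are
clamped at zero, with losses that would go negative resampled. Segmental
events draw a uniform breakpoint pair within one chromosome, subject to a
minimum size (`min_segment_length`, default 15 Mb): tumor segmental
aneuploidies are typically chromosome-arm scale, and events much below
~10 Mb are statistically unresolvable at megabase bins and the read depths
this assay produces — by any detector — so simulating them would only
inject unrecoverable ground truth.

`simulate_read_counts` draws negative-binomial counts (variance
$\mu + d\mu^2$; $d=0$ is Poisson) around the mean model above, with the
quadratic GC factor $f(g) = \max(0,\, 1 + a\,(g-0.45)^2)$ — the same shape
`gc_correct` must remove. The defaults (5 reads/bin/copy, the QC anchor)
describe the shallow end of real libraries. The generator does *not*
emulate read-level artifacts: mappability structure, replication-timing
coverage waves, duplicate reads, or breakpoints below bin resolution.
Passing tests therefore demonstrate correctness of the calling and scoring
machinery under the stated noise model, not robustness to every artifact of
real sequencing.

For end-to-end validation the suite simulates 50 cells over 22 human-sized
autosomes (~2,900 one-megabase bins) at 30 reads/bin/copy and dispersion
0.05, with 8 clonal founder events, 0.5 missegregations and 1.0 segmental
events per cell — a heavily aneuploid, actively unstable tumor, which also
gives each score enough signal (roughly a hundred true transitions) that a
10% relative comparison measures the caller rather than small-count noise.
Recovery there is ≥95% of bins at the true copy number with all three
scores within 10% of ground truth.

## The spectral-count interactome pipeline

The FLAG-IP design has three conditions — empty vector (EV), H3.3WT and
H3.3K27M — with (by default) four technical replicates each, quantified by
spectral counts, and histone H4 as the anchor tracking nucleosome pull-down
yield. The pipeline order is fixed: replicate QC → per-condition means →
EV background subtraction → anchor normalization → classification.

* **Replicate QC** keeps a bait replicate only when its anchor count is
  strictly above the mean EV anchor (the strict/non-strict choice is a
  switch, `strict_qc`).
* **Means** are taken over retained replicates with proteins absent from a
  replicate counted as zero observations.
* **Subtraction** clamps at zero (negative abundance is meaningless);
  proteins at zero in both baits are background-only and leave the
  analysis.
* **Normalization** multiplies each bait's corrected means by
  (WT anchor mean / that bait's anchor mean), i.e. the WT factor is 1.
  Because subtraction precedes normalization, a global rescaling of one
  condition cancels exactly only for proteins without EV background; the
  test suite pins the property in that regime.
* **Classification**: present with exactly one bait (normalized corrected
  mean strictly above `presence_floor`, default 0) → unique to it; present
  with both → common, not-enriched when the absolute difference is at most
  `enrichment_delta` (default 2 spectral counts, the boundary inclusive),
  otherwise enriched for the larger side. Both the threshold and the stage
  it applies to (normalized or unnormalized means) are configurable, since
  the convention is a descriptive cut rather than an estimand.

The generator (`simulate_spectral_counts`) draws Poisson counts with
class-structured means: sticky background proteins at `background_mean` in
every condition; bait-specific and shared interactors at `effect_mean` in
the conditions carrying their bait and *absent elsewhere, including EV* —
the mass-spectrometry reading of a true interactor, which is not pulled
down without its bait. Bait-specific means scale with the condition's
pull-down yield (its H4 level relative to WT), which is exactly the
distortion anchor normalization removes. Two consequences are worth
stating plainly. First, designed unique and shared classes are recovered
essentially perfectly at realistic effect sizes. Second, background
proteins at mean ~1 land above or below their EV estimate by what is close
to a coin flip after zero-clamped subtraction, so roughly half of them are
assigned some interactor label — this is a property of the
subtract-and-threshold convention itself, not of this implementation, and
it is why the recovery metric is defined over the designed interactor
classes (with "shared" recovered by any common label: under symmetric
Poisson noise at effect mean 10, the ±2-count enriched/not-enriched cut
has no stable ground truth, as the difference of two such means lies
within ±2 only ~63% of the time). The background false-assignment rate is
reported, un-thresholded, by the acceptance script.

## Cohort burden comparison

`sum_autosomal_burden` sums per-tumor CNA events over autosomes (chr1–22;
X, Y and the mitochondrial contig are excluded; anything else is an error
naming the label) or passes pre-summed totals through. `mann_whitney`
computes U from joint mid-ranks; the two-sided p-value is exact (full
enumeration of the permutation null) when the pooled sample is ≤ 12 without
ties — a cutoff that keeps the oracle cheap while exercising both code
paths; real cohort groups of tens to hundreds always take the
tie-corrected, continuity-corrected normal approximation. Two-sided p is
min(1, 2 × one-sided), stated explicitly because exact two-sided
conventions vary. The burden generator is negative-binomial
(`dispersion` default 0.3) because real per-tumor CNA totals are
overdispersed; at equal group means the test's empirical type-I error at
α = 0.05 is calibrated within binomial error over a thousand simulated
cohorts. Pairwise subtype comparisons report raw p-values by default, with
Bonferroni adjustment available (`compare_burden_groups(bonferroni =
TRUE)`); raw is the default because the motivating analyses report
per-pair tests.

## Numerical and interface conventions

Coordinates are 0-based half-open (BED) everywhere internally. All
generators are pure functions of (config, seed) and restore the caller's
RNG state; permutation tests inside the caller derive per-cell seeds as
`seed + cell index`. Bin-map TSV matrices round-trip exactly, integer
profiles serialize without decimal points, and every CLI output carries a
JSON sidecar with the producing parameters, version and seed. The
command-line surface (`main()`, wrapped by `inst/cli/cinspect.R`) exposes
the simulators, the caller, the scorer, the interactome classifier and the
burden comparison as subcommands with the package defaults.

## Known limitations

* Scale identification assumes a near-diploid genome median; clonal
  whole-genome-duplicated populations without odd-copy segments are called
  at half ploidy (by design of the euploid reference).
* Concordance is bin-wise on integer calls, and the 90% rule is applied
  per cell; whether the original curation was per cell or per sample is
  not stated in the source material for this convention.
* The heterogeneity denominator skips pairs with missing copy states
  defensively, but curated profiles are always complete.
* The e-divisive permutation test shares its null with the t-detector's
  (segment-versus-complement maxima); the two are not independent tests of
  the same hypothesis, and concordance curation should be read as
  agreement between two algorithms, not as replication.
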