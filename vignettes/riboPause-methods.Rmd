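---
title: "Codon-resolution ribosome and disome profiling: models and methods"
author: "riboPause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolution ribosome and disome profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboPause)
```

# Scope

riboPause analyses ribosome-profiling (monosome) and disome-profiling
(collided-ribosome) footprint data at codon resolution.  Its five analysis
layers are: (i) the coordinate backbone — frame classification, A-site
offset assignment and metagene profiles; (ii) per-codon pause and
vulnerability scores and a read-based codon decoding-speed comparison;
(iii) P/A-site di-codon pause matrices; (iv) occupancy profiles aligned at
codons or codon pairs of interest, with detection of collision/queue
peaks; and (v) gene-level disome-enrichment interaction testing that
classifies transcripts as targets of ribosome-associated quality control
(RQC) or as RQC-refractory transcripts (RRTs).  A synthetic footprint
generator encodes the ribosome geometry and the stalling model, so every
layer can be exercised and validated without sequencing data.

The biological setting is translation elongation under perturbed codon
optimality — for example yeast lacking wobble-uridine (U34) tRNA
modifications, where decoding of cognate codons such as AAA and CAA slows
down, ribosomes stall preferentially at particular P/A-site codon *pairs*,
stalled ribosomes are rear-ended by elongating neighbours, and the
resulting collisions are surveilled by RQC.

# Coordinate conventions and footprint geometry

All coordinates are 0-based, half-open, in transcript space.  A CDS runs
from `cds_start` to `cds_end` (stop codon included; length divisible
by 3), and every transcript carries at least 21 nt of flanking sequence on
both sides so footprints spanning the start/stop codons stay on the
transcript (the "ORF extended by 21 bp" convention used when aligning
reads).

A monosome footprint's reading frame is 0/1/2 when its 5' end falls on the
first/second/third nucleotide of a codon.  The A site is assigned with a
fixed offset table — 28-nt frame-0 and 29-nt frame-0 reads use a 16-nt
offset, 29-nt frame-2 reads use 17 nt — as

    a_site_nt  = five_prime_pos + offset
    codon      = floor((a_site_nt - cds_start) / 3)

The floor makes the assignment well-defined even though the empirical
offsets do not point at a codon boundary.  Offsets are configuration, not
re-inferred from data: the empirical initiation peak (around -12 nt at the
start codon, visible via `metageneProfile(..., anchor = "start")`) is a
diagnostic only and never overrides the table.  Disome footprints
(selected at 56-64 nt) are assigned 45 nt downstream of their 5' end — the
A site of the *lead*, stalled ribosome of the collided pair.

Collided ribosomes are stacked with a 30-nt 5'-to-5' spacing (one 28-nt
footprint plus a 2-nt gap), i.e. exactly 10 codons.  Terminating ribosomes
accommodate 4 nt in their A site during stop-codon recognition; in
stop-anchored metagene coordinates (last stop nucleotide at -1) their
footprint 5' ends peak at -18, and ribosomes queued directly behind them
at -48 = -(28 + 2 + 18).

Two geometric subtleties are worth recording.  First, with the 16-nt
offset and floor assignment, a frame-0 28-nt read reporting A-site codon k
has its 5' end at `3k - 15` relative to `cds_start`; the naive arithmetic
"A-site start minus 16" would land one nucleotide earlier, in frame 2, and
would be discarded by the very selection rule the offsets define.  The
simulator therefore emits each footprint at the unique position *in its
configured frame* that the assignment rule maps back to the emitting
codon, which keeps selection, assignment and geometry mutually consistent.
Second, under this frame-0 convention the -18 terminating peak coincides
with the position a frame-0 elongating read would occupy with its A site
on the stop codon, so the +1-nt shift that the 4-nt A-site accommodation
produces in real libraries is not separately visible in simulated
output — the simulator reproduces the *positions* (-18/-48), which is what
the downstream analysis consumes.

# The synthetic footprint generator

`simulateTranscriptome()` draws CDSs (ATG + internal codons from a
configurable codon-usage vector + one stop codon) with 21-nt random
flanks.  `simulateFootprints()` then emits, per genotype and replicate:

* **Elongation footprints**, multinomially over (gene, codon) cells with
  probability proportional to transcript abundance x per-codon dwell time
  x P/A-codon-pair dwell multiplier.  Lengths follow the configured 28/29
  distribution (the default 0.7/0.3 mirrors the predominance of 28-nt
  reads in optimised libraries); 29-nt reads split evenly between frames
  0 and 2 so both offset-table keys are exercised.
* **Stall stacks** at explicit sites: `depth` is the *total* number of
  stacked ribosomes (lead included); queued members sit at multiples of
  30 nt behind the lead, and each adjacent collided pair emits a disome
  footprint 45 nt upstream of its lead ribosome's A site, with length
  uniform over 56-64 nt.  Queue depth is a fixed integer per site rather
  than a distribution: the geometry checks downstream need exact stack
  shapes.
* **Termination events**: terminating footprints at stop-anchored -18 and,
  with configurable probability, a queued partner at -48.  These are
  geometry inputs, not the output of a digestion model — the analysis
  consumes the peak positions.
* Optionally, **initiation footprints** with a configurable 5'-end offset
  (default 12 nt upstream of the AUG).

Every footprint row carries provenance columns (`origin`, `source_codon`)
so that A-site assignment can be validated footprint-by-footprint against
the emitting codon; `writeFootprints()` drops them when exporting the
canonical table.  The random-number consumption order is fixed (genotypes
in configuration order, replicates within genotype; within a library:
elongation multinomial, length/frame split, termination counts,
termination-queue binomial, disome lengths), so a seed fully determines
the output.

What the generator deliberately does *not* emulate: sequencing errors,
rRNA/ncRNA contamination, alignment artefacts, nuclease digestion
heterogeneity beyond the two read lengths, and any 5'-biased degradation
signal.  Passing tests therefore demonstrate the correctness of the
analysis contracts, not robustness to those nuisances in real libraries.

`simulateGeneCounts()` is the separate gene-level generator for the
classification layer: negative-binomial counts over a genotype x
fraction x replicate design in which a planted interaction effect shifts a
gene's disome/monosome ratio per genotype (RQC target: up in the
modification mutant, back down when the collision sensor is removed; RRT:
mirrored).  Defaults — mean 200, dispersion 0.05, disome/monosome ratio
0.3, 3 replicates — are typical of a well-sequenced yeast profiling
experiment.

# Pause and vulnerability scores

For gene j with CDS length l codons, 15 codons are excluded at both ends
and the pause score of codon i is its A-site count normalised to the
gene's mean count over the included positions:

    pause(i, j) = C_ij / ( sum_{i in [15, l-16]} C_ij / (l - 30) )

so the per-gene mean over included positions is exactly 1.  Genes with read coverage below
0.1 reads per codon — total A-site reads over the CDS divided by l — are
excluded.

The vulnerability score of a codon instance is the ratio of its pause
score in the mutant to that in the wild type, computed on counts + 1 (the
pseudocount exists solely to avoid division by zero and is *not* applied
in plain pause scores).  With replicate libraries the score is the median
over all mutant x wild-type replicate-pair ratios (the pairing is not
canonical; all-pairs is symmetric and is the package default), and a
two-sample Student's t-test on the per-replicate pause scores provides the
per-instance p-value.  The coverage filter must pass in every replicate of
both genotypes so all replicates score the same instance set.

`decileEnrichment()` ranks instances by score, cuts them into 10
equal-size bins (remainder to the lower bins) and reports each codon's
within-bin frequency relative to its overall frequency.
`positionalResidueEnrichment()` compares amino-acid composition at the 30
codon positions upstream of the top 1000 instances against a background
instance set (a wild-type-vs-wild-type contrast in practice), with a
two-sided binomial test per (position, residue) cell and Bonferroni
correction over all 600 cells at corrected P < 0.01.  Background
frequencies of exactly 0 or 1 are nudged by half a count to keep the
binomial test defined; instances with fewer than 30 upstream codons are
skipped and counted.

# Read-based decoding speed

Independently of position-level scores, `readBasedSpeed()` compares
transcriptome-pooled codon frequencies: per library, each sense codon's
frequency in the A site is normalised to its mean frequency at the +1, +2
and +3 downstream sites (this cancels codon-usage and library-composition
biases), log2 is taken and the 61 values are median-centred per library.
Pooling across the transcriptome (rather than per-gene normalisation
first) is one admissible reading of the procedure and is the documented
choice here.  The mutant/wild-type contrast is the difference of
replicate-mean centred log rates, re-centred so the reported median is
exactly 0; significance is a one-sided Welch's t-test (alternative:
slower in the mutant) at P < 0.05 with a centred log2 fold change > 0.1.
No multiple-testing correction is applied across the 61 codons — raw
thresholds are the convention for this comparison — while the motif
analysis above, where the cell count is 600, uses Bonferroni.

# Di-codon matrices

`dicodonPause()` attributes the per-gene-normalised pause score of each included
position i (with i >= 16, so the P-site codon at i - 1 is also inside the
trim) to the cell (P = codon i-1, A = codon i) of a 61 x 61 sense-codon
grid; the cell value is the instance-weighted mean over all contributing
positions, averaged across replicates.  Instance weighting (rather than
averaging per-ORF means) is the documented resolution of an ambiguity in
the verbal description; cells with fewer than 5 contributing instances are
flagged low-support.  `dicodonRatio()` forms the cell-wise mutant/wild-type
ratio, preserving the raw value and adding a display copy clamped at 2
(ratios >= 2 are shown as 2, a visualisation convention only).
`slicePairs()` extracts the raw NNN-A column for a fixed A-site codon.

# Site-aligned profiles and queue detection

`alignAtSites()` aligns all instances of a codon or codon pair (position 0
= the A-site codon of the first stalled ribosome) and averages pause
scores or occupancy counts per relative position over instances, not
genes; instances whose window (-35..+10 codons by default) leaves the CDS
are skipped.  The replicate band is min/max by default (the shaded
"experimental variation" convention is not defined numerically anywhere;
min/max is the conservative choice) with an s.d. option.
`disomeSiteProfile()` does the same for disome footprints after 45-nt lead
A-site assignment.

`detectQueuePeaks()` scans negative multiples of the 10-codon collided
spacing (+-1 codon tolerance, absorbing offset rounding) for local maxima
exceeding `minFold` (default 2) times the profile median.  Queue peaks are
conventionally read off profiles by eye; as a programmatic criterion,
2-fold over median is strict enough to reject flat profiles yet
permissive for real queue peaks.  On a depth-d simulated stack the detector returns exactly the
d - 2 queueing positions -10, -20, ....

# Disome-enrichment interaction test and RQC classification

Gene-level monosome and disome counts (footprints overlapping the CDS) are
tested per gene with a negative-binomial GLM likelihood-ratio test of

    full:    counts ~ fraction + genotype + fraction:genotype
    reduced: counts ~ fraction + genotype

using median-of-ratios size factors as offsets.  Monosome counts sit
inside the model as the fraction main effect, so the interaction isolates
disome enrichment over and above expression changes.  Dispersion is
estimated per gene by maximising the Cox-Reid adjusted profile likelihood,
a parametric trend a0 + a1/mean is fitted by an iterated gamma GLM on the
mean scale (gene-wise estimates are right-skewed; a log-scale fit would
bias the trend low), and each gene's dispersion is re-estimated as the
maximum of adjusted likelihood plus a log-normal prior centred on the
trend.  The prior variance is the spread of log residuals in excess of the
sampling noise expected at the design's residual degrees of freedom,
floored at 0.25; genes more than 2 s.d. above the trend keep their
gene-wise estimate.  This is a deliberate simplification of the
empirical-Bayes machinery of dedicated DE packages — it reproduces their
LRT results closely (a cross-check against DESeq2 runs in the test suite)
while keeping the implementation self-contained.  P-values come from the
chi-squared(1) LRT and are BH-adjusted within each contrast.

Two notes on exactness.  The test is *approximately* invariant to
rescaling a sample's counts: size factors absorb the scale, but a
negative-binomial likelihood on integer counts is not exactly
scale-equivariant, so the invariance test uses tolerances.  And with two
replicates per cell the chi-squared approximation is only honest when the
dispersion is well estimated — the shrinkage above is what keeps the null
type-I error at the nominal 5% (the calibration is asserted on a
2000-gene null simulation in the test suite).

`classifyRQC()` applies the two-contrast rule: RQC target = disome
enrichment significantly up (adjusted P < 0.05, lfc > 0) in the
modification-mutant-vs-wild-type contrast and significantly down in the
triple-mutant-vs-double-mutant contrast; RRT = the sign-mirrored pattern;
everything else neither.  The two contrasts are run independently, which
matches the observation that including or excluding the collision-sensor
single mutant does not change the outcome.  Downstream comparisons use a
one-sided two-sample Kolmogorov-Smirnov test (`compareLogFC()`), a
two-sided Fisher's exact test on the aggregation cross-tab
(`aggregationCrosstab()`, strict > 2 / < 0.5 fold-change categories,
sample odds ratio ad/bc) and a Mann-Whitney test on per-gene codon-content
densities (`codonContentEnrichment()`).  The Fisher test is two-sided;
callers wanting a directional hypothesis can recompute from the table.

# Numerical choices and degenerate inputs

* Metagene/profile peak ties resolve toward the position closest to the
  anchor.
* `pauseScores()` with pseudocount 0 drops (with a warning) genes whose
  included window is all-zero after the coverage filter.
* Profile medians of 0 make the queue-peak threshold "any positive
  value" — relevant only for background-free simulations.
* All-zero genes are excluded from `interactionDE()`; fitted means are
  clipped to [1e-10, 1e12] inside the IRLS; dispersion optimisation is on
  log scale over [1e-8, 30].
* An empty footprint selection or an empty site query warns and returns an
  empty object rather than erroring.

# Problem sizes

The test suite validates the exact identities on toy genes (40-120
codons), the geometry on 20-200-gene simulations with 1e4-2e5 footprints,
the speed/di-codon recovery at 2000 genes x 5e6 and 300 genes x 1e6
footprints, and the classifier at 2000 genes (null calibration with 2
replicates; planted recovery with 3).  These sizes were chosen so that a
full desk-scale run completes in minutes while keeping multinomial noise
far below the planted effect sizes.

# Known limitations

* Offsets are fixed configuration; libraries whose digestion chemistry
  departs from the 28/29-nt frame-0/2 pattern need a user-supplied table.
* The simulator's stall model superimposes deterministic stacks on the
  dwell-time background rather than emerging from a kinetic traffic model;
  emergent queueing (e.g. partial stacking) is out of scope.
* The dispersion shrinkage uses a single parametric trend; on real data
  with strong mean-dispersion structure a spline trend (as in dedicated DE
  packages) may fit better.
* Real disome libraries show length- and position-dependent offsets that
  the single 45-nt rule approximates.
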