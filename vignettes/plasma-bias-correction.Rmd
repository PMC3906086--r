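---
title: "Correcting coverage bias in plasma cell-free DNA sequencing"
author: "plasmaBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting coverage bias in plasma cell-free DNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaBias)
```

# The problem

Non-invasive prenatal testing (NIPT) detects fetal trisomy by counting
sequenced cell-free DNA (cfDNA) fragments from maternal plasma.  A
trisomic fetus contributing a fetal fraction $f$ of the plasma DNA raises
the representation of the affected chromosome by a factor
$\frac{2(1-f) + 3f}{2} = 1 + f/2$ — only 5% at a typical $f = 0.10$.
Detecting so small a shift in low-pass data requires careful removal of
the systematic coverage biases of short-read sequencing: the unimodal
dependence of coverage on local GC content, the loss of reads in
repetitive (non-uniquely mappable) regions, and — specific to plasma —
the non-random cleavage of cfDNA, which leaves a strong nucleotide
signature around fragment ends.

plasmaBias implements and compares four correction protocols on binned
fragment counts, a Z-score trisomy test, and a synthetic cfDNA
simulator that provides ground truth for every recovery claim the
package makes.

# Models

## Binning and mappability

Fragments are reduced to their strand-aware 5' ends and counted in
non-overlapping, full-width bins (default 50 kb, the width in common use
for NIPT; trailing partial bins are dropped so bins stay comparable).
Mappability of a position is defined by exact k-mer matching: the
length-$k$ sequence starting there (default $k = 50$, a typical
single-end read length) must occur exactly once in the genome counting
both the k-mer and its reverse complement as hits.  This definition is
deterministic and aligner-free; aligner-derived tracks can be imported
from bedGraph when fidelity to a specific aligner matters, and the two
definitions will differ near repeats for mismatch-tolerant aligners.
A bin's mappability is the fraction of its valid read-start positions
flagged unique.  Counts are corrected by the reciprocal of bin
mappability; bins under 50% mappability are removed instead of
corrected, to avoid amplifying noise.  The alternative, hard removal of
reads in annotated repeats, is implemented for comparison
(`removeRepeatFragments`), keyed on the 5' end to stay consistent with
5'-based bin counting (an any-overlap variant is available via
`overlap = "any"`).

## The two GC models

The **binned LOESS** correction groups valid bins into 1% GC intervals,
averages the non-zero counts per interval, fits a LOESS curve (span 0.3)
to the interval means, and divides each bin's count by the fit evaluated
at its GC.  Predictions between fitted midpoints are linearly
interpolated and held constant beyond the edges, so bins at extreme GC
are never extrapolated into negative territory; a non-positive
prediction anywhere aborts the correction.  Zero-count bins are excluded
from the fit (they carry no rate information and would drag the curve
down) but still receive a prediction and a corrected value of 0.  A
variant that fits all bins directly instead of the interval means is
available behind `fitToBins = TRUE`.

The **single-position model** works at base-pair resolution: uniquely
mappable 5'-end positions are stratified by the integer G+C count of the
length-$l$ window starting at the position, strand-specifically (for
minus-strand positions the window ends at the position; GC content is
strand-symmetric but the windows differ).  The mean fragment rate per
stratum, $\lambda_s = F_s / n_s$, is smoothed over strata by local
regression weighted by stratum occupancy and clamped at zero.  Every
uniquely mappable position then receives the smoothed rate of its
stratum as its predicted rate (zero at non-unique positions), the
predictions are aggregated per bin, and the corrected value is
raw count / aggregated prediction, multiplied by the reciprocal of bin
mappability.  That final $1/m$ factor double-uses mappability — the
zeroed predictions already account for non-unique positions — but it is
applied as the protocol specifies; `reciprocalMappability = FALSE`
disables it.  Strata are integer G+C counts ($l + 1$ of them), not
percentage intervals.

## Choosing the GC window: the TV score

The right window length $l$ tracks the (unobserved, in single-end data)
fragment length.  The TV score of a stratification measures how much of
the coverage variation the strata explain: it is the half-$L_1$ distance
between the distribution of fragments over strata and the distribution
of positions over strata,

$$\mathrm{TV} = \tfrac12 \sum_s \left| \frac{F_s}{\sum F} -
\frac{n_s}{\sum n} \right| \in [0, 1],$$

zero exactly when the fragment rate is constant across strata, and
never decreased by refining the stratification.  `gcWindowScan`
evaluates the score for window lengths 1–700 bp on one shared
strand-specific position sample.  Plasma data shows a spike below 10 bp
(breakpoint motifs, not fragment-scale GC) and a broad plateau around
nucleosomal lengths, so `selectGCWindow` takes the argmax over
[50, 500] bp and falls back to 180 bp — about one nucleosome plus
linker — when the restricted curve is flat (max − median below 0.005).

## The fragmentation signature

cfDNA is cleaved by biological processes, not sonication, and the base
composition around fragment ends is strongly non-uniform.
`baseProfile` tabulates base proportions at offsets −25..+24 around the
5' or 3' terminus in fragment-strand orientation; `positionalTV` and
`greedyMotifPositions` use the same TV machinery, stratifying positions
by the bases at chosen offsets, to find which positions carry the bias.
In plasma data the informative offsets are −2, 0 and +1, which defines
the breakpoint 3-mer (64 classes, written `X*YZ` with a wildcard at
−1).  Motif context is always read from the reference at the mapped
position — not from read bases — so the stratum is a property of
(position, strand) and the same stratification applies to positions and
to fragments; this is what makes a stratified GC model coherent.
The `mapqMin = 60` filter restricts profile and motif estimation to
stringently mapped fragments but is deliberately not applied during
correction.

`stratifiedCorrect` pools the 64 motifs into two classes (default
stratum 1: C\*CC, C\*GG, C\*CA, C\*TG, the high-frequency motifs whose
GC profile is visibly shifted), fits the single-position model within
each class, and combines the two per-bin corrected values with the
sample-wide stratum proportions as weights.  Per-bin weights are
available behind `perBinWeights = TRUE`, but sample-wide weights are
the default reading of "proportion of reads belonging to the two
strata": per-bin weights would re-introduce count noise into the
combination.  Strand homogeneity of motif usage is testable with a
chi-square on the common top-20-plus-rest partition (21 categories,
df = 20), on counts — proportions alone do not define a valid test.

## The trisomy test

The sample statistic is the target chromosome's share of the corrected
bin values, excluding chrY (present in male-fetus pregnancies only, so
it would add between-sample variance).  The Z-score standardizes this
proportion against a reference set of euploid samples (sample sd,
$n - 1$ denominator); diploidy is rejected for $z > 3$, the one-tailed
99.9th percentile under normality.  Reference samples are scored
against the full reference set, themselves included — the convention
used when only a small reference pool exists.  Cohorts are summarized
by accuracy and by the discriminatory distance, the 5th percentile of
trisomy Z-scores minus the 95th percentile of euploid Z-scores
(type-7, linear-interpolation quantiles; the sign convention makes
separation positive).  A reference-free alternative,
`welchPairwiseMinT`, compares each chromosome's corrected bin values to
every other chromosome with one-sided Welch t-tests and calls
over-representation only when the minimum t across all 21 comparisons
clears the Bonferroni-adjusted critical value
($\alpha = 0.001 / (22 \times 21)$ for 22 autosomes); the sidedness
(over-representation) matches the aneuploidy alternative.

# The simulator

`simConfig`/`simulateGenome`/`simulateFragments` generate toy genomes
and plasma-like fragments with known truth, so every estimator in the
package can be tested for parameter recovery:

* **Genome**: i.i.d. bases in blocks (default 20 kb) whose GC
  probability is drawn from [0.32, 0.58], giving bins a realistic GC
  spread; optional duplicated segments create genuinely non-unique
  k-mers.
* **Fragment rate**: per (position, strand), proportional to a scaled
  Beta density of the GC fraction of the length-$l$ window (default
  peak 0.45, concentration 30 — coverage maximal in the 40–50% GC
  range, falling at the extremes), times a breakpoint-motif weight,
  times a copy factor of $2(1-f) + 3f$ on a trisomic target chromosome
  (2 elsewhere).  The default motif weights elevate the C-rich motifs
  seen in plasma (C\*CC strongest), which puts roughly one seventh of
  reads into stratum 1.
* **Lengths**: 0.85 N(166, 20) + 0.15 N(340, 30), truncated at 50 bp —
  the mono- and di-nucleosomal modes; an optional shorter fetal mode
  N(143, 15) reflects that fetal fragments run under 150 bp.
* **Alignment filter**: passing a mappability track discards fragments
  at non-unique positions, emulating upstream multi-mapper removal —
  without this, duplicated regions would not show the coverage loss
  that repeat handling exists to fix.

What the simulator does *not* model: sequencing error, PCR duplicates,
fragment-length-dependent GC bias, end-repair artifacts, and
chromosome-specific technical variation between sequencing runs.
Passing tests therefore demonstrate correctness of the estimators under
the stated generative model, not performance on real libraries, where
residual inter-run bias still requires a reference pool.

# Numerical choices

* Default problem sizes in the test-suite cohorts: 20 Mb genomes with a
  1 Mb target chromosome, $5 \times 10^5$ fragments per sample, 50 kb
  bins, 20 euploid references — a desk-scale analogue of a 0.01–0.4X
  human cohort chosen so a full cohort evaluation completes in minutes.
* Position samples: fits default to 5 × 10⁶ positions (capped at the
  number available); the cohort tests use 10⁶, at which the fit
  contribution to the Z-score variance is negligible against counting
  noise.
* Local regressions use span 0.3; with very few points the span is
  widened to cover at least ~8 points so the fit stays defined.
  Smoothed rates are clamped at 0; empty strata get predictions by
  linear interpolation between occupied strata (constant at the edges).
* Bins with N fraction above 0.1 are invalid; bins with aggregated
  single-position prediction below 10⁻⁸ or mappability below 0.5 are
  invalid.  Subsample size is round(pN).  Coordinates are 0-based
  half-open at all file interfaces (BED/bedGraph) and 1-based closed
  internally (GRanges convention).
* k-mer uniqueness is exact (2-bit packed, both strands, k ≤ 64);
  k-mers containing N, and self-reverse-complementary k-mers (which hit
  their own site on both strands), are never unique.

# Limitations

The exact-match mappability differs from aligner-specific mappability
near repeats; import an aligner-derived track when that matters.  The
fragmentation model reduces an ~18-position signature to a 3-position
motif, which captures most but not all of the positional TV signal.
Whole-chromosome trisomy only; no sub-chromosomal CNV calling, no
fetal-fraction estimation, and no empirical reference-chromosome
matching (which needs far larger reference pools than the package
targets).
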