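---
title: "Measuring A-tract spacing periodicity: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring A-tract spacing periodicity: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioscan)
```

## The signal and its model

Intrinsic DNA curvature arises when A-tracts — operationalized here as the
dinucleotides AA and TT — recur in phase with the helical repeat of
~10–11 bp, so that each tract's small bend adds up in a consistent
direction. The quantity the package estimates is therefore not a property
of individual tracts but of their *mutual spacings*: if tracts tend to sit
an integer number of helical turns apart, the spacing histogram $N(s)$
carries an oscillation with the helical period, and the strength of that
oscillation relative to the spacing noise is the measurement.

The chain applied to each sequence (or window) is:

$$N(s) \;\to\; h(s)=\frac{N(s)}{E(s)} \;\to\; h_3(s) \;\to\;
d(s)=h_3(s)-\widehat{\text{parabola}}(s) \;\to\;
Q(P)=\Bigl|\sum_{s=s_\min}^{s_\max} d(s)\,e^{2\pi i s/P}\Bigr| \;\to\;
Q^*(P)=\frac{Q(P)}{\overline{Q}_{[5,20]}}$$

Each stage removes one artifact: the normalization removes the trivial
growth of pair counts with tract density; the 3-bp average removes the
codon-periodic component that protein-coding sequence contributes at
$P=3$; the parabola removes the slow trend that compositional
heterogeneity along the replicon induces in $h(s)$; and the mean-1 scaling
over periods 5–20 bp makes spectra comparable across replicons of very
different length and composition.

### Why an amplitude-scale spectrum

The significance convention for the whole-sequence index is MaxQ ≥ 3,
calibrated so that roughly 1.5 % of random sequences exceed it. That
calibration pins down the scale on which the spectrum must be read. Over
$s \in [30,100]$ the detrended histogram supports only ~10 effectively
independent Fourier components in the 5–20 bp band; for the *squared*
magnitude of such a spectrum, the peak-to-mean ratio exceeds 3 in roughly
half of all pure-noise sequences, so a threshold of 3 on that scale could
not be a meaningful significance criterion. On the amplitude scale
$Q(P)=|\cdot|$ the same threshold is reached by about 1–1.5 % of random
sequences — the package measures 1.0–1.3 % at 500 kb across
G+C ∈ [0.30, 0.65] — matching the published convention. `perioscan`
therefore defines $Q(P)$ as the magnitude (not squared magnitude) of the
direct Fourier sum, and `null_maxq_calibration()` re-derives the
false-positive rate at any settings.

### The expected-count normalization

$E(s) = (n_t/M)^2 (M-s)$ with $M = L-1$ is the expectation under uniform
random placement of the observed number of tracts: there are $M-s$
positions for a pair at distance $s$, each occupied with probability
$(n_t/M)^2$. Real tract placement is not uniform (runs of A produce
overlapping tracts), but any smooth misfit of $E$ only adds a slow trend
to $h(s)$ that the parabolic detrending absorbs; the choice affects
numerical conditioning, not the indices.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `s_min`, `s_max` | 30, 100 | bp | spacing range analyzed; where curvature periodicity is most pronounced. The histogram is computed to `s_max`+1 so the smoother has full support. |
| `grid` | 3–25 by 0.05 | bp | period grid for direct summation; 0.05 bp keeps grid error far below the 0.2 bp MaxMax tolerance. A period-uniform (not frequency-uniform) grid is used because every index is defined in period units. |
| `norm_range` | 5–20 | bp | band with mean $Q^* = 1$; also the MaxQ/PMaxQ search band. |
| `star_range` | 9.5–11.5 | bp | curvature band for MaxQ\*/PMaxQ\*; excludes repeat-driven peaks far from the helical period. |
| `window`, `step` | 10000, 5000 | bp | sliding-window scan geometry. |
| `maxmax_threshold` | 20 | % | MaxMax at or above which a replicon is called persistently periodic. |
| `period_tol` | 0.2 | bp | agreement tolerance between window dominant periods in MaxMax. |
| `min_tracts_genome`, `min_tracts_window` | 50, 20 | tracts | below these, results are flagged missing: with fewer tracts the normalized histogram is shot-noise dominated. The per-window floor is lower because a 10 kb window at moderate A+T already holds ~10³ tracts; 20 marks truly degenerate (e.g. low-complexity or N-rich) windows. |
| `n_iter`, `alpha` | 1000, 0.05 | — | resampling protocol for the cohort tests. |

## Persistency bookkeeping

A window's dominant period `PMax_w` is the argmax of its $Q^*$ over
5–20 bp with **no magnitude threshold**; MaxMax is the modal share of
dominant periods (±0.2 bp). This makes MaxMax a pure concordance
statistic: random sequences acquire a small nonzero baseline (a few
percent for replicons with ≥40 windows), while thresholded persistence is
captured separately by Max2/Max3. Candidate periods for all three indices
are restricted to the 5–20 bp band — the spectrum outside it exists only
for plotting — and ties always resolve to the smallest period, making
every index deterministic. Missing windows stay in denominators and never
satisfy any criterion, so a replicon cannot look persistent by virtue of
unanalyzable windows. Two consequences worth knowing:

* MaxMax is only meaningful with enough windows: with $m$ windows a single
  window contributes $100/m$ percent, so replicons shorter than a few
  hundred kb should not be classified with the MaxMax ≥ 20 rule.
* When periodic and aperiodic regions alternate on the same length scale
  as the window, windows straddling a boundary still inherit the dominant
  period from their periodic half. A construction with 50 % coverage in
  10 kb blocks scanned at 10 kb/5 kb therefore yields MaxMax ≈ 75, not 50
  (25 % of windows fully periodic, 50 % half-periodic and still locked,
  25 % aperiodic). The share-of-coverage intuition (MaxMax ≈ 100·coverage)
  holds once blocks are several windows long, and the package's tests
  verify it with 100 kb blocks.

## Statistical assessments

`fisher_exact()` and `mann_whitney_u()` delegate to the standard
`stats::fisher.test()` / `stats::wilcox.test()` machinery: the two-sided
Fisher p is the point-probability sum, and the rank test enumerates the
exact distribution when the smaller sample has ≤ 8 values and no ties,
otherwise using the tie-corrected normal approximation with continuity
correction. Both are cross-checked in the test suite against exhaustive
enumeration written independently of either implementation. On the
published 23/284 vs 5/353 contingency table the two-sided point-probability
p is 1.27 × 10⁻⁴ (one-sided: 7.5 × 10⁻⁵); claims of p < 10⁻⁴ for that
table hold only under a one-sided reading.

The one-strain-per-species resampling draws uniformly one replicon per
species key (genus + species, lower-cased; strain designations ignored)
per iteration, with independent draws across iterations. Iterations in
which a prophage group empties are recorded as non-significant rather than
discarded, keeping the iteration total fixed.

## The synthetic generators

`random_sequence()` is an i.i.d. length- and G+C-preserving null: it
emulates what randomized-control genomes preserve (size, composition) and
deliberately nothing else — no codon structure, gene models, or higher
dinucleotide correlations. Null calibrations under richer randomizations
could differ slightly; conclusions about real genomes should lean on the
indices, not on re-using the 1.5 % figure for other null models.

`planted_periodic_sequence()` writes the tract motif at phase-accumulated
positions $\mathrm{round}(\phi + k\,p)$ (optionally jittered) inside
periodic blocks, which is what lets non-integer periods such as 10.9 bp
exist on an integer sequence grid. Planted signals sit on top of the
background's own random tracts, so recovered peak heights are
conservative. `synthetic_cohort()` assembles labelled cohorts — periodic
prophage-free chromosomes versus aperiodic chromosomes carrying a spliced,
recorded "prophage" insert — giving every cohort statistic a ground truth.
Passing tests on these cohorts demonstrate that the pipeline recovers
strong, cleanly planted contrasts; they do not certify power on the far
subtler contrasts in real genomes.

## Numerical choices and degenerate inputs

* Direct summation (not FFT) evaluates the spectrum exactly on the period
  grid; at 71 spacing bins × 441 periods this costs two small
  matrix-vector products per sequence, with the trig matrices cached.
* The mean-1 normalization is exact by construction (enforced to 1e-9 in
  tests); a spectrum that is identically zero over the band (possible only
  for pathological inputs) raises a degenerate-spectrum error, which the
  scan converts to a missing window.
* Sequences shorter than `s_max` + 2, or windows/sequences under the tract
  floors, yield flagged missing results, not crashes; the command-line
  tools emit `NA` markers and exit 0 for such records.
* Ambiguity codes are kept in the sequence (they count toward $L$ and
  window geometry) but can never match a tract motif, biasing the signal
  conservatively in N-rich assemblies.
* All generators and resampling protocols take explicit seeds;
  re-running any command with identical inputs, configuration and seed
  reproduces identical output bytes.

## Problem sizes used in the shipped checks

The package's own verification uses desk-scale inputs chosen to keep the
full suite in a few minutes while leaving each estimate's Monte-Carlo
error well inside its tolerance: 2000–3000 replicates of 500 kb for the
null calibration (binomial s.e. ≈ 0.2 percentage points at 1.5 %),
200 kb plants for period recovery, 60-replicon cohorts (120–200 kb
chromosomes) for the end-to-end association, and 200 replicates of 250 kb
for the null persistency distribution.

## Known limitations

* Only the A2T2 tract vocabulary ships (the registry accepts extensions);
  longer-tract definitions weight the signal differently.
* No curvature-angle computation: the package measures spacing
  periodicity, not predicted bend magnitude.
* MaxMax inherits window-quantization effects near region boundaries (see
  above); prophage-boundary localization from periodicity dips is a visual
  observation, not an automated caller here.
* The i.i.d. null understates the spectral background of genomes with
  strong repeat families; interpret MaxQ near the threshold accordingly.
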