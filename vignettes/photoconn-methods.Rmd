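---
title: "Mapping granule-cell input with noise-calibrated Z-scores: models and methods"
author: "photoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping granule-cell input with noise-calibrated Z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoconn)
```

## The experiment this package analyses

Laser photostimulation releases caged glutamate over a small patch of the
cerebellar granule-cell (GC) layer while a target neuron — a Purkinje cell
(PC), Golgi cell (GoC) or molecular-layer interneuron (MLI) — is held in
voltage clamp. Each uncaging spot recruits a patch of GCs; each recruited
GC fires a burst of action potentials and each spike deposits roughly one
unitary charge (about 0.1 pC at the GC–PC synapse) in the target. Scanning
a lattice of spots therefore produces, per cell, a grid of current sweeps
whose evoked synaptic charge measures the functional connectivity between
that GC patch and the recorded cell.

The standard lattice spans 332 µm on each side of the recorded soma with a
41.5 µm step (17 mediolateral positions, 664 µm mapped width) over 2–5
rows of GC-layer depth, i.e. 34–85 sites. Positions are expressed in
signed µm from the cerebellar midline, with the recorded soma registered
into a standardized zebrin-band coordinate frame (P1+ 48.5 µm, P1−
275.6 µm, P2+ 64.6 µm, P2− 445.2 µm from the midline) so cells from
different animals are comparable.

## The per-site statistic

For every sweep the evoked charge is the baseline-subtracted integral of
current over the 200 ms window after stimulus onset, reported as inward
(excitatory) magnitude in pC; the baseline is the mean current over the
50 ms preceding the stimulus. The same integral applied to the terminal
200 ms of every sweep of a cell yields that cell's noise-charge histogram,
summarized by its mean $\mu_Q$ and standard deviation $\sigma_Q$. The
per-site statistic is

$$ Z_{\mathrm{site}} \;=\; \frac{\bar q_{\mathrm{site}} - \mu_Q}{\sigma_Q}, $$

where $\bar q_{\mathrm{site}}$ is the mean evoked charge across repeats. A
site is *significant* (functionally connected) iff $Z$ strictly exceeds
3.09, the one-sided standard-normal quantile at significance level 0.001
(`significanceThreshold()`); equality is classified silent, since the
field's convention writes both classes with strict inequalities and leaves
the boundary undefined. No multiple-testing correction is applied — the
fixed per-site threshold is a deliberate reproduction of standard
practice, and the 0.001 level is itself the conservative correction.
`nullCalibration()` verifies the consequence: on noise-only recordings the
pipeline flags very close to 0.1 % of sites.

Because the charge is an integral over thousands of samples, $Z$ is
insensitive to the sampling rate; tests and the acceptance script exploit
this by simulating at 2 kHz rather than the 20–50 kHz of real
acquisitions.

For MLIs, whose evoked currents are small but whose EPSCs are countable,
the statistic is an event-count analogue: matched-filter EPSC counts in
the response window standardized against the counts of the terminal
control window (`countZscore()`, `computeMap(statistic = "events")`).

## From maps to mediolateral patterns

GC axons ascend and run transversely, so GCs at all depths of one
mediolateral position project through the same parallel-fiber beam.
Depth rows are therefore pooled by taking the maximum $Z$ per
mediolateral position (`maxProject()`; the maximum is taken on $Z$, not on
raw charge, because $Z$ is the comparable quantity across sites). A
position is silent only if no depth row at that position is significant.

The projected profile is resampled by linear interpolation onto a 1 µm
support and convolved with a unit-mass triangular kernel of 18 µm
half-width (`toPattern()`). The dense support exists because an 18 µm
kernel cannot act on the 41.5 µm lattice; linear interpolation is the
minimal-assumption resampler. At the support edges the kernel is
renormalized over its in-range part, so edges are unbiased rather than
damped. Thresholding into significant/silent is always done on unsmoothed
site $Z$; smoothing enters only the correlation and median-pattern
analyses.

## Population comparison and co-clustering

Cells are compared after registration into the standard band frame
(`registerPosition()`, `mapMeasuredPosition()`). Pattern pairs are
correlated position by position (Pearson $r$) on the intersection of
their supports resampled at 10 µm (`patternCorrelation()`). The null
reference is the shuffled-pair distribution: random re-pairings of the
population excluding self-pairs and true neighbor pairs, pairing without
replacement within each shuffle round (`shuffleNull()`).

Groups of cells are formed by a 100 µm window slid in 10 µm steps along
the registered soma positions; each group's representative is the
position-wise *median* of its members' smoothed patterns, with the median
absolute deviation as dispersion (`medianPatterns()`; windows may hold a
single cell — the real population of 49 cells over ~700 µm is sparse — so
groups report their membership and consumers may filter). The Pearson
correlation between every couple of group medians forms the correlation
matrix, labeled by window centers; undefined correlations propagate as
`NA`, never as 0.

`spectralCocluster()` implements bipartite spectral graph partitioning:
correlations are shifted to non-negative weights by $(r+1)/2$ (a monotone
choice; any affine map works), the weight matrix is normalized as
$D_1^{-1/2} A D_2^{-1/2}$, the leading $\lceil \log_2 k \rceil$
non-trivial singular-vector pairs form a joint row/column embedding, and
k-means (with a fixed seed and many restarts, so runs are reproducible)
partitions it. Symmetric input yields identical row and column
assignments. Clusters are renumbered by first appearance along the
position axis and checked for contiguity. Because no fixed cluster count
is assumed, `k = "auto"` scans $k \in 2..8$ and keeps the $k$ maximizing
mean within-cluster minus mean between-cluster correlation; $k = 4$ is
the replication preset for the published map.

The soma-centered control (`centerOnSoma()`) guards against the trivial
explanation that clusters only reflect local input: patterns are
translated to put every soma at 0, normalized to their own peak, and
averaged. Genuine shared distal structure lives at fixed midline
coordinates, so centering must wash it out, leaving one central peak and
no secondary peak.

## Plasticity

A pre/post map pair (same grid, and deliberately one pooled noise model —
computed from the pre sweeps or pre+post — so $\Delta Z = Z_{post} -
Z_{pre}$ reflects response change, not noise re-estimation) is compared
site by site. Sites with $\Delta Z > 3.09$ are potentiated, $\Delta Z <
-3.09$ depressed; a potentiated site that was silent pre-induction is
*awakened* (a refinement of potentiated — awakened sites count among the
potentiated in totals). `deltaVsInitial()` fits the ordinary
least-squares slope and Pearson $r$ of $\Delta Z$ against initial $Z$; a
negative relationship summarizes "strong connections depress, weak ones
potentiate". The published description of this regression pairs a
negative correlation with positive printed magnitudes; this package
treats the printed values as unsigned magnitudes and asserts only the
direction, which the synthetic experiments reproduce.

## The synthetic-experiment generator

Every stage above is testable without recordings because `synthesizeCell()`
renders the experiment the analysis assumes:

* **Ground truth** (`groundTruth()`): per-site connection counts derive
  from Gaussian hotspots parameterized by center, half-width at
  half-maximum (floored at 33 µm, the direct-spot size of the
  photostimulation) and peak strength; the hotspot width combines in
  quadrature with a 45 µm activation spread — between the 33.0 µm
  direct-spot and 59.6 µm whole-cell estimates of the uncaging
  point-spread. Counts round to integers; sites rounding to zero are
  silent. The per-site distribution of counts is deliberately exposed as
  configuration rather than asserted, since no empirical per-site count
  distribution is available.
* **Traces**: a connected site receives `round(count × burst)` events
  (burst defaults to 19.6 spikes per recruited GC, SD 6.6 when drawn), at
  times uniform over the first 100 ms after onset; each event is a
  difference-of-exponentials EPSC (1 ms rise, 10 ms decay — kinetics are a
  package choice, only charges are constrained) scaled so the train's
  total charge equals count × q_u × burst *exactly*, which makes charge
  conservation testable by numeric integration.
* **Noise**: white Gaussian current noise. Real recording noise is
  colored and includes spontaneous synaptic activity, but the Z statistic
  operates on 200 ms charge integrals where the central-limit argument
  makes whiteness immaterial; what matters is the integrated noise-charge
  scale. The default 150 pA at 20 kHz/1 s sweeps yields σ_Q ≈ 1 pC, so
  typical ~10 pC evoked charges sit at Z ≈ 10, the scale of real maps.
  Note that σ_Q depends on the sampling settings (σ_Q = σ·dt·√(N_w +
  N_w²/N_b)/1000); tests that lower the rate for speed adjust σ
  accordingly.
* **Seeds**: one root seed, split hierarchically per cell, then per site
  and repeat, so enlarging a population never perturbs the cells already
  generated, and identical seeds reproduce byte-identical traces. A
  missing seed is an error, never silent nondeterminism.
* **Archetypes** (`defaultArchetypes()`): four hotspot templates spanning
  0–400 µm from the midline, each combining a local hotspot with shared
  distal (including contralateral) partners; per-cell jitter of hotspot
  centers (SD 10 µm) and log-normal strength jitter (SD 0.15) emulates the
  within-cluster variability of real maps. `archetypes = NULL` generates
  independent cells (uniformly placed hotspots) for null studies.
* **Plasticity** (`applyPlasticity()`): multiplicative rules act on the
  unitary charge of connected sites; awakening raises a silent site's
  count to a configured value.

What passing tests on this generator do **not** show: robustness to
colored noise and spontaneous activity bursts, to series-resistance drift
across a session, to overlapping activation of neighboring sites beyond
the Gaussian spread model, or to real inter-animal variability in band
geometry. These require recordings.

## Numerical choices and degenerate inputs

* **Charge windows**: response 0–200 ms after onset, noise the last
  200 ms of each sweep, baseline the 50 ms before onset (the alternative
  — baselining on the noise-window mean — changes nothing under
  stationarity and is not used). Windows outside the trace raise bounds
  errors.
* **Degenerate noise** (σ_Q = 0) is an error, not an NA: downstream Z
  would be undefined. Similarly, zero-variance patterns make correlations
  undefined and propagate as `NA` entries; a constant correlation matrix
  refuses to co-cluster.
* **Direct-current removal** (`removeDirectCurrent()`, used for GoC maps):
  the slow stimulation artifact is estimated by a running median (101 ms)
  and subtracted, retaining the overall mean level. A plain running
  median partially tracks inward events — a median window follows any
  monotone segment, and measured charge losses were 13–43 % whatever the
  window — so the estimator is event-aware: inward transients are located
  as excursions below the trace's morphological closing (61 ms running
  max, then min), each detected stretch is extended over the EPSC tail
  (35 ms forward) and bridged linearly between flanking 15 ms local
  medians, and the median runs on the bridged trace. Errors are then
  bounded by the artifact's curvature over a bridge rather than its
  slope: single events well inside the response window recover to a few
  percent, sparse trains to ~7 % mean under 5 pA noise, and the filter
  perturbs noise-only charges by only ~0.03 pC. Densely overlapping
  trains riding a fast-curving artifact remain partially confounded — no
  single-trace method can separate them, and this limit is inherited by
  any analysis of direct-current-contaminated maps.
* **Event detection**: matched filter (unit-norm difference-of-
  exponentials template) with threshold 5 × the median absolute deviation
  of the filter output and 5 ms non-maximum suppression. The detector is
  a package choice; only the counting window is externally constrained.
* **Tie-breaks**: cluster labels are renumbered by first appearance along
  the position axis; k-means uses 50 restarts under a fixed seed.

## Problem sizes used by tests and the acceptance script

The suite runs synthetic experiments at 2 kHz sampling with 500 ms sweeps
(stimulus at 100 ms), which preserves every statistical property of the
analysis while keeping the suite fast: the null calibration uses 10^5
noise-only single-trial sites in cells of 5,000 (each noise model pools
5,000 windows); archetype recovery uses 16 cells × 34 sites × 3 repeats;
the shuffled null uses 24 independent cells and ≥ 400 shuffled pairs.
These sizes are the package's documented test conditions, chosen once.

Expected results at these sizes, all recomputed by
`scripts/acceptance.R` and `tests/testthat/test-acceptance.R`: a
noise-only significant-site fraction statistically compatible with 0.001;
a shuffled-pair mean r within 0.05 of zero (the published shuffled value
is 0.02 ± 0.09); exact recovery of planted biclusters against brute-force
bipartition; ARI ≥ 0.9 against planted archetypes over groups whose
planted identity is unambiguous (windows straddling an archetype boundary
mix members and have no defined label); hotspot peaks within one grid
step; ≥ 95 % re-classification of strong planted plasticity effects.

## Known limitations

The headline biological results of the mapping study — four clusters on
49 real PCs, 10.3 pC mean local charge, 38 % silent sites, 22 % plastic
sites, r = 0.74 between neighboring cells — depend on recordings that are
not publicly deposited; this package reproduces the *analysis* and
validates it by parameter recovery on synthetic data, not those numbers.
The generator's archetypes are a modeling device for cluster structure,
not an anatomical claim; cluster counts found by the k scan carry no
significance statement (no gap statistic or consensus clustering), and
recovered clusters carry no claim about anatomical microzone identity.
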