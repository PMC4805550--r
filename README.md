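# photoconn

Functional connectivity mapping from photostimulation electrophysiology.

## What problem this solves, and for whom

Laser glutamate-uncaging over the cerebellar granule-cell (GC) layer,
paired with a voltage-clamped target neuron (Purkinje cell, Golgi cell or
molecular-layer interneuron), yields one current sweep per stimulated grid
site. Turning those raw sweeps into a *functional connectivity map* — and
turning maps from many cells and animals into population-level statements
about stereotyped input patterns and their plasticity — requires a chain
of statistics that is easy to get subtly wrong: noise-calibrated
significance per site, depth pooling, spatial smoothing, cross-animal
registration, correlation nulls, biclustering, and pre/post comparisons.
`photoconn` packages that chain for electrophysiologists analysing
point-scan photostimulation mapping experiments, together with a
synthetic-experiment generator that makes every stage verifiable by
parameter recovery.

## The statistic at the core

For each site, with $\bar q$ the mean evoked charge (baseline-subtracted
integral of inward current over the 200 ms post-stimulus window) and
$(\mu_Q, \sigma_Q)$ the mean and SD of the cell's noise-charge histogram
(the same integral over the terminal 200 ms of every sweep):

$$ Z_{\mathrm{site}} = \frac{\bar q - \mu_Q}{\sigma_Q},\qquad
   \text{significant} \iff Z > 3.09 \;(p = 0.001). $$

Per-position depth maxima of $Z$, smoothed with an 18 µm triangular
kernel on a 1 µm support, form each cell's mediolateral input pattern.
Cells registered into a standard zebrin-band frame are grouped by a
100 µm window slid in 10 µm steps; Pearson correlations between group
median patterns form a correlation matrix that bipartite spectral
co-clustering (SVD of the degree-normalized matrix + k-means on the
singular-vector embedding) partitions into position-contiguous clusters.
Pre/post map pairs are compared via $\Delta Z$ with the same 3.09
threshold (potentiated / depressed / awakened / unchanged).

See `vignettes/photoconn-methods.Rmd` for the full model, parameter
meanings and design choices.

## Worked example

Simulate one mapped cell with two planted hotspots (10 and 6 connections
peak, at 120 and 360 µm from the midline), build its map and pattern:

```r
library(photoconn)

geom  <- gridGeometry(nDepthRows = 2, midlineOffset = 120)
truth <- groundTruth(geom,
  hotspots = data.frame(center_um = c(120, 360), halfwidth_um = 45,
                        strength = c(10, 6)),
  burstSd = 0)
rec <- synthesizeCell(truth, geom, noiseSpec(), nRepeats = 3, seed = 42)

(map <- computeMap(rec))
#> ConnectivityMap of cell1 (charge statistic): 34 sites, 18 significant (Z > 3.09)
#>   noise: mu = -0.121 pC, sigma = 1.01 pC (n = 102)

toPattern(map)
#> MediolateralPattern of cell1: [-212, 452] um, peak Z = 19.30 at 120 um (kernel 18 um)
```

The noise model pooled 102 terminal windows (34 sites × 3 repeats) and
estimates σ_Q ≈ 1 pC; the planted 120 µm hotspot (10 connections × 0.1 pC
× 19.6 spikes ≈ 19.6 pC expected charge) is recovered as the pattern peak
at exactly 120 µm with Z ≈ 19, and 18 of 34 sites — the two hotspot
neighborhoods across both depth rows — exceed the 3.09 threshold.

A full population pipeline (16 cells drawn from 4 connectivity
archetypes, short sweeps for speed), through grouping, correlation and
co-clustering:

```r
cfg <- defaultConfig()
cfg$synth$n_cells <- 16; cfg$synth$n_repeats <- 3
cfg$noise$duration_ms <- 500; cfg$noise$sampling_khz <- 2
cfg$noise$stim_onset_ms <- 100

b <- runPipeline(cfg, seed = 42)
#> simulate: 16 cells generated
#> map: 16 cells, 544 sites, 112 significant (Z > 3.09)
#> pattern: 16 mediolateral patterns (kernel 18 um)
#> groups: 39 median-pattern groups (window 100 um, shift 10 um)
#> cluster: k = 4, contiguous clusters: 4 of 4

b@derived$clusters
#> ClusterAssignment: k = 4 over 39 groups; contiguous: yes, yes, yes, yes
```

The data-driven k scan (`cfg$analysis$k = "auto"`, the default) selects
k = 4 — the planted number of archetypes — and all four clusters occupy
contiguous runs along the mediolateral axis. Derived tables
(`maps_table`, `patterns_table`, `groups_table`, `matrix_table`,
`clusters_table`) are plain data.frames; `writeBundle()` serializes the
whole experiment, losslessly for traces, to a plain-text directory
container.

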