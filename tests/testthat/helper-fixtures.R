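# Shared fixtures: small, fast synthetic experiments.
# Short sweeps at coarse sampling keep tests quick; the charge/Z pipeline
# is insensitive to the sampling rate because it integrates.

fastNoise <- function(sdPa = 150, samplingKhz = 2) {
  noiseSpec(sdPa = sdPa, durationMs = 500, samplingKhz = samplingKhz,
            stimOnsetMs = 100)
}

# one cell, one depth row, a single planted hotspot at the soma
smallCell <- function(strength = 10, nRepeats = 2, seed = 1,
                      noise = fastNoise(), nDepthRows = 1L) {
  geom <- gridGeometry(nDepthRows = nDepthRows)
  truth <- groundTruth(geom, data.frame(center_um = 0, halfwidth_um = 45,
                                        strength = strength), burstSd = 0)
  synthesizeCell(truth, geom, noise, nRepeats = nRepeats, seed = seed)
}

# a difference-of-exponentials EPSC (1 pC per unit q) starting at `at` ms
addEpsc <- function(x, dt, at, q = 1, riseMs = 1, decayMs = 10) {
  tk <- seq(0, riseMs + 10 * decayMs, by = dt)
  k <- exp(-tk / decayMs) - exp(-tk / riseMs)
  k <- k / (sum(k) * dt / 1000)
  i <- round(at / dt) + 1
  j <- i:min(length(x), i + length(k) - 1)
  x[j] <- x[j] - q * k[seq_along(j)]
  x
}

# build a MediolateralPattern directly from positions/values
mkPattern <- function(values, positions = seq_along(values) - 1,
                      soma = mean(positions), id = "p",
                      halfwidth = 18) {
  new("MediolateralPattern", positions = as.numeric(positions),
      values = as.numeric(values), cellId = id,
      somaPosition = soma, kernelHalfwidth = halfwidth)
}

# gaussian-bump pattern on a fixed support (for population-level tests)
bumpPattern <- function(centers, heights, support = seq(-400, 600, by = 1),
                        sd = 30, soma = centers[1], id = "p") {
  v <- numeric(length(support))
  for (i in seq_along(centers))
    v <- v + heights[i] * exp(-(support - centers[i])^2 / (2 * sd^2))
  mkPattern(v, support, soma = soma, id = id)
}

# sample indices whose time falls in [start, start + len)
.windowIdxTest <- function(n, dt, start, len) {
  t <- (seq_len(n) - 1) * dt
  which(t >= start & t < start + len)
}

# agreement between two partitions (chance-corrected); mclust provides the
# reference implementation
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
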