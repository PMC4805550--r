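#' False-positive calibration of the Z-score pipeline
#'
#' Runs the complete charge-to-Z pipeline on noise-only synthetic
#' recordings (no planted connections, one sweep per site) and reports the
#' fraction of sites classified significant. With a well-estimated
#' per-cell noise model, that fraction should match the nominal
#' significance level of the threshold (0.001 for the default 3.09).
#'
#' Sites are organized into cells of \code{sitesPerCell} sites so each
#' cell's noise model is pooled over well more than 1,000 terminal noise
#' windows, as in the real analysis.
#'
#' @param nSites total number of noise-only sites (>= \code{sitesPerCell}).
#' @param sitesPerCell sites (and thus pooled noise windows) per synthetic
#'   cell; rounded up to an odd lattice size.
#' @param noise a [NoiseSpec-class]; the default uses short, coarsely
#'   sampled sweeps, to which the Z statistic is insensitive since it
#'   operates on integrated charge.
#' @param threshold significance threshold.
#' @param seed integer root seed (mandatory).
#' @return list: \code{fraction} significant, \code{nSignificant},
#'   \code{nSites} actually simulated, \code{ci95} binomial 95% CI.
#' @export
nullCalibration <- function(nSites = 1e5, sitesPerCell = 5000,
                            noise = noiseSpec(durationMs = 500,
                                              samplingKhz = 2,
                                              stimOnsetMs = 100),
                            threshold = significanceThreshold(), seed) {
  seed <- .requireSeed(seed)
  nSide <- ceiling((sitesPerCell - 1) / 2)
  geom <- gridGeometry(halfExtent = nSide * 41.5, step = 41.5,
                       nDepthRows = 1)
  perCell <- 2 * nSide + 1
  nCellsNeeded <- ceiling(nSites / perCell)
  truth <- groundTruth(geom, hotspots = NULL, burstSd = 0)
  nSig <- 0L; nTot <- 0L
  for (i in seq_len(nCellsNeeded)) {
    rec <- synthesizeCell(truth, geom, noise, nRepeats = 1,
                          seed = .childSeed(seed, i),
                          cellId = sprintf("null%03d", i))
    m <- computeMap(rec)
    nSig <- nSig + sum(m@sites$z > threshold)
    nTot <- nTot + nrow(m@sites)
  }
  ci <- as.numeric(stats::binom.test(nSig, nTot)$conf.int)
  list(fraction = nSig / nTot, nSignificant = nSig, nSites = nTot,
       ci95 = ci)
}
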