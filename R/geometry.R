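#' Construct a photostimulation grid geometry
#'
#' The default geometry reproduces the mapping protocol: the lattice extends
#' 332 um on each side of the recorded cell with a 41.5 um step, giving 17
#' mediolateral positions (664 um mapped width); with 2--5 depth rows this
#' yields 34--85 sites.
#'
#' @param halfExtent grid half-extent in um (default 332).
#' @param step lattice step in um (default 41.5).
#' @param nDepthRows number of depth rows in the granule-cell layer.
#' @param midlineOffset soma position in um from the cerebellar midline
#'   (ipsilateral positive).
#' @return a [GridGeometry-class] object.
#' @examples
#' g <- gridGeometry(nDepthRows = 2)
#' nrow(makeGrid(g))  # 34 sites
#' @export
gridGeometry <- function(halfExtent = 332, step = 41.5, nDepthRows = 2,
                         midlineOffset = 0) {
  new("GridGeometry", halfExtent = as.numeric(halfExtent),
      step = as.numeric(step), nDepthRows = as.integer(nDepthRows),
      midlineOffset = as.numeric(midlineOffset))
}

#' @rdname gridGeometry
#' @param x a \code{GridGeometry}.
#' @export
setMethod("geometry", "CellRecording", function(x) x@geometry)

#' @rdname gridGeometry
#' @export
setMethod("geometry", "ConnectivityMap", function(x) x@geometry)

#' Enumerate the stimulation sites of a grid
#'
#' Sites are ordered by (depth row, mediolateral position). Mediolateral
#' coordinates are reported in signed um from the midline; the lattice is
#' symmetric about the recorded cell at \code{midlineOffset}.
#'
#' @param geom a [GridGeometry-class].
#' @return data.frame with columns \code{site} (1-based index),
#'   \code{ml_um}, \code{depth_row} (0-based).
#' @export
makeGrid <- function(geom) {
  stopifnot(is(geom, "GridGeometry"))
  validObject(geom)
  nSide <- round(geom@halfExtent / geom@step)
  offsets <- seq.int(-nSide, nSide) * geom@step
  ml <- geom@midlineOffset + offsets
  grid <- expand.grid(ml_um = ml,
                      depth_row = seq_len(geom@nDepthRows) - 1L)
  grid <- grid[order(grid$depth_row, grid$ml_um), ]
  data.frame(site = seq_len(nrow(grid)), ml_um = grid$ml_um,
             depth_row = as.integer(grid$depth_row), row.names = NULL)
}

#' Describe the synthetic recording conditions
#'
#' Defaults give a 1 s sweep sampled at 20 kHz with the stimulus at 200 ms,
#' so the evoked response occupies 200--400 ms and the terminal noise window
#' 800--1000 ms.
#'
#' The default current-noise SD of 150 pA is chosen so the integrated
#' noise-charge SD lands near 1 pC at these sampling settings: the white
#' generator noise stands in for every noise source of a real recording
#' (instrument noise plus spontaneous synaptic activity), and 1 pC puts
#' typical ~10 pC evoked charges at Z-scores around 10, the scale seen in
#' real maps.
#'
#' @param sdPa white current-noise SD in pA.
#' @param durationMs sweep duration, ms.
#' @param samplingKhz sampling rate, kHz.
#' @param stimOnsetMs stimulus onset, ms.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(sdPa = 150, durationMs = 1000, samplingKhz = 20,
                      stimOnsetMs = 200) {
  new("NoiseSpec", sdPa = as.numeric(sdPa), durationMs = as.numeric(durationMs),
      samplingKhz = as.numeric(samplingKhz), stimOnsetMs = as.numeric(stimOnsetMs))
}

#' Wrap a raw current sweep
#'
#' @param samples current samples in pA.
#' @param dt sampling interval in ms.
#' @param stimOnset stimulus onset in ms.
#' @param siteId stimulated site index.
#' @param trial repeat index.
#' @return a [PhotostimTrace-class].
#' @export
photostimTrace <- function(samples, dt, stimOnset, siteId = 1L, trial = 1L) {
  new("PhotostimTrace", samples = as.numeric(samples), dt = as.numeric(dt),
      stimOnset = as.numeric(stimOnset), siteId = as.integer(siteId),
      trial = as.integer(trial))
}

#' @rdname photostimTrace
#' @param x a \code{PhotostimTrace}.
#' @export
setMethod("traceSamples", "PhotostimTrace", function(x) x@samples)

setMethod("show", "GridGeometry", function(object) {
  nSide <- round(object@halfExtent / object@step)
  cat("GridGeometry:", 2 * nSide + 1, "mediolateral positions x",
      object@nDepthRows, "depth rows =",
      (2 * nSide + 1) * object@nDepthRows, "sites\n")
  cat(sprintf("  half-extent %g um, step %g um, soma at %g um from midline\n",
              object@halfExtent, object@step, object@midlineOffset))
})

setMethod("show", "PhotostimTrace", function(object) {
  cat(sprintf("PhotostimTrace: site %d trial %d, %d samples @ %g kHz, stim at %g ms\n",
              object@siteId, object@trial, length(object@samples),
              1 / object@dt, object@stimOnset))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: %g ms @ %g kHz, stim %g ms, current noise SD %g pA\n",
              object@durationMs, object@samplingKhz, object@stimOnsetMs,
              object@sdPa))
})
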