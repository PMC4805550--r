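#' @import methods
NULL

#' Photostimulation grid geometry
#'
#' Describes the uncaging grid used to map granule-cell inputs: a regular
#' mediolateral lattice extending \code{halfExtent} micrometres on each side
#' of the recorded cell, sampled every \code{step} micrometres, repeated over
#' \code{nDepthRows} rows spanning the depth of the granule-cell layer.
#' Mediolateral site coordinates are expressed in signed micrometres from the
#' cerebellar midline (ipsilateral positive); \code{midlineOffset} is the
#' recorded soma's own midline coordinate, so the grid is centered on the
#' cell but reported in midline coordinates.
#'
#' @slot halfExtent numeric(1), grid half-extent in um (default 332).
#' @slot step numeric(1), lattice step in um (default 41.5).
#' @slot nDepthRows integer(1), number of depth rows (typically 2--5).
#' @slot midlineOffset numeric(1), soma position in um from the midline.
#'
#' @seealso [gridGeometry()], [makeGrid()]
#' @exportClass GridGeometry
setClass("GridGeometry",
  representation(
    halfExtent = "numeric",
    step = "numeric",
    nDepthRows = "integer",
    midlineOffset = "numeric"
  )
)

setValidity("GridGeometry", function(object) {
  msg <- character()
  if (length(object@halfExtent) != 1L || is.na(object@halfExtent) ||
      object@halfExtent < 0)
    msg <- c(msg, "'halfExtent' must be a single non-negative number")
  if (length(object@step) != 1L || is.na(object@step) || object@step <= 0)
    msg <- c(msg, "'step' must be a single positive number")
  if (length(object@nDepthRows) != 1L || is.na(object@nDepthRows) ||
      object@nDepthRows < 1L)
    msg <- c(msg, "'nDepthRows' must be a positive integer")
  if (length(object@midlineOffset) != 1L || is.na(object@midlineOffset))
    msg <- c(msg, "'midlineOffset' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Sampling and noise description of a synthetic recording
#'
#' @slot sdPa numeric(1), standard deviation of the white Gaussian current
#'   noise in pA.
#' @slot durationMs numeric(1), sweep duration in ms.
#' @slot samplingKhz numeric(1), sampling rate in kHz.
#' @slot stimOnsetMs numeric(1), photostimulation onset in ms.
#'
#' @seealso [noiseSpec()]
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(
    sdPa = "numeric",
    durationMs = "numeric",
    samplingKhz = "numeric",
    stimOnsetMs = "numeric"
  )
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (object@sdPa < 0) msg <- c(msg, "'sdPa' must be >= 0")
  if (object@samplingKhz <= 0) msg <- c(msg, "'samplingKhz' must be > 0")
  if (object@stimOnsetMs < 0) msg <- c(msg, "'stimOnsetMs' must be >= 0")
  # room for the 200 ms response window and the 200 ms terminal noise window
  if (object@durationMs < object@stimOnsetMs + 400)
    msg <- c(msg, "'durationMs' must be >= stimOnsetMs + 400 ms")
  if (length(msg)) msg else TRUE
})

#' A single digitized photostimulation sweep
#'
#' Holds one voltage-clamp current trace recorded while glutamate was
#' uncaged at one grid site, together with its sampling metadata.
#'
#' @slot samples numeric, current in pA.
#' @slot dt numeric(1), sampling interval in ms.
#' @slot stimOnset numeric(1), stimulus onset in ms from sweep start.
#' @slot siteId integer(1), index of the stimulated site.
#' @slot trial integer(1), repeat index.
#'
#' @seealso [photostimTrace()], [integrateCharge()]
#' @exportClass PhotostimTrace
setClass("PhotostimTrace",
  representation(
    samples = "numeric",
    dt = "numeric",
    stimOnset = "numeric",
    siteId = "integer",
    trial = "integer"
  )
)

setValidity("PhotostimTrace", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  dur <- length(object@samples) * object@dt
  if (dur < object@stimOnset + 400)
    msg <- c(msg, "trace must extend >= 400 ms beyond stimulus onset")
  if (length(msg)) msg else TRUE
})

#' Per-cell noise-charge model
#'
#' The noise model against which evoked synaptic charges are standardized.
#' It is built once per cell by integrating the terminal 200 ms window of
#' every sweep of that cell (the same baseline-subtracted integral used for
#' the response window), pooling the resulting charges into a histogram, and
#' recording its mean \code{muQ} and standard deviation \code{sigmaQ}.
#'
#' @slot muQ numeric(1), mean noise charge in pC.
#' @slot sigmaQ numeric(1), standard deviation of the noise charge in pC.
#' @slot nSamples integer(1), number of noise windows pooled.
#'
#' @seealso [estimateNoise()], [siteZscore()]
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(muQ = "numeric", sigmaQ = "numeric", nSamples = "integer")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@sigmaQ < 0) msg <- c(msg, "'sigmaQ' must be >= 0")
  if (object@nSamples < 2L) msg <- c(msg, "'nSamples' must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Planted connectivity ground truth for one synthetic cell
#'
#' @slot sites data.frame with one row per grid site: \code{site} (index),
#'   \code{ml_um} (midline coordinate), \code{depth_row} (0-based),
#'   \code{count} (number of connected granule cells recruited at the site),
#'   \code{q_u} (mean unitary charge, pC), \code{burst} (mean spikes per
#'   recruited cell).
#' @slot hotspots data.frame of \code{center_um}, \code{halfwidth_um},
#'   \code{strength} descriptors the site counts were derived from.
#' @slot archetypeId character(1) or NA, identifier of the archetype the
#'   truth was instantiated from.
#'
#' @seealso [groundTruth()], [synthesizeCell()], [applyPlasticity()]
#' @exportClass GroundTruthMap
setClass("GroundTruthMap",
  representation(
    sites = "data.frame",
    hotspots = "data.frame",
    archetypeId = "character"
  )
)

setValidity("GroundTruthMap", function(object) {
  msg <- character()
  need <- c("site", "ml_um", "depth_row", "count", "q_u", "burst")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("'sites' must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(object@sites$count < 0))
      msg <- c(msg, "connection counts must be non-negative")
    if (any(object@sites$count != round(object@sites$count)))
      msg <- c(msg, "connection counts must be integers")
  }
  if (nrow(object@hotspots) &&
      any(object@hotspots$halfwidth_um < 33))
    msg <- c(msg, "hotspot half-widths must be >= 33 um (photostimulation spread floor)")
  if (length(msg)) msg else TRUE
})

#' Raw recordings of one (synthetic or imported) cell
#'
#' Sweeps are stored as a site x trial x sample array of currents in pA,
#' alongside the site coordinate table and, for synthetic cells, the planted
#' ground truth.
#'
#' @slot cellId character(1).
#' @slot traces 3-d numeric array, \code{[site, trial, sample]} in pA.
#' @slot dt numeric(1), sampling interval in ms.
#' @slot stimOnset numeric(1), stimulus onset in ms.
#' @slot sites data.frame: \code{site}, \code{ml_um}, \code{depth_row}.
#' @slot geometry a [GridGeometry-class].
#' @slot meta list of cell metadata (\code{type}, \code{band}, \code{soma_um}).
#' @slot truth a [GroundTruthMap-class] or NULL.
#'
#' @seealso [synthesizeCell()], [computeMap()]
#' @exportClass CellRecording
setClass("CellRecording",
  representation(
    cellId = "character",
    traces = "array",
    dt = "numeric",
    stimOnset = "numeric",
    sites = "data.frame",
    geometry = "GridGeometry",
    meta = "list",
    truth = "ANY"
  )
)

setValidity("CellRecording", function(object) {
  msg <- character()
  if (length(dim(object@traces)) != 3L)
    msg <- c(msg, "'traces' must be a site x trial x sample array")
  else if (dim(object@traces)[1L] != nrow(object@sites))
    msg <- c(msg, "first dimension of 'traces' must match nrow(sites)")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Functional connectivity map of one cell
#'
#' Per-site mean evoked charge and its Z-score against the cell's noise
#' model, on the 2-d (mediolateral x depth) grid.
#'
#' @slot cellId character(1).
#' @slot sites data.frame: \code{site}, \code{ml_um}, \code{depth_row},
#'   \code{mean_charge_pC}, \code{z}, \code{n_trials}.
#' @slot noise the [NoiseModel-class] used for standardization.
#' @slot geometry the grid [GridGeometry-class].
#' @slot statistic character(1), \code{"charge"} or \code{"events"},
#'   recording which per-site statistic the Z-scores standardize.
#'
#' @seealso [computeMap()], [classifySites()], [maxProject()]
#' @exportClass ConnectivityMap
setClass("ConnectivityMap",
  representation(
    cellId = "character",
    sites = "data.frame",
    noise = "NoiseModel",
    geometry = "GridGeometry",
    statistic = "character"
  )
)

setValidity("ConnectivityMap", function(object) {
  msg <- character()
  need <- c("site", "ml_um", "depth_row", "z")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("'sites' must have columns:",
                        paste(need, collapse = ", ")))
  else if (anyNA(object@sites$z))
    msg <- c(msg, "'z' must be defined for every site")
  if (length(msg)) msg else TRUE
})

#' Smoothed 1-d mediolateral input pattern
#'
#' Depth-maximum Z-scores placed at their midline coordinates, resampled to
#' a regular 1 um support and convolved with a unit-mass triangular kernel.
#'
#' @slot positions numeric, um from the midline, strictly increasing.
#' @slot values numeric, smoothed Z-scores.
#' @slot cellId character(1).
#' @slot somaPosition numeric(1), um from the midline.
#' @slot kernelHalfwidth numeric(1), um (0 means unsmoothed).
#'
#' @seealso [toPattern()], [patternCorrelation()]
#' @exportClass MediolateralPattern
setClass("MediolateralPattern",
  representation(
    positions = "numeric",
    values = "numeric",
    cellId = "character",
    somaPosition = "numeric",
    kernelHalfwidth = "numeric"
  )
)

setValidity("MediolateralPattern", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "'positions' and 'values' must have equal length")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Standardized zebrin-band coordinate frame
#'
#' Ordered widths, in um from the midline, of the aldolase-C (zebrin II)
#' bands used as the common mediolateral coordinate system across animals.
#'
#' @slot widths named numeric, band widths in um ordered from the midline.
#'
#' @seealso [bandFrame()], [registerPosition()]
#' @exportClass BandCoordinateFrame
setClass("BandCoordinateFrame", representation(widths = "numeric"))

setValidity("BandCoordinateFrame", function(object) {
  msg <- character()
  if (is.null(names(object@widths)) || any(!nzchar(names(object@widths))))
    msg <- c(msg, "'widths' must be named by band")
  if (any(object@widths <= 0))
    msg <- c(msg, "band widths must be > 0")
  if (length(msg)) msg else TRUE
})

#' Sliding-window median pattern group
#'
#' The median granule-cell input pattern of all cells whose somata fall in a
#' 100 um mediolateral window, with its per-position dispersion.
#'
#' @slot center numeric(1), window center in um from the midline.
#' @slot width numeric(1), window width in um.
#' @slot members character, ids of the member cells.
#' @slot pattern the elementwise-median [MediolateralPattern-class].
#' @slot dispersion numeric, per-position median absolute deviation.
#'
#' @seealso [medianPatterns()]
#' @exportClass MedianPatternGroup
setClass("MedianPatternGroup",
  representation(
    center = "numeric",
    width = "numeric",
    members = "character",
    pattern = "MediolateralPattern",
    dispersion = "numeric"
  )
)

setValidity("MedianPatternGroup", function(object) {
  if (length(object@members) < 1L) "group must have >= 1 member" else TRUE
})

#' Pairwise Pearson correlation of median patterns
#'
#' @slot r square numeric matrix of Pearson coefficients (NA where a
#'   correlation is undefined).
#' @slot centers numeric, window center of each group, used as axis labels.
#'
#' @seealso [correlationMatrix()], [spectralCocluster()]
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(r = "matrix", centers = "numeric")
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "'r' must be square")
  else {
    if (length(object@centers) != nrow(r))
      msg <- c(msg, "'centers' must match the matrix dimension")
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8, check.attributes = FALSE)))
      msg <- c(msg, "'r' must be symmetric")
    finite <- r[is.finite(r)]
    if (length(finite) && (max(finite) > 1 + 1e-8 || min(finite) < -1 - 1e-8))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    d <- diag(r)
    if (any(is.finite(d) & abs(d - 1) > 1e-8))
      msg <- c(msg, "diagonal must be 1 where defined")
  }
  if (length(msg)) msg else TRUE
})

#' Co-clustering assignment of median-pattern groups
#'
#' @slot clusters integer, one cluster id per group.
#' @slot k integer(1), number of clusters.
#' @slot contiguous logical, per cluster: whether its groups occupy a
#'   contiguous run along the mediolateral position axis.
#' @slot centers numeric, group window centers (position axis).
#'
#' @seealso [spectralCocluster()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(
    clusters = "integer",
    k = "integer",
    contiguous = "logical",
    centers = "numeric"
  )
)

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (anyNA(object@clusters))
    msg <- c(msg, "every group must be assigned exactly one cluster")
  if (length(object@contiguous) != object@k)
    msg <- c(msg, "'contiguous' must have one flag per cluster")
  if (length(msg)) msg else TRUE
})

#' Site-by-site plasticity comparison of a pre/post map pair
#'
#' @slot sites data.frame: \code{site}, \code{ml_um}, \code{depth_row},
#'   \code{z_pre}, \code{z_post}, \code{delta_z}, \code{class} (one of
#'   \code{potentiated}, \code{depressed}, \code{awakened},
#'   \code{unchanged}; awakened sites are a refinement of potentiated).
#' @slot slope numeric(1), OLS slope of delta-Z against the initial Z.
#' @slot r numeric(1), Pearson r of that regression.
#' @slot threshold numeric(1), the |delta-Z| significance threshold used.
#'
#' @seealso [comparePlasticity()], [classifyChanges()]
#' @exportClass PlasticityResult
setClass("PlasticityResult",
  representation(
    sites = "data.frame",
    slope = "numeric",
    r = "numeric",
    threshold = "numeric"
  )
)

setValidity("PlasticityResult", function(object) {
  msg <- character()
  cls <- object@sites$class
  ok <- c("potentiated", "depressed", "awakened", "unchanged")
  if (!all(cls %in% ok))
    msg <- c(msg, paste("site classes must be one of:",
                        paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A complete experiment: cells, traces, and derived products
#'
#' @slot cells data.frame of per-cell metadata (\code{cell_id}, \code{type},
#'   \code{band}, \code{soma_um}).
#' @slot recordings named list of [CellRecording-class].
#' @slot derived named list of derived products (maps, patterns, groups,
#'   correlation matrix, clusters, plasticity).
#' @slot provenance list: config used, root seed, schema/tool versions.
#'
#' @seealso [runPipeline()], [writeBundle()], [readBundle()]
#' @exportClass ExperimentBundle
setClass("ExperimentBundle",
  representation(
    cells = "data.frame",
    recordings = "list",
    derived = "list",
    provenance = "list"
  )
)

setValidity("ExperimentBundle", function(object) {
  msg <- character()
  if (length(object@recordings) &&
      !all(vapply(object@recordings, is, logical(1), "CellRecording")))
    msg <- c(msg, "'recordings' must all be CellRecording objects")
  if (length(object@recordings) && nrow(object@cells) &&
      !setequal(names(object@recordings), object@cells$cell_id))
    msg <- c(msg, "'recordings' names must match cells$cell_id")
  if (length(msg)) msg else TRUE
})
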