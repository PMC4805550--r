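# Per-site Z-scores, significance classification, and 1-d mediolateral
# input patterns.

#' The default per-site significance threshold
#'
#' One-sided standard-normal quantile at significance level
#' \code{alpha = 0.001}; rounds to 3.09, the fixed per-site threshold
#' separating significant (connected) from silent sites.
#'
#' @param alpha one-sided significance level.
#' @param digits rounding applied to the quantile.
#' @return numeric threshold.
#' @examples
#' significanceThreshold()  # 3.09
#' @export
significanceThreshold <- function(alpha = 0.001, digits = 2) {
  round(stats::qnorm(1 - alpha), digits)
}

#' Standardize a site's mean evoked charge against the cell's noise
#'
#' \code{Z = (mean evoked charge - mean noise charge) / SD of noise charge},
#' making maps comparable across cells with different background noise.
#'
#' @param meanCharge mean synaptic charge at the site, pC (vectorized).
#' @param noise a [NoiseModel-class].
#' @return dimensionless Z (same length as \code{meanCharge}).
#' @export
siteZscore <- function(meanCharge, noise) {
  stopifnot(is(noise, "NoiseModel"))
  if (noise@sigmaQ <= 0)
    stop("degenerate noise: sigmaQ must be > 0", call. = FALSE)
  (meanCharge - noise@muQ) / noise@sigmaQ
}

#' Event-count Z-score for interneuron maps
#'
#' For molecular-layer interneurons the connectivity statistic is the number
#' of individual EPSCs in the response window, standardized against the
#' event counts of a distant control window:
#' \code{Z = (mean response count - mean control count) / SD of control
#' counts}.
#'
#' @param responseCounts EPSC counts per trial in the response window.
#' @param controlCounts EPSC counts per trial in the control window.
#' @return dimensionless Z.
#' @export
countZscore <- function(responseCounts, controlCounts) {
  if (length(controlCounts) < 2L)
    stop("need >= 2 control trials", call. = FALSE)
  s <- stats::sd(controlCounts)
  if (s == 0)
    stop("degenerate control: zero SD of control event counts", call. = FALSE)
  (mean(responseCounts) - mean(controlCounts)) / s
}

#' Build the connectivity map of one cell
#'
#' Runs the per-site statistics over all sweeps of a cell: for
#' \code{statistic = "charge"}, the mean baseline-subtracted inward charge
#' in the 200 ms response window per site, standardized by the cell's
#' pooled noise-charge model; for \code{statistic = "events"}, matched-filter
#' EPSC counts in the response window standardized against terminal-window
#' counts pooled over the cell.
#'
#' @param rec a [CellRecording-class].
#' @param statistic \code{"charge"} (default) or \code{"events"}.
#' @param noise optionally, a precomputed [NoiseModel-class] (e.g. pooled
#'   over a pre/post pair); for \code{"charge"} only.
#' @param removeDC apply [removeDirectCurrent()] to every sweep first (used
#'   for Golgi-cell maps contaminated by slow direct currents).
#' @param responseWindowMs response-window length, ms.
#' @param ... passed to [detectEvents()] for \code{"events"}.
#' @return a [ConnectivityMap-class].
#' @export
computeMap <- function(rec, statistic = c("charge", "events"), noise = NULL,
                       removeDC = FALSE, responseWindowMs = 200, ...) {
  stopifnot(is(rec, "CellRecording"))
  statistic <- match.arg(statistic)
  d <- dim(rec@traces)
  nSite <- d[1]; nTrial <- d[2]; nSamp <- d[3]
  mat <- matrix(aperm(rec@traces, c(3, 1, 2)), nrow = nSite * nTrial,
                byrow = TRUE)  # rows ordered site-major within trial blocks
  if (removeDC) {
    for (i in seq_len(nrow(mat)))
      mat[i, ] <- removeDirectCurrent(mat[i, ], dt = rec@dt)
  }
  dur <- nSamp * rec@dt
  if (statistic == "charge") {
    q <- .windowCharges(mat, rec@dt, rec@stimOnset, rec@stimOnset,
                        responseWindowMs)
    qMat <- matrix(q, nrow = nSite)           # site x trial
    if (is.null(noise))
      noise <- estimateNoise(mat, dt = rec@dt, stimOnset = rec@stimOnset)
    meanQ <- rowMeans(qMat)
    z <- siteZscore(meanQ, noise)
  } else {
    counts <- function(from, to) {
      apply(mat, 1, function(x) {
        ev <- detectEvents(x, dt = rec@dt, ...)
        sum(ev$time_ms >= from & ev$time_ms < to)
      })
    }
    resp <- counts(rec@stimOnset, rec@stimOnset + responseWindowMs)
    ctrl <- counts(dur - responseWindowMs, dur)
    if (stats::sd(ctrl) == 0)
      stop("degenerate control: zero SD of control event counts",
           call. = FALSE)
    respMat <- matrix(resp, nrow = nSite)
    z <- (rowMeans(respMat) - mean(ctrl)) / stats::sd(ctrl)
    meanQ <- rowMeans(respMat)
    noise <- new("NoiseModel", muQ = mean(ctrl), sigmaQ = stats::sd(ctrl),
                 nSamples = length(ctrl))
  }
  sites <- rec@sites
  sites$mean_charge_pC <- meanQ
  sites$z <- z
  sites$n_trials <- nTrial
  new("ConnectivityMap", cellId = rec@cellId, sites = sites, noise = noise,
      geometry = rec@geometry, statistic = statistic)
}

#' @rdname siteTable
#' @export
setMethod("siteTable", "ConnectivityMap", function(x) x@sites)

#' Site table and Z-score accessors
#'
#' @param x a [ConnectivityMap-class].
#' @return \code{siteTable}: the per-site data.frame; \code{zScores}: the
#'   per-site Z vector.
#' @name siteTable
NULL

#' @rdname zScores
#' @export
setMethod("zScores", "ConnectivityMap", function(x) x@sites$z)

#' @rdname zScores
#' @name zScores
#' @param x a [ConnectivityMap-class].
NULL

#' Classify sites as significant or silent
#'
#' A site is significant iff its Z-score strictly exceeds the threshold.
#' With \code{perPosition = TRUE} the classification is reported per
#' mediolateral position: a position is silent iff no depth row at that
#' position is significant.
#'
#' @param map a [ConnectivityMap-class] (or a numeric Z vector).
#' @param threshold significance threshold (default
#'   [significanceThreshold()], 3.09, i.e. p = 0.001).
#' @param perPosition collapse depth rows per mediolateral position.
#' @param ... unused.
#' @return factor of \code{"significant"}/\code{"silent"} per site, or, for
#'   \code{perPosition}, a data.frame of \code{ml_um} and \code{label}.
#' @export
setMethod("classifySites", "ConnectivityMap",
  function(map, threshold = significanceThreshold(), perPosition = FALSE,
           ...) {
    stopifnot(threshold > 0)
    lab <- classifySites(map@sites$z, threshold = threshold)
    if (!perPosition) return(lab)
    sig <- tapply(lab == "significant", map@sites$ml_um, any)
    data.frame(ml_um = as.numeric(names(sig)),
               label = factor(ifelse(sig, "significant", "silent"),
                              levels = c("significant", "silent")),
               row.names = NULL)
  })

#' @rdname classifySites
#' @export
setMethod("classifySites", "numeric",
  function(map, threshold = significanceThreshold(), ...) {
    stopifnot(threshold > 0)
    factor(ifelse(map > threshold, "significant", "silent"),
           levels = c("significant", "silent"))
  })

#' Depth-maximum projection of a map
#'
#' Granule cells at all depths of a mediolateral position project through
#' the same parallel-fiber beam, so positions are pooled by taking, at each
#' mediolateral coordinate, the maximum Z-score over depth rows.
#'
#' @param map a [ConnectivityMap-class].
#' @return data.frame with \code{ml_um} and \code{z}, ordered by position.
#' @export
setMethod("maxProject", "ConnectivityMap", function(map) {
  z <- tapply(map@sites$z, map@sites$ml_um, max)
  data.frame(ml_um = as.numeric(names(z)), z = as.numeric(z),
             row.names = NULL)
})

#' Build the smoothed 1-d mediolateral input pattern
#'
#' Depth-maximum Z values are placed at their midline coordinates, linearly
#' interpolated onto a regular 1 um support, and convolved with a unit-mass
#' triangular kernel (half-width 18 um; renormalized over its in-range
#' support at the edges). The dense support is needed because an 18 um
#' kernel cannot act on the 41.5 um site lattice directly.
#'
#' @param x a [ConnectivityMap-class], or a data.frame with \code{ml_um}
#'   and \code{z} (e.g. from [maxProject()]).
#' @param kernelHalfwidth triangular-kernel half-width, um (0 skips
#'   smoothing).
#' @param cellId,somaPosition provenance for the data.frame method.
#' @param ... unused.
#' @return a [MediolateralPattern-class].
#' @export
setMethod("toPattern", "ConnectivityMap",
  function(x, kernelHalfwidth = 18, ...) {
    toPattern(maxProject(x), kernelHalfwidth = kernelHalfwidth,
              cellId = x@cellId, somaPosition = x@geometry@midlineOffset)
  })

#' @rdname toPattern
#' @export
setMethod("toPattern", "data.frame",
  function(x, kernelHalfwidth = 18, cellId = NA_character_,
           somaPosition = NA_real_, ...) {
    stopifnot(all(c("ml_um", "z") %in% names(x)), kernelHalfwidth >= 0)
    x <- x[order(x$ml_um), ]
    support <- seq(ceiling(min(x$ml_um)), floor(max(x$ml_um)), by = 1)
    v <- .resampleLinear(x$ml_um, x$z, support)
    v <- .triSmooth(v, spacing = 1, halfwidthUm = kernelHalfwidth)
    new("MediolateralPattern", positions = support, values = v,
        cellId = as.character(cellId), somaPosition = somaPosition,
        kernelHalfwidth = kernelHalfwidth)
  })

#' @rdname pattern-accessors
#' @export
setMethod("patternPositions", "MediolateralPattern", function(x) x@positions)

#' @rdname pattern-accessors
#' @export
setMethod("patternValues", "MediolateralPattern", function(x) x@values)

setMethod("show", "ConnectivityMap", function(object) {
  sig <- sum(object@sites$z > significanceThreshold())
  cat(sprintf("ConnectivityMap of %s (%s statistic): %d sites, %d significant (Z > %.2f)\n",
              object@cellId, object@statistic, nrow(object@sites), sig,
              significanceThreshold()))
  cat(sprintf("  noise: mu = %.3g pC, sigma = %.3g pC (n = %d)\n",
              object@noise@muQ, object@noise@sigmaQ, object@noise@nSamples))
})

setMethod("show", "MediolateralPattern", function(object) {
  cat(sprintf("MediolateralPattern of %s: [%g, %g] um, peak Z = %.2f at %g um (kernel %g um)\n",
              object@cellId, min(object@positions), max(object@positions),
              max(object@values),
              object@positions[which.max(object@values)],
              object@kernelHalfwidth))
})
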