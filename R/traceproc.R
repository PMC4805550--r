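# Trace-level processing: charge integration, noise modelling,
# direct-current removal, EPSC event detection.

# Vectorized core: rows of `mat` are sweeps of one cell (pA). Returns the
# baseline-subtracted inward charge (pC) over [start, start+len) per row.
# Baseline is the mean current over the `baselineLenMs` preceding stimulus
# onset (capped at the available pre-stimulus time); inward (negative)
# current yields positive charge so stronger responses score higher.
.windowCharges <- function(mat, dt, stimOnset, start, len = 200,
                           baselineLenMs = 50) {
  n <- ncol(mat)
  idx <- .windowIdx(n, dt, start, len)
  bLen <- min(baselineLenMs, stimOnset)
  if (bLen > 0) {
    bidx <- .windowIdx(n, dt, stimOnset - bLen, bLen)
    base <- rowMeans(mat[, bidx, drop = FALSE])
  } else {
    base <- 0
  }
  -(rowSums(mat[, idx, drop = FALSE]) - length(idx) * base) * dt / 1000
}

#' Integrate evoked synaptic charge
#'
#' Computes the baseline-subtracted integral of current over an analysis
#' window, reported as the magnitude of inward (excitatory) charge in pC.
#' The baseline is the mean current over the 50 ms preceding stimulus onset.
#' The default window length of 200 ms matches the response window used for
#' evoked charges and the terminal window used for the noise model.
#'
#' @param trace a [PhotostimTrace-class], or a numeric vector of currents in
#'   pA (then \code{dt} and \code{stimOnset} must be given).
#' @param windowStart window start in ms (defaults to stimulus onset).
#' @param windowLen window length in ms.
#' @param baselineLenMs length of the pre-stimulus baseline window, ms.
#' @param dt,stimOnset sampling metadata for the numeric method.
#' @param ... unused.
#' @return charge in pC (positive for net inward current).
#' @examples
#' tr <- photostimTrace(rep(0, 20000), dt = 0.05, stimOnset = 200)
#' integrateCharge(tr)  # 0
#' @export
setMethod("integrateCharge", "PhotostimTrace",
  function(trace, windowStart = trace@stimOnset, windowLen = 200,
           baselineLenMs = 50, ...) {
    .windowCharges(matrix(trace@samples, nrow = 1), trace@dt,
                   trace@stimOnset, windowStart, windowLen,
                   baselineLenMs)[1L]
  })

#' @rdname integrateCharge
#' @export
setMethod("integrateCharge", "numeric",
  function(trace, dt, stimOnset, windowStart = stimOnset, windowLen = 200,
           baselineLenMs = 50, ...) {
    .windowCharges(matrix(trace, nrow = 1), dt, stimOnset, windowStart,
                   windowLen, baselineLenMs)[1L]
  })

.noiseFromCharges <- function(q) {
  if (length(q) < 2L)
    stop("need >= 2 traces to build a noise model", call. = FALSE)
  s <- stats::sd(q)
  if (s == 0)
    stop("degenerate noise: zero charge variance across noise windows; ",
         "Z-scores would be undefined", call. = FALSE)
  new("NoiseModel", muQ = mean(q), sigmaQ = s, nSamples = length(q))
}

#' Build the per-cell noise-charge model
#'
#' Applies the same baseline-subtracted charge integral used for responses
#' to the terminal 200 ms window of every sweep of a cell, pools the
#' resulting charges, and summarizes them by their mean and standard
#' deviation. Z-scores standardize evoked charges against this model.
#'
#' @param traces a list of [PhotostimTrace-class], a numeric matrix with one
#'   sweep per row (then give \code{dt} and \code{stimOnset}), or a
#'   [CellRecording-class].
#' @param noiseWindowMs length of the terminal noise window, ms.
#' @param dt,stimOnset sampling metadata for the matrix method.
#' @param ... unused.
#' @return a [NoiseModel-class].
#' @export
setMethod("estimateNoise", "list",
  function(traces, noiseWindowMs = 200, ...) {
    q <- vapply(traces, function(tr) {
      dur <- length(tr@samples) * tr@dt
      integrateCharge(tr, windowStart = dur - noiseWindowMs,
                      windowLen = noiseWindowMs)
    }, numeric(1))
    .noiseFromCharges(q)
  })

#' @rdname estimateNoise
#' @export
setMethod("estimateNoise", "matrix",
  function(traces, dt, stimOnset, noiseWindowMs = 200, ...) {
    dur <- ncol(traces) * dt
    q <- .windowCharges(traces, dt, stimOnset, dur - noiseWindowMs,
                        noiseWindowMs)
    .noiseFromCharges(q)
  })

#' @rdname estimateNoise
#' @export
setMethod("estimateNoise", "CellRecording",
  function(traces, noiseWindowMs = 200, ...) {
    d <- dim(traces@traces)
    mat <- matrix(aperm(traces@traces, c(3, 1, 2)),
                  nrow = d[1] * d[2], byrow = TRUE)
    estimateNoise(mat, dt = traces@dt, stimOnset = traces@stimOnset,
                  noiseWindowMs = noiseWindowMs)
  })

#' Remove the slow direct current from a sweep
#'
#' Direct somatodendritic stimulation (seen when mapping Golgi cells)
#' superimposes a slow current on the fast evoked EPSCs. The slow
#' component is estimated by a running median and subtracted; the trace's
#' overall mean level is retained, so a flat sweep passes through
#' unchanged.
#'
#' A plain running median partially tracks fast inward deflections and
#' removes part of their charge, so the estimator is made event-aware
#' first: inward transients are located as excursions below the trace's
#' morphological closing (running maximum then minimum over
#' \code{closingMs}, an upper envelope immune to inward events), each
#' detected stretch is extended over the EPSC tail and bridged by linear
#' interpolation between flanking local medians, and the running median of
#' that bridged trace is the slow-current estimate. Errors are bounded by
#' the artifact's curvature over a bridge, not its slope, and single
#' events well inside the response window are recovered to a few percent
#' of their charge; densely overlapping trains on a fast-curving artifact
#' remain partially confounded (no single-trace method can separate them).
#'
#' @param trace a [PhotostimTrace-class] or numeric vector.
#' @param medianWindowMs running-median window for the slow-current
#'   estimate, ms; longer than any EPSC, much shorter than the slow
#'   current's time scale.
#' @param closingMs closing window, ms; wider than a single EPSC (~40 ms
#'   at 2% of peak for a 10 ms decay).
#' @param eventMaskSigma detection threshold for masking, in robust SDs of
#'   the below-envelope excursion.
#' @param maskBackMs,maskFwdMs extension of each masked stretch, ms
#'   (forward covers the EPSC decay tail).
#' @param anchorMs length of the flanking segments whose medians anchor
#'   each bridge, ms.
#' @param dt sampling interval for the numeric method, ms.
#' @param ... unused.
#' @return the filtered trace, same class as the input.
#' @export
setMethod("removeDirectCurrent", "PhotostimTrace",
  function(trace, medianWindowMs = 101, closingMs = 61,
           eventMaskSigma = 6, maskBackMs = 5, maskFwdMs = 35,
           anchorMs = 15, ...) {
    out <- trace
    out@samples <- removeDirectCurrent(trace@samples,
      medianWindowMs = medianWindowMs, closingMs = closingMs,
      eventMaskSigma = eventMaskSigma, maskBackMs = maskBackMs,
      maskFwdMs = maskFwdMs, anchorMs = anchorMs, dt = trace@dt)
    out
  })

#' @rdname removeDirectCurrent
#' @export
setMethod("removeDirectCurrent", "numeric",
  function(trace, medianWindowMs = 101, closingMs = 61,
           eventMaskSigma = 6, maskBackMs = 5, maskFwdMs = 35,
           anchorMs = 15, dt, ...) {
    if (medianWindowMs <= 0) stop("'medianWindowMs' must be > 0")
    n <- length(trace)
    oddCap <- function(k) {
      if (k %% 2 == 0) k <- k + 1
      min(k, if (n %% 2 == 1) n else n - 1)
    }
    kc <- oddCap(round(closingMs / dt))
    km <- oddCap(round(medianWindowMs / dt))
    if (km < 3 || kc < 3) return(trace)
    env <- zoo::rollmax(trace, kc, fill = "extend")    # dilation
    env <- -zoo::rollmax(-env, kc, fill = "extend")    # erosion
    resid <- trace - env
    # absolute floor keeps the threshold meaningful on noise-free input
    scale <- max(stats::mad(resid), 0.05 * max(abs(resid)))
    bridged <- trace
    if (scale > 0) {
      bad <- resid < -eventMaskSigma * scale
      if (any(bad)) {
        r <- rle(bad)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        back <- round(maskBackMs / dt); fwd <- round(maskFwdMs / dt)
        anc <- max(1L, round(anchorMs / dt))
        mask <- logical(n)
        for (k in which(r$values))
          mask[max(1, starts[k] - back):min(n, ends[k] + fwd)] <- TRUE
        r2 <- rle(mask)
        e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1
        for (k in which(r2$values)) {
          a <- s2[k]; b <- e2[k]
          la <- if (a > 1)
            stats::median(trace[max(1, a - anc):(a - 1)]) else NA_real_
          lb <- if (b < n)
            stats::median(trace[(b + 1):min(n, b + anc)]) else NA_real_
          if (is.na(la)) la <- lb
          if (is.na(lb)) lb <- la
          bridged[a:b] <- la + (lb - la) *
            (seq_len(b - a + 1) - 1) / max(1, b - a)
        }
      }
    }
    slow <- as.numeric(stats::runmed(bridged, km, endrule = "median"))
    trace - slow + mean(slow)
  })

# unit-norm EPSC matched-filter template (difference of exponentials)
.epscTemplate <- function(dt, riseMs, decayMs) {
  t <- seq(0, riseMs + 5 * decayMs, by = dt)
  k <- exp(-t / decayMs) - exp(-t / riseMs)
  k / sqrt(sum(k^2))
}

#' Detect individual EPSCs by matched filtering
#'
#' Correlates the (sign-flipped, so EPSCs are positive) sweep with a
#' difference-of-exponentials EPSC template and marks local maxima of the
#' filter output exceeding \code{thresholdFactor} times its robust noise
#' scale (median absolute deviation). Used for event-count connectivity
#' statistics in molecular-layer interneurons.
#'
#' @param trace a [PhotostimTrace-class] or numeric vector (pA).
#' @param riseMs,decayMs template kinetics, ms.
#' @param thresholdFactor detection threshold in robust SDs of the filtered
#'   trace.
#' @param minSeparationMs minimal separation between events, ms.
#' @param dt sampling interval for the numeric method, ms.
#' @param ... unused.
#' @return data.frame with \code{time_ms} (event onset, strictly
#'   increasing) and \code{amplitude_pA} (peak inward amplitude, positive).
#' @export
setMethod("detectEvents", "PhotostimTrace",
  function(trace, riseMs = 1, decayMs = 10, thresholdFactor = 5,
           minSeparationMs = 5, ...) {
    detectEvents(trace@samples, dt = trace@dt, riseMs = riseMs,
                 decayMs = decayMs, thresholdFactor = thresholdFactor,
                 minSeparationMs = minSeparationMs)
  })

#' @rdname detectEvents
#' @export
setMethod("detectEvents", "numeric",
  function(trace, dt, riseMs = 1, decayMs = 10, thresholdFactor = 5,
           minSeparationMs = 5, ...) {
    if (thresholdFactor <= 0) stop("'thresholdFactor' must be > 0")
    k <- .epscTemplate(dt, riseMs, decayMs)
    n <- length(trace)
    if (length(k) > n)
      stop("EPSC template is longer than the trace", call. = FALSE)
    s <- -(trace - stats::median(trace))
    # score[i] = correlation of the template with the segment starting at i
    f <- stats::filter(c(s, numeric(length(k) - 1)), rev(k), sides = 1)
    score <- as.numeric(f)[seq.int(length(k), length(k) + n - 1)]
    thr <- thresholdFactor * stats::mad(score)
    if (thr == 0) return(data.frame(time_ms = numeric(), amplitude_pA = numeric()))
    isPeak <- score > thr &
      score >= c(-Inf, score[-n]) & score >= c(score[-1], -Inf)
    cand <- which(isPeak)
    if (!length(cand)) return(data.frame(time_ms = numeric(), amplitude_pA = numeric()))
    # greedy non-maximum suppression within the refractory distance
    minSep <- max(1L, round(minSeparationMs / dt))
    cand <- cand[order(score[cand], decreasing = TRUE)]
    kept <- integer()
    for (i in cand) {
      if (!length(kept) || all(abs(kept - i) >= minSep)) kept <- c(kept, i)
    }
    kept <- sort(kept)
    amp <- vapply(kept, function(i) {
      seg <- seq.int(i, min(n, i + round((riseMs + 2 * decayMs) / dt)))
      max(s[seg])
    }, numeric(1))
    data.frame(time_ms = (kept - 1) * dt, amplitude_pA = amp)
  })

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: mu = %.4g pC, sigma = %.4g pC (n = %d windows)\n",
              object@muQ, object@sigmaQ, object@nSamples))
})

#' @rdname noiseModel
#' @export
setMethod("noiseModel", "ConnectivityMap", function(x) x@noise)

#' Noise-model accessors
#'
#' @param x a [NoiseModel-class] (or an object carrying one).
#' @return \code{noiseMean}/\code{noiseSd}: the mean and SD of the pooled
#'   noise-charge distribution, pC.
#' @name noiseModel
#' @export
noiseMean <- function(x) {
  if (is(x, "ConnectivityMap")) x <- x@noise
  x@muQ
}

#' @rdname noiseModel
#' @export
noiseSd <- function(x) {
  if (is(x, "ConnectivityMap")) x <- x@noise
  x@sigmaQ
}
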