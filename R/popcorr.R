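# Population-level comparison of input patterns: band registration,
# pairwise correlation with a shuffled null, sliding-window median
# patterns, the correlation matrix, spectral co-clustering, and the
# soma-centered control.

#' Standardized zebrin-band coordinate frame
#'
#' Average widths of the aldolase-C (zebrin II) bands of lobule III/IV,
#' ordered from the midline: P1+ 48.5 um, P1- 275.6 um, P2+ 64.6 um,
#' P2- 445.2 um. Cells recorded in different animals are positioned inside
#' this common frame so their patterns can be compared.
#'
#' @param widths named numeric of band widths in um, ordered from the
#'   midline.
#' @return a [BandCoordinateFrame-class].
#' @export
bandFrame <- function(widths = c("P1+" = 48.5, "P1-" = 275.6,
                                 "P2+" = 64.6, "P2-" = 445.2)) {
  new("BandCoordinateFrame", widths = widths)
}

#' Register a cell position into the standard band frame
#'
#' A cell whose soma sits at a relative \code{fraction} of its (animal-
#' specific) band is placed at the same fraction of the standard band:
#' the returned coordinate is the cumulative width of the preceding bands
#' plus \code{fraction} times the standard width of the cell's band.
#'
#' @param band band identity of the cell (e.g. \code{"P2+"}); vectorized.
#' @param fraction relative position within the band, 0 (medial edge) to 1
#'   (lateral edge).
#' @param frame a [BandCoordinateFrame-class].
#' @return standardized um-from-midline coordinate(s).
#' @examples
#' registerPosition("P1+", 0)    # midline: 0
#' registerPosition("P1+", 1)    # P1+/P1- boundary: 48.5
#' registerPosition("P2+", 0.5)  # center of P2+: 356.4
#' @export
registerPosition <- function(band, fraction = 0.5, frame = bandFrame()) {
  stopifnot(is(frame, "BandCoordinateFrame"))
  i <- match(band, names(frame@widths))
  if (anyNA(i))
    stop("unknown band(s): ",
         paste(unique(band[is.na(i)]), collapse = ", "), call. = FALSE)
  cum <- cumsum(c(0, frame@widths))
  unname(cum[i] + fraction * frame@widths[i])
}

#' Map a measured position into the standard band frame
#'
#' Converts a coordinate measured against an animal's own band boundaries
#' into the standard frame, proportionally within its band.
#'
#' @param positionUm measured um-from-midline coordinate(s).
#' @param measured a [BandCoordinateFrame-class] holding the animal's own
#'   band widths.
#' @param frame the standard [BandCoordinateFrame-class].
#' @return standardized coordinate(s).
#' @export
mapMeasuredPosition <- function(positionUm, measured, frame = bandFrame()) {
  stopifnot(is(measured, "BandCoordinateFrame"))
  cumM <- cumsum(c(0, measured@widths))
  vapply(positionUm, function(p) {
    i <- findInterval(p, cumM, rightmost.closed = TRUE)
    if (i < 1 || i > length(measured@widths))
      stop("position ", p, " um lies outside the measured bands",
           call. = FALSE)
    frac <- (p - cumM[i]) / measured@widths[i]
    registerPosition(names(measured@widths)[i], frac, frame)
  }, numeric(1))
}

#' Pearson correlation between two input patterns
#'
#' Patterns are resampled onto the intersection of their mediolateral
#' ranges at a common 10 um resolution and compared position by position
#' with the Pearson coefficient.
#'
#' @param p1,p2 [MediolateralPattern-class] objects, or plain numeric
#'   vectors of equal length.
#' @param by resampling step for the common support, um.
#' @param ... unused.
#' @return Pearson r.
#' @export
setMethod("patternCorrelation",
  signature(p1 = "MediolateralPattern", p2 = "MediolateralPattern"),
  function(p1, p2, by = 10, ...) {
    s <- .commonSupport(p1, p2, by)
    x <- .resampleLinear(p1@positions, p1@values, s)
    y <- .resampleLinear(p2@positions, p2@values, s)
    .pearson(x, y)
  })

#' @rdname patternCorrelation
#' @export
setMethod("patternCorrelation",
  signature(p1 = "numeric", p2 = "numeric"),
  function(p1, p2, ...) {
    stopifnot(length(p1) == length(p2))
    .pearson(p1, p2)
  })

#' Shuffled-pair null distribution of pattern correlations
#'
#' Correlations between true neighboring-cell pairs are benchmarked against
#' random re-pairings. Each shuffle round draws a random pairing of the
#' cells without replacement, excludes self-pairs and any pair listed as
#' true neighbors, and records the Pearson r of every remaining pair.
#'
#' @param patterns list of [MediolateralPattern-class], one per cell.
#' @param nShuffles number of shuffle rounds.
#' @param seed integer seed (mandatory).
#' @param neighbors optional 2-column matrix of cell-index pairs to
#'   exclude (the true neighbor pairs).
#' @param by resampling step passed to [patternCorrelation()].
#' @return numeric vector of shuffled-pair r values.
#' @export
shuffleNull <- function(patterns, nShuffles = 100, seed, neighbors = NULL,
                        by = 10) {
  seed <- .requireSeed(seed)
  n <- length(patterns)
  if (n < 3L) stop("need >= 3 cells for a shuffled null", call. = FALSE)
  excl <- character()
  if (!is.null(neighbors)) {
    excl <- apply(neighbors, 1, function(p)
      paste(sort(p), collapse = "-"))
  }
  set.seed(seed)
  rs <- numeric()
  for (b in seq_len(nShuffles)) {
    perm <- sample(n)
    i1 <- perm[seq(1, n - 1, by = 2)]
    i2 <- perm[seq(2, n, by = 2)]
    for (j in seq_along(i1)) {
      key <- paste(sort(c(i1[j], i2[j])), collapse = "-")
      if (key %in% excl) next
      rs <- c(rs, patternCorrelation(patterns[[i1[j]]], patterns[[i2[j]]],
                                     by = by))
    }
  }
  rs
}

#' Sliding-window median patterns of a registered population
#'
#' Cells are grouped by a 100 um mediolateral window slid in 10 um steps
#' over their registered soma positions; each group's representative is the
#' position-wise median of its members' smoothed patterns (on the
#' intersection of their supports), with the median absolute deviation as
#' dispersion. Windows with fewer than \code{minMembers} cells (or no
#' overlapping support) are skipped.
#'
#' @param patterns list of [MediolateralPattern-class].
#' @param somaPositions registered soma positions (um), one per pattern;
#'   defaults to the patterns' own \code{somaPosition}.
#' @param windowUm group window width.
#' @param shiftUm shift between consecutive windows.
#' @param minMembers minimal group size.
#' @return list of [MedianPatternGroup-class].
#' @export
medianPatterns <- function(patterns, somaPositions = NULL, windowUm = 100,
                           shiftUm = 10, minMembers = 1) {
  if (is.null(somaPositions))
    somaPositions <- vapply(patterns, function(p) p@somaPosition, numeric(1))
  stopifnot(length(patterns) >= 1, length(somaPositions) == length(patterns))
  centers <- seq(ceiling(min(somaPositions) / shiftUm) * shiftUm,
                 floor(max(somaPositions) / shiftUm) * shiftUm,
                 by = shiftUm)
  if (!length(centers)) centers <- mean(somaPositions)
  groups <- list()
  skipped <- 0L
  for (ct in centers) {
    mem <- which(abs(somaPositions - ct) <= windowUm / 2)
    if (length(mem) < minMembers) { skipped <- skipped + 1L; next }
    lo <- max(vapply(patterns[mem], function(p) min(p@positions), numeric(1)))
    hi <- min(vapply(patterns[mem], function(p) max(p@positions), numeric(1)))
    if (hi - lo < 1) { skipped <- skipped + 1L; next }
    support <- seq(ceiling(lo), floor(hi), by = 1)
    vals <- vapply(patterns[mem], function(p)
      .resampleLinear(p@positions, p@values, support),
      numeric(length(support)))
    vals <- matrix(vals, nrow = length(support))
    med <- apply(vals, 1, stats::median)
    disp <- apply(vals, 1, stats::mad)
    ids <- vapply(patterns[mem], function(p) p@cellId, character(1))
    pat <- new("MediolateralPattern", positions = support, values = med,
               cellId = sprintf("group@%g", ct), somaPosition = ct,
               kernelHalfwidth = patterns[[mem[1]]]@kernelHalfwidth)
    groups[[length(groups) + 1L]] <-
      new("MedianPatternGroup", center = ct, width = windowUm,
          members = ids, pattern = pat, dispersion = disp)
  }
  if (skipped)
    message(skipped, " window position(s) skipped (too few members or no ",
            "overlapping support)")
  groups
}

#' Correlation matrix of median-pattern groups
#'
#' Pearson correlation between each couple of group median patterns, with
#' group window centers as axis labels. Entries whose correlation is
#' undefined (zero-variance pattern or no overlap) are reported as NA,
#' never as 0.
#'
#' @param groups list of [MedianPatternGroup-class] (>= 2).
#' @param by resampling step for pairwise common supports, um.
#' @return a [CorrelationMatrix-class].
#' @export
correlationMatrix <- function(groups, by = 10) {
  n <- length(groups)
  if (n < 2L) stop("need >= 2 groups", call. = FALSE)
  r <- diag(nrow = n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      rij <- tryCatch(
        patternCorrelation(groups[[i]]@pattern, groups[[j]]@pattern, by = by),
        error = function(e) NA_real_)
      r[i, j] <- r[j, i] <- rij
    }
  }
  centers <- vapply(groups, function(g) g@center, numeric(1))
  dimnames(r) <- list(centers, centers)
  new("CorrelationMatrix", r = r, centers = centers)
}

#' Bipartite spectral co-clustering of a correlation matrix
#'
#' Implements spectral co-clustering by bipartite graph partitioning:
#' correlations are shifted to non-negative weights via \code{(r + 1) / 2},
#' the weight matrix is degree-normalized
#' (\code{D1^-1/2 A D2^-1/2}), the leading
#' \code{ceiling(log2(k))} non-trivial singular-vector pairs form a joint
#' row/column embedding, and k-means on that embedding yields the
#' partition. Rows and columns of a symmetric matrix receive identical
#' assignments. Each cluster is additionally checked for contiguity along
#' the mediolateral position axis.
#'
#' With \code{k = "auto"}, k is scanned over \code{kRange} and the value
#' maximizing (mean within-cluster r - mean between-cluster r) is kept.
#'
#' @param cm a [CorrelationMatrix-class] with no missing entries.
#' @param k number of biclusters (>= 2), or \code{"auto"}.
#' @param kRange candidate k values for \code{k = "auto"}.
#' @param seed seed for the k-means refinement.
#' @param nstart random restarts for k-means.
#' @return a [ClusterAssignment-class].
#' @export
spectralCocluster <- function(cm, k = 4, kRange = 2:8, seed = 1L,
                              nstart = 50) {
  stopifnot(is(cm, "CorrelationMatrix"))
  r <- cm@r
  if (anyNA(r))
    stop("correlation matrix has undefined entries; cannot co-cluster",
         call. = FALSE)
  n <- nrow(r)
  if (stats::sd(r) == 0)
    stop("degenerate structure: constant correlation matrix", call. = FALSE)
  if (identical(k, "auto")) {
    kRange <- kRange[kRange >= 2 & kRange < n]
    scores <- vapply(kRange, function(kk) {
      a <- spectralCocluster(cm, k = kk, seed = seed, nstart = nstart)
      .separationScore(r, a@clusters)
    }, numeric(1))
    k <- kRange[which.max(scores)]
  }
  k <- as.integer(k)
  if (k < 2 || k > n)
    stop("'k' must lie in [2, number of groups]", call. = FALSE)
  A <- (r + 1) / 2
  d1 <- rowSums(A); d2 <- colSums(A)
  if (any(d1 <= 0) || any(d2 <= 0))
    stop("degenerate structure: zero-degree row/column", call. = FALSE)
  An <- A / sqrt(d1 %o% d2)
  sv <- svd(An)
  l <- ceiling(log2(k))
  keep <- seq.int(2, min(l + 1, n))
  U <- sv$u[, keep, drop = FALSE] / sqrt(d1)
  V <- sv$v[, keep, drop = FALSE] / sqrt(d2)
  emb <- rbind(U, V)
  set.seed(as.integer(seed))
  km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100)
  rowCl <- km$cluster[seq_len(n)]
  # stable labels: clusters numbered by first appearance along the axis
  ord <- order(cm@centers)
  relabel <- match(rowCl, unique(rowCl[ord]))
  contiguous <- vapply(seq_len(k), function(cl) {
    idx <- which(relabel[ord] == cl)
    length(idx) > 0 && all(diff(idx) == 1)
  }, logical(1))
  new("ClusterAssignment", clusters = as.integer(relabel), k = k,
      contiguous = contiguous, centers = cm@centers)
}

# mean within-cluster r minus mean between-cluster r (off-diagonal only)
.separationScore <- function(r, clusters) {
  n <- nrow(r)
  same <- outer(clusters, clusters, "==") & upper.tri(r)
  diff <- !outer(clusters, clusters, "==") & upper.tri(r)
  if (!any(same) || !any(diff)) return(-Inf)
  mean(r[same]) - mean(r[diff])
}

#' @rdname clusterIds
#' @export
setMethod("clusterIds", "ClusterAssignment", function(x) x@clusters)

#' Cluster assignment accessor
#'
#' @param x a [ClusterAssignment-class].
#' @return integer cluster id per group.
#' @name clusterIds
NULL

#' Soma-centered mean input profile (control analysis)
#'
#' Tests whether population structure merely reflects each cell's local
#' input: every pattern is translated so its soma sits at 0, amplitude-
#' normalized to its own peak, and the profiles are averaged per offset. A
#' population with genuinely shared distal hotspots keeps them in midline
#' coordinates, so centering on somata must wash them out, leaving a single
#' central peak and no secondary peak.
#'
#' @param patterns list of [MediolateralPattern-class] with soma positions.
#' @param normalize divide each pattern by its own maximum absolute value.
#' @return a [MediolateralPattern-class] of mean normalized values over
#'   soma-relative offsets.
#' @export
centerOnSoma <- function(patterns, normalize = TRUE) {
  stopifnot(length(patterns) >= 1)
  offs <- lapply(patterns, function(p) p@positions - p@somaPosition)
  lo <- floor(min(vapply(offs, min, numeric(1))))
  hi <- ceiling(max(vapply(offs, max, numeric(1))))
  support <- seq(lo, hi, by = 1)
  acc <- matrix(NA_real_, nrow = length(support), ncol = length(patterns))
  for (i in seq_along(patterns)) {
    v <- patterns[[i]]@values
    if (normalize && max(abs(v)) > 0) v <- v / max(abs(v))
    o <- offs[[i]]
    inside <- support >= min(o) & support <= max(o)
    acc[inside, i] <- .resampleLinear(o, v, support[inside])
  }
  m <- rowMeans(acc, na.rm = TRUE)
  new("MediolateralPattern", positions = support, values = m,
      cellId = "soma-centered mean", somaPosition = 0,
      kernelHalfwidth = patterns[[1]]@kernelHalfwidth)
}

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d groups, centers %g..%g um, r in [%.2f, %.2f]\n",
              nrow(object@r), min(object@centers), max(object@centers),
              min(object@r, na.rm = TRUE), max(object@r, na.rm = TRUE)))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: k = %d over %d groups; contiguous: %s\n",
              object@k, length(object@clusters),
              paste(ifelse(object@contiguous, "yes", "no"), collapse = ", ")))
})

setMethod("show", "MedianPatternGroup", function(object) {
  cat(sprintf("MedianPatternGroup @ %g um (width %g): %d member(s)\n",
              object@center, object@width, length(object@members)))
})

setMethod("show", "BandCoordinateFrame", function(object) {
  b <- cumsum(object@widths)
  cat("BandCoordinateFrame:",
      paste(sprintf("%s [%g, %g]", names(object@widths),
                    c(0, b[-length(b)]), b), collapse = ", "), "um\n")
})
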