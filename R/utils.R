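# internal helpers shared across modules

# Deterministic hierarchical seed derivation: mixing a parent seed with an
# index path gives a child seed, so adding cells/sites/trials never perturbs
# streams already drawn. All arithmetic stays exact in doubles (< 2^53) and
# results stay below 2^31 - 1.
.childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (i in idx) {
    s <- (s * 69069 + (as.double(i) + 1) * 104729) %% 2147483629
  }
  as.integer(s)
}

.requireSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a 'seed' must be supplied explicitly (no silent nondeterminism)",
         call. = FALSE)
  as.integer(seed)
}

# indices of samples whose time (0-based, t = (i-1)*dt) falls in
# [start, start + len)
.windowIdx <- function(n, dt, start, len) {
  i0 <- floor(start / dt + 1e-9) + 1
  i1 <- ceiling((start + len) / dt - 1e-9)
  if (i0 < 1 || i1 > n)
    stop(sprintf("window [%g, %g) ms lies outside the trace (duration %g ms)",
                 start, start + len, n * dt), call. = FALSE)
  seq.int(i0, i1)
}

# linear interpolation of irregular (x, y) onto a regular integer-um support
.resampleLinear <- function(x, y, support) {
  stats::approx(x, y, xout = support, method = "linear", rule = 2)$y
}

# unit-mass triangular kernel smoothing on a regular support, with the
# kernel renormalized over its in-range part so edges are unbiased
.triSmooth <- function(values, spacing, halfwidthUm) {
  if (halfwidthUm <= 0) return(values)
  h <- halfwidthUm / spacing
  lags <- seq.int(-floor(h), floor(h))
  w <- pmax(0, 1 - abs(lags) / h)
  n <- length(values)
  num <- stats::convolve(values, rev(w), type = "open")
  den <- stats::convolve(rep(1, n), rev(w), type = "open")
  keep <- seq.int(floor(h) + 1, floor(h) + n)
  num[keep] / den[keep]
}

# Pearson r via the explicit covariance formula; NA-free inputs assumed
.pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0)
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  sum((x - mx) * (y - my)) / (sx * sy)
}

# common regular support (at `by` um) shared by two patterns
.commonSupport <- function(p1, p2, by) {
  lo <- max(min(p1@positions), min(p2@positions))
  hi <- min(max(p1@positions), max(p2@positions))
  if (hi - lo < by)
    stop("patterns share no overlapping mediolateral range", call. = FALSE)
  seq(ceiling(lo / by) * by, floor(hi / by) * by, by = by)
}
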