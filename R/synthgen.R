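# Synthetic uncaging experiments with planted ground truth.
#
# Uncaging at a grid site recruits a patch of granule cells; each recruited
# cell fires a burst of action potentials and each spike deposits roughly
# one unitary charge q_u at the target. The generator plants per-site
# connection counts from hotspot descriptors, renders compound EPSC trains
# on top of white Gaussian current noise, and retains the truth so every
# downstream stage can be tested by parameter recovery.

.HWHM_TO_SD <- 1 / sqrt(2 * log(2))

#' Plant a connectivity ground truth from hotspot descriptors
#'
#' Connection counts at each grid site are the summed contributions of
#' Gaussian hotspots: a hotspot of given \code{strength} (peak count),
#' \code{center_um} and \code{halfwidth_um} (half-width at half-maximum)
#' contributes \code{strength * exp(-d^2 / (2 sigma^2))} connections at
#' mediolateral distance d, where sigma combines, in quadrature, the
#' hotspot's own width with the spatial spread of photostimulation
#' (45 um half-width, between the 33 um direct-spot and 59.6 um whole-cell
#' activation estimates). Counts are rounded to integers; sites rounding to
#' zero are silent.
#'
#' @param geom a [GridGeometry-class].
#' @param hotspots data.frame with \code{center_um}, \code{halfwidth_um}
#'   (>= 33 um), \code{strength} (peak connection count per depth row).
#' @param qU mean unitary charge per action potential, pC.
#' @param burst mean number of evoked action potentials per recruited cell.
#' @param burstSd per-site SD of the burst size (0 for a deterministic
#'   truth; draws require \code{seed}).
#' @param spreadHalfwidthUm photostimulation spread (HWHM), um.
#' @param seed integer, required when \code{burstSd > 0}.
#' @param archetypeId optional archetype label.
#' @return a [GroundTruthMap-class].
#' @examples
#' g <- gridGeometry(nDepthRows = 2)
#' tr <- groundTruth(g, data.frame(center_um = 0, halfwidth_um = 45,
#'                                 strength = 10), burstSd = 0)
#' sum(expectedCharge(tr) > 0)
#' @export
groundTruth <- function(geom, hotspots = NULL, qU = 0.1, burst = 19.6,
                        burstSd = 0, spreadHalfwidthUm = 45, seed = NULL,
                        archetypeId = NA_character_) {
  sites <- makeGrid(geom)
  counts <- numeric(nrow(sites))
  if (!is.null(hotspots) && nrow(hotspots)) {
    for (h in seq_len(nrow(hotspots))) {
      sd2 <- (hotspots$halfwidth_um[h] * .HWHM_TO_SD)^2 +
             (spreadHalfwidthUm * .HWHM_TO_SD)^2
      d <- sites$ml_um - hotspots$center_um[h]
      counts <- counts + hotspots$strength[h] * exp(-d^2 / (2 * sd2))
    }
  }
  sites$count <- as.integer(round(counts))
  sites$q_u <- qU
  if (burstSd > 0) {
    seed <- .requireSeed(seed)
    set.seed(seed)
    sites$burst <- pmax(0, stats::rnorm(nrow(sites), burst, burstSd))
  } else {
    sites$burst <- burst
  }
  hs <- if (is.null(hotspots))
    data.frame(center_um = numeric(), halfwidth_um = numeric(),
               strength = numeric())
  else hotspots
  new("GroundTruthMap", sites = sites, hotspots = hs,
      archetypeId = as.character(archetypeId))
}

#' Expected evoked charge per site of a ground truth
#'
#' The expected compound charge at a site is the product of its connection
#' count, the unitary charge and the burst size.
#'
#' @param truth a [GroundTruthMap-class].
#' @return numeric, pC, one value per site.
#' @export
expectedCharge <- function(truth) {
  with(truth@sites, count * q_u * burst)
}

# current kernel (pA) carrying exactly 1 pC: difference of exponentials,
# discretized so that sum(k) * dt / 1000 == 1
.unitChargeKernel <- function(dt, riseMs = 1, decayMs = 10) {
  t <- seq(0, riseMs + 10 * decayMs, by = dt)
  k <- exp(-t / decayMs) - exp(-t / riseMs)
  k / (sum(k) * dt / 1000)
}

#' Render the raw sweeps of one synthetic cell
#'
#' Each connected site receives a compound EPSC train: the planted number of
#' events (connection count x burst size, rounded) at times drawn uniformly
#' over the first 100 ms after stimulus onset, each event a
#' difference-of-exponentials EPSC (1 ms rise, 10 ms decay) scaled so the
#' train's total inward charge equals the site's expected charge exactly.
#' White Gaussian current noise is added throughout. Randomness is split
#' hierarchically (cell seed, then site and repeat), so the same seed
#' reproduces identical sample arrays.
#'
#' @param truth a [GroundTruthMap-class] from the same geometry.
#' @param geom the [GridGeometry-class] used to build \code{truth}.
#' @param noise a [NoiseSpec-class].
#' @param nRepeats sweeps per site.
#' @param seed integer root seed (mandatory).
#' @param cellId cell identifier.
#' @param meta extra metadata (\code{type}, \code{band}, ...).
#' @return a [CellRecording-class] with the truth retained.
#' @export
synthesizeCell <- function(truth, geom, noise = noiseSpec(), nRepeats = 1,
                           seed, cellId = "cell1", meta = list(type = "PC")) {
  seed <- .requireSeed(seed)
  stopifnot(is(truth, "GroundTruthMap"), is(geom, "GridGeometry"),
            is(noise, "NoiseSpec"), nRepeats >= 1)
  sites <- truth@sites
  dt <- 1 / noise@samplingKhz
  nSamp <- round(noise@durationMs * noise@samplingKhz)
  kern <- .unitChargeKernel(dt)
  onsetIdx <- round(noise@stimOnsetMs / dt)
  arr <- array(0, dim = c(nrow(sites), nRepeats, nSamp))
  for (s in seq_len(nrow(sites))) {
    nEv <- as.integer(round(sites$count[s] * sites$burst[s]))
    qTot <- sites$count[s] * sites$q_u[s] * sites$burst[s]
    for (r in seq_len(nRepeats)) {
      set.seed(.childSeed(seed, s, r))
      x <- stats::rnorm(nSamp, 0, noise@sdPa)
      if (nEv > 0) {
        qEach <- qTot / nEv
        evIdx <- onsetIdx + 1 + floor(stats::runif(nEv, 0, 100) / dt)
        for (i in evIdx) {
          j <- seq.int(i, min(nSamp, i + length(kern) - 1))
          x[j] <- x[j] - qEach * kern[seq_along(j)]
        }
      }
      arr[s, r, ] <- x
    }
  }
  meta$soma_um <- geom@midlineOffset
  new("CellRecording", cellId = cellId, traces = arr, dt = dt,
      stimOnset = noise@stimOnsetMs,
      sites = sites[, c("site", "ml_um", "depth_row")],
      geometry = geom, meta = meta, truth = truth)
}

#' Apply a plasticity rule to a ground truth
#'
#' Connected sites have their unitary charge scaled by the multiplier the
#' rule assigns to their initial expected charge (LTP for multipliers > 1,
#' LTD for < 1). Sites listed in \code{awakenSites} that are silent in the
#' input have their connection count raised from 0 to \code{awakenCount};
#' an awaken site that is already connected triggers a warning and follows
#' the rule instead.
#'
#' @param truth a [GroundTruthMap-class].
#' @param rule function mapping initial expected charge (pC) to a
#'   multiplicative change (>= 0).
#' @param awakenSites integer site indices to awaken.
#' @param awakenCount connection count given to awakened sites.
#' @return the modified [GroundTruthMap-class].
#' @export
applyPlasticity <- function(truth, rule = function(q) 1,
                            awakenSites = integer(), awakenCount = 10) {
  sites <- truth@sites
  q0 <- sites$count * sites$q_u * sites$burst
  mult <- vapply(q0, rule, numeric(1))
  if (any(mult < 0)) stop("plasticity multipliers must be >= 0")
  awake <- intersect(awakenSites, sites$site)
  already <- awake[sites$count[match(awake, sites$site)] > 0]
  if (length(already)) {
    warning("awaken site(s) already connected: ",
            paste(already, collapse = ", "), "; rule applied instead")
    awake <- setdiff(awake, already)
  }
  connected <- sites$count > 0
  sites$q_u[connected] <- sites$q_u[connected] * mult[connected]
  if (length(awake)) {
    i <- match(awake, sites$site)
    sites$count[i] <- as.integer(awakenCount)
  }
  out <- truth
  out@sites <- sites
  out
}

#' Define a set of connectivity archetypes
#'
#' An archetype is a hotspot template in midline coordinates together with
#' the mediolateral span of somata it applies to. Cells instantiated from an
#' archetype jitter the hotspot centers (Gaussian, \code{centerJitterSd})
#' and strengths (log-normal, \code{strengthJitterSd} on the log scale), so
#' cells of one archetype share correlated, but not identical, input maps.
#'
#' @param templates list of hotspot data.frames (see [groundTruth()]).
#' @param spans numeric matrix (one row per archetype) of soma-position
#'   spans \code{[lo, hi)} in um from the midline.
#' @param centerJitterSd per-cell hotspot-center jitter SD, um.
#' @param strengthJitterSd per-cell log-normal strength jitter SD.
#' @return an object of class \code{ArchetypeSet} (a validated list).
#' @export
archetypeSet <- function(templates, spans, centerJitterSd = 10,
                         strengthJitterSd = 0.15) {
  stopifnot(length(templates) == nrow(spans),
            centerJitterSd >= 0, strengthJitterSd >= 0)
  structure(list(templates = templates, spans = spans,
                 centerJitterSd = centerJitterSd,
                 strengthJitterSd = strengthJitterSd),
            class = "ArchetypeSet")
}

#' Four stereotyped archetypes spanning the midline-to-P2+ region
#'
#' Each archetype combines a hotspot near its own soma span with one or two
#' shared distal hotspots (including contralateral ones), emulating the
#' cluster structure of granule-cell input maps: cells in one mediolateral
#' neighbourhood share both their local input and their distal partners.
#'
#' @inheritParams archetypeSet
#' @return an \code{ArchetypeSet} of 4 archetypes.
#' @export
defaultArchetypes <- function(centerJitterSd = 10, strengthJitterSd = 0.15) {
  hs <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center_um = m[, 1], halfwidth_um = m[, 2], strength = m[, 3])
  }
  archetypeSet(
    templates = list(
      hs(50, 45, 10,   360, 45, 6),
      hs(150, 45, 8,  -150, 45, 7),
      hs(250, 45, 10,   60, 45, 6),
      hs(350, 45, 9,  -250, 45, 6,   120, 45, 5)
    ),
    spans = rbind(c(0, 100), c(100, 200), c(200, 300), c(300, 400)),
    centerJitterSd = centerJitterSd,
    strengthJitterSd = strengthJitterSd
  )
}

#' Simulate a cross-animal population of mapped cells
#'
#' Cells are assigned to archetypes round-robin; each cell's soma position
#' is drawn uniformly within its archetype's span, its hotspots are
#' jittered, and its sweeps are rendered with [synthesizeCell()]. All
#' randomness derives from the root seed, split per cell, so adding cells
#' never changes existing ones.
#'
#' @param nCells number of cells.
#' @param archetypes an \code{ArchetypeSet} (or NULL for independent cells:
#'   every cell gets \code{nHotspots} hotspots at uniform positions over its
#'   mapped range, abolishing cross-cell structure).
#' @param nHotspots hotspots per cell when \code{archetypes} is NULL.
#' @param halfExtent,step,nDepthRows grid parameters (see [gridGeometry()]).
#' @param noise a [NoiseSpec-class].
#' @param nRepeats sweeps per site.
#' @param seed integer root seed (mandatory).
#' @return an [ExperimentBundle-class]; each recording retains its truth and
#'   its archetype id (or \code{"independent"}).
#' @export
simulatePopulation <- function(nCells = 20, archetypes = defaultArchetypes(),
                               nHotspots = 3, halfExtent = 332, step = 41.5,
                               nDepthRows = 2, noise = noiseSpec(),
                               nRepeats = 3, seed) {
  seed <- .requireSeed(seed)
  recs <- vector("list", nCells)
  meta <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    cSeed <- .childSeed(seed, i)
    set.seed(cSeed)
    if (is.null(archetypes)) {
      soma <- stats::runif(1, 0, 200)
      hsN <- nHotspots
      hspots <- data.frame(
        center_um = stats::runif(hsN, soma - halfExtent * 0.8,
                                 soma + halfExtent * 0.8),
        halfwidth_um = 45,
        strength = stats::runif(hsN, 5, 10)
      )
      aid <- "independent"
    } else {
      a <- ((i - 1) %% length(archetypes$templates)) + 1
      span <- archetypes$spans[a, ]
      soma <- stats::runif(1, span[1], span[2])
      tmpl <- archetypes$templates[[a]]
      hspots <- tmpl
      hspots$center_um <- tmpl$center_um +
        stats::rnorm(nrow(tmpl), 0, archetypes$centerJitterSd)
      hspots$strength <- tmpl$strength *
        exp(stats::rnorm(nrow(tmpl), 0, archetypes$strengthJitterSd))
      aid <- as.character(a)
    }
    geom <- gridGeometry(halfExtent, step, nDepthRows, midlineOffset = soma)
    truth <- groundTruth(geom, hspots, burstSd = 6.6,
                         seed = .childSeed(cSeed, 1), archetypeId = aid)
    id <- sprintf("cell%03d", i)
    recs[[i]] <- synthesizeCell(truth, geom, noise, nRepeats,
                                seed = .childSeed(cSeed, 2), cellId = id,
                                meta = list(type = "PC", archetype = aid))
    meta[[i]] <- data.frame(cell_id = id, type = "PC", band = NA_character_,
                            soma_um = soma, archetype = aid)
  }
  names(recs) <- vapply(recs, function(r) r@cellId, character(1))
  new("ExperimentBundle", cells = do.call(rbind, meta), recordings = recs,
      derived = list(),
      provenance = list(seed = seed, generator = "simulatePopulation",
                        schema_version = "1.0"))
}
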