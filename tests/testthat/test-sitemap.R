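test_that("site Z-scores standardize charge against the noise model", {
  nm <- new("NoiseModel", muQ = 0, sigmaQ = 2, nSamples = 100L)
  expect_equal(siteZscore(10, nm), 5)
  nm2 <- new("NoiseModel", muQ = 1.3, sigmaQ = 2, nSamples = 100L)
  expect_equal(siteZscore(1.3, nm2), 0)

  # invariant under rescaling all charges and noise by c > 0
  for (c in c(0.1, 3, 42)) {
    nmc <- new("NoiseModel", muQ = 1.3 * c, sigmaQ = 2 * c,
               nSamples = 100L)
    expect_equal(siteZscore(7 * c, nmc), siteZscore(7, nm2))
  }

  bad <- new("NoiseModel", muQ = 0, sigmaQ = 2, nSamples = 100L)
  bad@sigmaQ <- 0
  expect_error(siteZscore(1, bad), "degenerate")
})

test_that("the significance threshold is the one-sided normal 0.001 quantile", {
  expect_equal(significanceThreshold(), 3.09)
  expect_equal(round(qnorm(1 - 0.001), 2), significanceThreshold())
})

test_that("event-count Z-scores behave like their charge counterparts", {
  expect_equal(countZscore(c(3, 3, 3), c(3, 2, 4)), 0)
  # mean response 8, mean control 2, control SD 2 -> Z = 3
  expect_equal(countZscore(8, c(0, 2, 4)), 3)
  expect_error(countZscore(5, c(2, 2, 2)), "degenerate")
  expect_error(countZscore(5, 2), "trials")

  # unbiased under equal Poisson rates
  set.seed(99)
  zs <- replicate(1000, countZscore(rpois(10, 5), rpois(10, 5)))
  expect_lt(abs(mean(zs)), 0.1)
})

test_that("site classification is strict at the threshold and per-position silent means no depth significant", {
  z <- c(3.0899, 3.09, 3.0901, 5, -1)
  lab <- classifySites(z)
  expect_equal(as.character(lab),
               c("silent", "silent", "significant", "significant",
                 "silent"))

  # per-position collapse over depth rows
  geom <- gridGeometry(halfExtent = 41.5, step = 41.5, nDepthRows = 2)
  sites <- makeGrid(geom)
  sites$mean_charge_pC <- 0
  sites$z <- c(5, 0, 0, 0, 1, 0)  # depth 0: (5,0,0); depth 1: (0,1,0)
  m <- new("ConnectivityMap", cellId = "c", sites = sites,
           noise = new("NoiseModel", muQ = 0, sigmaQ = 1,
                       nSamples = 10L),
           geometry = geom, statistic = "charge")
  pp <- classifySites(m, perPosition = TRUE)
  expect_equal(as.character(pp$label),
               c("significant", "silent", "silent"))
})

test_that("depth-maximum projection pools rows correctly", {
  geom <- gridGeometry(halfExtent = 41.5, step = 41.5, nDepthRows = 3)
  sites <- makeGrid(geom)
  sites$mean_charge_pC <- 0
  sites$z <- 0
  sites$z[sites$ml_um == 0] <- c(2, 5, 3)
  m <- new("ConnectivityMap", cellId = "c", sites = sites,
           noise = new("NoiseModel", muQ = 0, sigmaQ = 1,
                       nSamples = 10L),
           geometry = geom, statistic = "charge")
  proj <- maxProject(m)
  expect_equal(proj$z[proj$ml_um == 0], 5)

  # single row: identity
  g1 <- gridGeometry(halfExtent = 83, step = 41.5, nDepthRows = 1)
  s1 <- makeGrid(g1); s1$mean_charge_pC <- 0; s1$z <- c(1, -2, 0.5, 9, 3)
  m1 <- new("ConnectivityMap", cellId = "c", sites = s1,
            noise = m@noise, geometry = g1, statistic = "charge")
  expect_equal(maxProject(m1)$z, s1$z)

  # dominates every depth row elementwise, on random maps
  set.seed(5)
  for (rep in 1:5) {
    sites$z <- rnorm(nrow(sites))
    mr <- new("ConnectivityMap", cellId = "c", sites = sites,
              noise = m@noise, geometry = geom, statistic = "charge")
    pr <- maxProject(mr)
    for (d in 0:2) {
      row <- sites[sites$depth_row == d, ]
      expect_true(all(pr$z >= row$z[match(pr$ml_um, row$ml_um)]))
    }
  }
})

test_that("pattern construction smooths with a unit-mass triangular kernel", {
  # constant projection stays constant, edges included
  const <- data.frame(ml_um = seq(-332, 332, by = 41.5), z = 4.2)
  p <- toPattern(const)
  expect_equal(patternValues(p), rep(4.2, length(patternPositions(p))))

  # a single nonzero site on a dense lattice becomes the kernel itself:
  # a triangular bump with 18 um half-width
  dense <- data.frame(ml_um = -50:50, z = 0)
  dense$z[dense$ml_um == 0] <- 1
  pb <- toPattern(dense)
  v <- patternValues(pb); pos <- patternPositions(pb)
  expect_equal(pos[which.max(v)], 0)
  expect_equal(v[abs(pos) >= 18], rep(0, sum(abs(pos) >= 18)))
  # triangular shape: half-maximum at half the half-width
  expect_equal(v[pos == 9] / v[pos == 0], 0.5, tolerance = 1e-9)

  # superposition: two far-apart sites give two non-overlapping bumps
  two <- data.frame(ml_um = -100:100, z = 0)
  two$z[two$ml_um == -60] <- 1
  two$z[two$ml_um == 60] <- 2
  pt <- toPattern(two)
  one <- data.frame(ml_um = -100:100, z = 0); one$z[one$ml_um == -60] <- 1
  oth <- data.frame(ml_um = -100:100, z = 0); oth$z[oth$ml_um == 60] <- 2
  expect_equal(patternValues(pt),
               patternValues(toPattern(one)) + patternValues(toPattern(oth)))

  # translation of the whole grid translates the pattern
  base <- data.frame(ml_um = seq(0, 332, by = 41.5),
                     z = c(0, 1, 5, 2, 0, 0, 3, 1, 0))
  shft <- base; shft$ml_um <- shft$ml_um + 83
  pA <- toPattern(base); pB <- toPattern(shft)
  expect_equal(patternPositions(pB), patternPositions(pA) + 83)
  expect_equal(patternValues(pB), patternValues(pA))
})

test_that("planted hotspots are recovered within one grid step at default noise", {
  geom <- gridGeometry(nDepthRows = 2)
  centers <- c(-166, 83)
  truth <- groundTruth(geom, data.frame(center_um = centers,
                                        halfwidth_um = 45,
                                        strength = c(10, 12)),
                       burstSd = 0)
  rec <- synthesizeCell(truth, geom, fastNoise(), nRepeats = 3, seed = 21)
  m <- computeMap(rec)
  p <- toPattern(m)
  v <- patternValues(p); pos <- patternPositions(p)

  # strongest peak near one center; mask +-100 um and find the other
  i1 <- which.max(v)
  keep <- abs(pos - pos[i1]) > 100
  i2 <- which(keep)[which.max(v[keep])]
  found <- sort(c(pos[i1], pos[i2]))
  expect_true(all(abs(found - sort(centers)) <= 41.5))

  # both hotspots give significant sites
  sig <- classifySites(m, perPosition = TRUE)
  for (ct in centers) {
    near <- sig$label[abs(sig$ml_um - ct) <= 41.5]
    expect_true(any(near == "significant"))
  }
})

test_that("event-count and direct-current map variants work end to end", {
  # MLI-style cell: spontaneous EPSCs everywhere, extra evoked events at
  # two connected sites
  dt <- 0.2; nSamp <- 3000  # 600 ms at 5 kHz
  geom <- gridGeometry(halfExtent = 103.75, step = 41.5, nDepthRows = 1)
  sites <- makeGrid(geom)
  nSite <- nrow(sites); nTrial <- 4
  arr <- array(0, dim = c(nSite, nTrial, nSamp))
  set.seed(90)
  q5 <- 10 * 9 / 1000 * 5  # 5x-noise-SD event amplitude, in pC units
  for (s in seq_len(nSite)) for (r in seq_len(nTrial)) {
    x <- rnorm(nSamp, 0, 10)
    for (at in runif(rpois(1, 2), 0, 560)) x <- addEpsc(x, dt, at, q = q5)
    if (s %in% c(2, 5))
      for (at in runif(12, 105, 280)) x <- addEpsc(x, dt, at, q = q5)
    arr[s, r, ] <- x
  }
  rec <- new("CellRecording", cellId = "mli1", traces = arr, dt = dt,
             stimOnset = 100, sites = sites, geometry = geom,
             meta = list(type = "MLI"), truth = NULL)
  m <- computeMap(rec, statistic = "events")
  expect_equal(m@statistic, "events")
  z <- zScores(m)
  expect_true(all(z[c(2, 5)] > significanceThreshold()))
  expect_lt(max(z[-c(2, 5)]), min(z[c(2, 5)]))

  # GoC-style cell: slow direct current at some sites must not create
  # spurious significant charge
  geomG <- gridGeometry(halfExtent = 83, step = 41.5, nDepthRows = 1)
  sitesG <- makeGrid(geomG)
  nG <- nrow(sitesG); nSampG <- 2500; dtG <- 0.2  # 500 ms at 5 kHz
  t <- (seq_len(nSampG) - 1) * dtG
  arrG <- array(0, dim = c(nG, 3, nSampG))
  set.seed(91)
  for (s in seq_len(nG)) for (r in 1:3) {
    x <- rnorm(nSampG, 0, 10)
    if (s <= 2) x <- x - 60 * exp(-((t - 220) / 120)^2)  # direct current
    if (s == 4) for (at in c(120, 180, 240)) x <- addEpsc(x, dtG, at, q = 2)
    arrG[s, r, ] <- x
  }
  recG <- new("CellRecording", cellId = "goc1", traces = arrG, dt = dtG,
              stimOnset = 100, sites = sitesG, geometry = geomG,
              meta = list(type = "GoC"), truth = NULL)
  mRaw <- computeMap(recG)
  mFlt <- computeMap(recG, removeDC = TRUE)
  # unfiltered: the direct current masquerades as huge charge; filtered:
  # direct-current sites drop near noise level while the synaptic site
  # keeps its charge
  expect_gt(min(siteTable(mRaw)$mean_charge_pC[1:2]), 5)
  expect_lt(max(abs(siteTable(mFlt)$mean_charge_pC[1:2])), 3)
  expect_gt(siteTable(mFlt)$mean_charge_pC[4], 4)
  expect_gt(zScores(mFlt)[4], significanceThreshold())
})
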