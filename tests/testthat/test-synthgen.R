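test_that("grid enumeration matches the mapping protocol", {
  expect_equal(nrow(makeGrid(gridGeometry(nDepthRows = 2))), 34)
  expect_equal(nrow(makeGrid(gridGeometry(nDepthRows = 5))), 85)

  # degenerate grid: a single site at the soma
  g0 <- makeGrid(gridGeometry(halfExtent = 0, step = 41.5, nDepthRows = 1,
                              midlineOffset = 120))
  expect_equal(nrow(g0), 1)
  expect_equal(g0$ml_um, 120)

  # ordering and symmetry about the recorded cell
  g <- makeGrid(gridGeometry(nDepthRows = 3, midlineOffset = 50))
  expect_equal(order(g$depth_row, g$ml_um), seq_len(nrow(g)))
  ml <- unique(g$ml_um)
  expect_equal(sort(ml - 50), sort(50 - ml))
  expect_equal(max(ml) - min(ml), 664)

  expect_error(gridGeometry(step = 0), "step")
  expect_error(gridGeometry(halfExtent = -1), "halfExtent")
})

test_that("synthetic traces conserve the planted charge and reproduce under a seed", {
  geom <- gridGeometry(halfExtent = 41.5, step = 41.5, nDepthRows = 1)
  truth <- groundTruth(geom, NULL, burstSd = 0)
  truth@sites$count <- c(0L, 10L, 0L)
  truth@sites$burst <- 20

  rec <- synthesizeCell(truth, geom, fastNoise(sdPa = 0, samplingKhz = 10),
                        nRepeats = 1, seed = 11)
  q <- vapply(1:3, function(s)
    integrateCharge(rec@traces[s, 1, ], dt = rec@dt,
                    stimOnset = rec@stimOnset), numeric(1))
  # closed form: 10 connections x 0.1 pC x 20 spikes = 20 pC, by numeric
  # integration of the rendered trace
  expect_equal(q[2], 10 * 0.1 * 20, tolerance = 0.01)
  expect_equal(q[c(1, 3)], c(0, 0))

  # unconnected sites carry only noise
  recN <- synthesizeCell(groundTruth(geom, NULL, burstSd = 0), geom,
                         fastNoise(), nRepeats = 5, seed = 2)
  qN <- apply(recN@traces, c(1, 2), function(x)
    integrateCharge(x, dt = recN@dt, stimOnset = recN@stimOnset))
  expect_lt(abs(mean(qN)), 3 * sd(qN) / sqrt(length(qN)) + 0.5)

  # determinism
  r1 <- synthesizeCell(truth, geom, fastNoise(), nRepeats = 2, seed = 5)
  r2 <- synthesizeCell(truth, geom, fastNoise(), nRepeats = 2, seed = 5)
  expect_identical(r1@traces, r2@traces)
  r3 <- synthesizeCell(truth, geom, fastNoise(), nRepeats = 2, seed = 6)
  expect_false(identical(r1@traces, r3@traces))

  expect_error(synthesizeCell(truth, geom, fastNoise(), nRepeats = 1),
               "seed")
})

test_that("ground truth construction respects hotspot constraints", {
  geom <- gridGeometry(nDepthRows = 2)
  tr <- groundTruth(geom, data.frame(center_um = 0, halfwidth_um = 45,
                                     strength = 10), burstSd = 0)
  # peak count at the hotspot center, silent far away
  s0 <- tr@sites[tr@sites$depth_row == 0, ]
  expect_equal(s0$count[which.max(s0$count)], 10)
  expect_equal(s0$ml_um[which.max(s0$count)], 0)
  expect_true(all(s0$count[abs(s0$ml_um) > 250] == 0))

  # hotspot narrower than the photostimulation spread floor is rejected
  expect_error(groundTruth(geom, data.frame(center_um = 0,
                                            halfwidth_um = 20,
                                            strength = 5), burstSd = 0),
               "33")

  # burst draws require a seed and are reproducible
  expect_error(groundTruth(geom, NULL, burstSd = 6.6), "seed")
  t1 <- groundTruth(geom, NULL, burstSd = 6.6, seed = 3)
  t2 <- groundTruth(geom, NULL, burstSd = 6.6, seed = 3)
  expect_identical(t1@sites$burst, t2@sites$burst)
  expect_true(all(t1@sites$burst >= 0))
})

test_that("plasticity rules act multiplicatively and awaken silent sites", {
  geom <- gridGeometry(nDepthRows = 1)
  tr <- groundTruth(geom, data.frame(center_um = 0, halfwidth_um = 45,
                                     strength = 8), burstSd = 0)
  q0 <- expectedCharge(tr)

  # identity rule leaves the truth unchanged
  expect_equal(expectedCharge(applyPlasticity(tr)), q0)

  # halving rule halves every connected site's expected charge
  half <- applyPlasticity(tr, rule = function(q) 0.5)
  expect_equal(expectedCharge(half), q0 / 2)

  # awakening: silent site rises to count x q_u x burst
  silent <- which(tr@sites$count == 0)[1]
  awk <- applyPlasticity(tr, awakenSites = tr@sites$site[silent],
                         awakenCount = 10)
  expect_equal(expectedCharge(awk)[silent],
               10 * tr@sites$q_u[silent] * tr@sites$burst[silent])

  # awakening an already-connected site warns and applies the rule
  conn <- which(tr@sites$count > 0)[1]
  expect_warning(
    both <- applyPlasticity(tr, rule = function(q) 2,
                            awakenSites = tr@sites$site[conn]),
    "already connected")
  expect_equal(expectedCharge(both)[conn], 2 * q0[conn])

  expect_error(applyPlasticity(tr, rule = function(q) -1), ">= 0")
})

test_that("population seeds are hierarchical: adding cells never perturbs existing ones", {
  b3 <- simulatePopulation(nCells = 3, noise = fastNoise(), nRepeats = 1,
                           nDepthRows = 1, seed = 42)
  b5 <- simulatePopulation(nCells = 5, noise = fastNoise(), nRepeats = 1,
                           nDepthRows = 1, seed = 42)
  for (id in names(b3@recordings))
    expect_identical(b3@recordings[[id]]@traces,
                     b5@recordings[[id]]@traces)
  expect_equal(nCells(b5), 5)
})
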