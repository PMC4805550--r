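# brute-force bipartition oracle: over all 2-partitions, maximize
# (mean within-cluster r) - (mean between-cluster r)
bruteBipartition <- function(r) {
  n <- nrow(r)
  best <- NULL; bestScore <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {
    part <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(part)) < 2) next
    same <- outer(part, part, "==") & upper.tri(r)
    diff <- !outer(part, part, "==") & upper.tri(r)
    sc <- mean(r[same]) - mean(r[diff])
    if (sc > bestScore) { bestScore <- sc; best <- part }
  }
  best
}

test_that("band registration maps cells into the standard frame", {
  expect_equal(registerPosition("P1+", 0), 0)
  expect_equal(registerPosition("P1+", 1), 48.5)
  # center of P2+: 48.5 + 275.6 + 64.6/2
  expect_equal(registerPosition("P2+", 0.5), 356.4)
  expect_error(registerPosition("P9-"), "unknown band")

  # proportional mapping from an animal's own (here: doubled) band widths
  mine <- bandFrame(c("P1+" = 97, "P1-" = 551.2, "P2+" = 129.2,
                      "P2-" = 890.4))
  expect_equal(mapMeasuredPosition(97 / 2, mine), 48.5 / 2)
  expect_equal(mapMeasuredPosition(97 + 551.2, mine), 48.5 + 275.6)
})

test_that("pattern correlation equals the direct covariance formula", {
  p <- mkPattern(c(1, 4, 2, 8, 5), positions = seq(0, 40, by = 10))
  expect_equal(patternCorrelation(p, p), 1)
  pn <- mkPattern(-c(1, 4, 2, 8, 5), positions = seq(0, 40, by = 10))
  expect_equal(patternCorrelation(p, pn), -1)

  x <- c(2.5, -1, 0.25, 7, 3)
  y <- c(1, 2, -4, 2, 0.5)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(patternCorrelation(x, y), direct, tolerance = 1e-12)

  expect_error(patternCorrelation(x, rep(1, 5)), "zero variance")

  # affine rescaling a*x + b (a > 0) of both patterns leaves r unchanged
  p2 <- mkPattern(c(1, 2, 0, 5, 4), positions = seq(0, 40, by = 10))
  r0 <- patternCorrelation(p, p2)
  pa <- mkPattern(3 * c(1, 4, 2, 8, 5) + 7, positions = seq(0, 40, by = 10))
  pb <- mkPattern(3 * c(1, 2, 0, 5, 4) + 7, positions = seq(0, 40, by = 10))
  expect_equal(patternCorrelation(pa, pb), r0)
})

test_that("the shuffled-pair null is centered at zero and honors exclusions", {
  # identical patterns: every shuffled r is 1
  pats <- replicate(6, mkPattern(c(1, 5, 2, 7, 3, 1),
                                 positions = seq(0, 100, by = 20)),
                    simplify = FALSE)
  rs <- shuffleNull(pats, nShuffles = 10, seed = 1)
  expect_true(all(rs == 1))

  # determinism
  set.seed(31)
  ind <- lapply(1:10, function(i)
    bumpPattern(runif(3, -300, 500), runif(3, 3, 10), id = paste0("c", i)))
  r1 <- shuffleNull(ind, nShuffles = 30, seed = 7)
  r2 <- shuffleNull(ind, nShuffles = 30, seed = 7)
  expect_identical(r1, r2)

  # independent patterns: mean r within Monte-Carlo error of 0
  set.seed(32)
  many <- lapply(1:24, function(i)
    bumpPattern(runif(3, -300, 500), runif(3, 3, 10), id = paste0("c", i)))
  rs <- shuffleNull(many, nShuffles = 30, seed = 8)
  expect_gte(length(rs), 100)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.05)

  # excluded neighbor pairs never contribute: cells 1 and 2 identical,
  # every other pairing is imperfectly correlated
  base <- bumpPattern(c(0, 200), c(5, 3))
  other <- lapply(1:2, function(i) bumpPattern(c(-100 * i, 300), c(4, 6)))
  pats2 <- c(list(base, base), other)
  rsx <- shuffleNull(pats2, nShuffles = 50, seed = 2,
                     neighbors = rbind(c(1, 2)))
  expect_true(all(rsx < 1 - 1e-12))

  expect_error(shuffleNull(pats2[1:2], nShuffles = 5, seed = 1), ">= 3")
  expect_error(shuffleNull(pats2, nShuffles = 5), "seed")
})

test_that("sliding-window median patterns take elementwise medians of members", {
  sup <- seq(0, 100, by = 10)
  p1 <- mkPattern(rep(1, 11), sup, soma = 50, id = "a")
  p2 <- mkPattern(rep(2, 11), sup, soma = 52, id = "b")
  p3 <- mkPattern(rep(9, 11), sup, soma = 48, id = "c")
  gs <- medianPatterns(list(p1, p2, p3))
  expect_gt(length(gs), 0)
  for (g in gs) expect_true(all(patternValues(g@pattern) == 2))

  # single cell: its own pattern at every window containing it
  gs1 <- medianPatterns(list(p1))
  expect_gt(length(gs1), 0)
  for (g in gs1) {
    expect_equal(g@members, "a")
    expect_true(all(patternValues(g@pattern) == 1))
    expect_lte(abs(g@center - 50), 50)
  }
})

test_that("the correlation matrix is symmetric with unit diagonal and NA for undefined entries", {
  set.seed(41)
  pats <- lapply(1:6, function(i)
    bumpPattern(c(50 * i - 100, 300), c(6, 4), soma = 40 * i,
                id = paste0("c", i)))
  gs <- medianPatterns(pats)
  cm <- correlationMatrix(gs)
  expect_equal(cm@r, t(cm@r))
  expect_equal(unname(diag(cm@r)), rep(1, nrow(cm@r)))
  expect_true(all(cm@r[is.finite(cm@r)] >= -1 - 1e-12 &
                  cm@r[is.finite(cm@r)] <= 1 + 1e-12))

  # identical groups: all-ones matrix
  same <- replicate(4, mkPattern(c(1, 3, 2, 6), seq(0, 30, 10), soma = 15),
                    simplify = FALSE)
  gsI <- suppressMessages(medianPatterns(same,
                                         somaPositions = c(10, 30, 50, 70)))
  expect_gte(length(gsI), 2)
  cmI <- correlationMatrix(gsI)
  expect_true(all(cmI@r == 1))

  # a zero-variance group propagates NA, never 0
  flat <- mkPattern(rep(2, 4), seq(0, 30, 10), soma = 15)
  gsF <- suppressMessages(
    medianPatterns(list(same[[1]], flat), somaPositions = c(10, 90)))
  cmF <- correlationMatrix(gsF)
  expect_true(anyNA(cmF@r))
  expect_false(any(cmF@r[upper.tri(cmF@r)] == 0, na.rm = TRUE))

  expect_error(correlationMatrix(gsI[1]), ">= 2")
})

test_that("spectral co-clustering recovers planted blocks exactly (brute-force oracle)", {
  mkAssign <- function(r, centers, k)
    spectralCocluster(new("CorrelationMatrix", r = r, centers = centers),
                      k = k)

  # permuted 2-block all-ones block-diagonal matrices, several sizes
  set.seed(51)
  for (sizes in list(c(3, 3), c(4, 2), c(5, 3))) {
    n <- sum(sizes)
    truth <- rep(seq_along(sizes), sizes)
    r <- outer(truth, truth, function(a, b) ifelse(a == b, 1, 0))
    perm <- sample(n)
    rp <- r[perm, perm]
    dimnames(rp) <- NULL
    a <- mkAssign(rp, centers = seq_len(n) * 10, k = 2)
    expect_equal(ari(clusterIds(a), truth[perm]), 1)
    expect_equal(ari(clusterIds(a), bruteBipartition(rp)), 1)
  }

  # degenerate (constant) matrix
  const <- matrix(1, 4, 4)
  expect_error(mkAssign(const, 1:4 * 10, 2), "degenerate")
  # k larger than the number of groups
  r2 <- diag(4); r2[r2 == 0] <- 0.1
  expect_error(mkAssign(r2, 1:4 * 10, 5), "k")
})

test_that("co-clustering is equivariant under permuting the matrix", {
  set.seed(52)
  truth <- rep(1:3, times = c(4, 3, 3))
  n <- length(truth)
  r <- outer(truth, truth, function(a, b) ifelse(a == b, 0.9, 0.05)) +
    diag(0.1, n)
  noise <- matrix(rnorm(n * n, 0, 0.02), n)
  r <- r + (noise + t(noise)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  cm <- new("CorrelationMatrix", r = r, centers = seq_len(n) * 10)
  a0 <- spectralCocluster(cm, k = 3)
  perm <- sample(n)
  cmP <- new("CorrelationMatrix", r = r[perm, perm],
             centers = (seq_len(n) * 10)[perm])
  aP <- spectralCocluster(cmP, k = 3)
  expect_equal(ari(clusterIds(aP), clusterIds(a0)[perm]), 1)
})

test_that("soma-centered averaging keeps a central peak and washes out distal structure", {
  # one pattern: itself, translated
  p <- bumpPattern(c(100, 300), c(5, 3), soma = 100)
  cp <- centerOnSoma(list(p), normalize = FALSE)
  expect_equal(patternPositions(cp), patternPositions(p) - 100)
  expect_equal(patternValues(cp), patternValues(p))

  # mirror-image pair: symmetric mean (on a symmetric support)
  sup <- seq(-300, 300, by = 1)
  pm1 <- bumpPattern(c(0, 150), c(5, 3), support = sup, soma = 0)
  pm2 <- bumpPattern(c(0, -150), c(5, 3), support = sup, soma = 0)
  cm <- centerOnSoma(list(pm1, pm2))
  v <- patternValues(cm)
  expect_equal(v, rev(v), tolerance = 1e-9)

  # population with a local hotspot plus one at a random absolute
  # position: centered mean has one central peak, no secondary peak
  set.seed(61)
  pop <- lapply(1:30, function(i) {
    soma <- runif(1, 0, 400)
    bumpPattern(c(soma, runif(1, -300, 500)), c(6, 6),
                soma = soma, id = paste0("c", i))
  })
  cpop <- centerOnSoma(pop)
  v <- patternValues(cpop); pos <- patternPositions(cpop)
  ok <- is.finite(v)
  v <- v[ok]; pos <- pos[ok]
  core <- abs(pos) <= 60
  expect_lt(abs(pos[which.max(v)]), 20)
  expect_lt(max(v[!core & abs(pos) < 280]), 0.5 * max(v))
})
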