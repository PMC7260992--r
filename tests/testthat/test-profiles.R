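test_that("contour sampling matches a brute-force segment oracle", {
  # linear ramp
  expect_equal(sampleContour(cbind(c(1, 11), c(0, 10)), 11), 0:10)
  # constant extrapolation beyond the endpoints
  expect_equal(sampleContour(cbind(c(4, 8), c(2, 2)), 10), rep(2, 10))
  # random polylines against dense per-segment evaluation
  set.seed(21)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    x <- sort(runif(k, 1, 40)); y <- runif(k, -5, 5)
    got <- sampleContour(cbind(x, y), 40)
    oracle <- vapply(seq_len(40), function(q) {
      if (q <= x[1]) return(y[1])
      if (q >= x[k]) return(y[k])
      j <- max(which(x <= q))
      if (x[j] == q) return(y[j])
      y[j] + (y[j + 1] - y[j]) * (q - x[j]) / (x[j + 1] - x[j])
    }, numeric(1))
    expect_lt(max(abs(got - oracle)), 1e-9)
  }
  # duplicate x with conflicting y: averaged, with a warning
  expect_warning(v <- sampleContour(cbind(c(1, 5, 5, 9), c(0, 2, 4, 0)), 9),
                 "conflicting")
  expect_equal(v[5], 3)
})

test_that("joint normalization preserves relative layer heights", {
  pp <- profilePair("P1", "S1", 3, cbind(c(1, 10), c(2, 4)),
                    cbind(c(1, 10), c(0, 2)))
  nz <- normalizeProfilePair(pp, 10)
  # joint range [0, 4]: textile in [0.5, 1], base in [0, 0.5]
  expect_equal(range(nz$textile), c(0.5, 1))
  expect_equal(range(nz$base), c(0, 0.5))
  expect_equal(min(c(nz$textile, nz$base)), 0)
  expect_equal(max(c(nz$textile, nz$base)), 1)
  # idempotence and invariance under common affine transforms
  pp2 <- profilePair("P1", "S1", 3, cbind(c(1, 10), 3 * c(2, 4) + 7),
                     cbind(c(1, 10), 3 * c(0, 2) + 7))
  nz2 <- normalizeProfilePair(pp2, 10)
  expect_equal(nz2$textile, nz$textile)
  expect_equal(nz2$base, nz$base)
  # degenerate: both contours constant and equal -> 0.5 by convention
  flat <- profilePair("P1", "S1", 3, cbind(c(1, 10), c(2, 2)),
                      cbind(c(1, 10), c(2, 2)))
  expect_equal(normalizeProfilePair(flat, 10)$textile, rep(0.5, 10))
})

test_that("mean responses average normalized observers", {
  p1 <- profilePair("P1", "S1", 3, cbind(c(1, 10), c(0, 1)),
                    cbind(c(1, 10), c(0, 0.5)))
  # one participant: mean equals that participant's normalized response
  m1 <- meanProfileResponse(list(p1), 10)
  expect_equal(m1$textile, normalizeProfilePair(p1, 10)$textile)
  expect_identical(m1$n, 1L)
  # two mirror-image responses: constant mean
  p2 <- profilePair("P2", "S1", 3, cbind(c(1, 10), c(1, 0)),
                    cbind(c(1, 10), c(0.5, 0)))
  m2 <- meanProfileResponse(list(p1, p2), 10)
  expect_equal(m2$textile, rep(0.5, 10))
  expect_error(meanProfileResponse(list(), 10), "empty")
})

test_that("profile scores are affine-invariant Pearson correlations", {
  study <- smallStudy(seed = 4)
  b <- bundles(study)[[1]]
  w <- ncol(stimulusImage(b))
  row <- chooseRasterRows(b, n = 1)
  truthT <- depthTextile(b)[row, ]; truthB <- depthBase(b)[row, ]
  # mean response equal to an affine transform of the truth: r = 1
  mr <- list(textile = 0.3 * truthT + 2, base = 0.5 * truthB - 1, n = 1L)
  sc <- scoreProfiles(mr, b, row)
  expect_equal(sc$r[sc$layer == "textile"], 1, tolerance = 1e-12)
  expect_equal(sc$r[sc$layer == "base"], 1, tolerance = 1e-12)
  # reversed response anti-correlates perfectly
  mr2 <- list(textile = -truthT, base = truthB, n = 1L)
  expect_equal(scoreProfiles(mr2, b, row)$r[1], -1, tolerance = 1e-12)
  # scores do not depend on the per-raster normalization constants
  prs <- lapply(1:6, function(i)
    simulateProfiler(b, row, noiseSd = 0.1, seed = i,
                     participantId = sprintf("Q%d", i)))
  sc1 <- scoreProfiles(meanProfileResponse(prs, w), b, row)
  shifted <- lapply(prs, function(p)
    profilePair(participantId(p), stimulusId(p), row,
                cbind(p@textilePoints[, 1], 5 * p@textilePoints[, 2] + 3),
                cbind(p@basePoints[, 1], 5 * p@basePoints[, 2] + 3)))
  sc2 <- scoreProfiles(meanProfileResponse(shifted, w), b, row)
  expect_equal(sc1$r, sc2$r, tolerance = 1e-12)
})

test_that("correlations rise toward 1 as profiler noise vanishes", {
  study <- smallStudy(seed = 2)
  b <- bundles(study)[[1]]
  w <- ncol(stimulusImage(b))
  row <- chooseRasterRows(b, n = 1)
  ladder <- c(0.3, 0.1, 0.03, 0)
  rT <- rB <- numeric(length(ladder))
  for (i in seq_along(ladder)) {
    prs <- lapply(1:8, function(s)
      simulateProfiler(b, row, noiseSd = ladder[i], seed = s,
                       participantId = sprintf("Q%d", s)))
    sc <- scoreProfiles(meanProfileResponse(prs, w), b, row)
    rT[i] <- sc$r[sc$layer == "textile"]
    rB[i] <- sc$r[sc$layer == "base"]
  }
  expect_true(all(diff(rT) >= -0.02))  # non-decreasing up to MC wiggle
  expect_gt(rT[length(ladder)], 0.99)
  expect_gt(rB[length(ladder)], 0.99)
  expect_gt(rB[length(ladder)], rB[1])
})
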