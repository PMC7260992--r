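test_that("base shapes are deterministic, distinct across ids and seeds", {
  a1 <- makeBaseShape("A", 1, size = c(64, 64))
  a2 <- makeBaseShape("A", 1, size = c(64, 64))
  expect_identical(a1, a2)
  # distinct seeds decorrelate the fields (10 consecutive seed pairs)
  for (s in 1:10) {
    x <- makeBaseShape("A", s, size = c(64, 64))
    y <- makeBaseShape("A", s + 1, size = c(64, 64))
    expect_lt(abs(cor(as.numeric(x), as.numeric(y))), 0.5)
  }
  # distinct base ids (the condition the study design relies on)
  for (s in 1:5) for (p in list(c("A", "B"), c("A", "C"), c("B", "C")))
    expect_lt(abs(cor(
      as.numeric(makeBaseShape(p[1], s, size = c(64, 64))),
      as.numeric(makeBaseShape(p[2], s, size = c(64, 64))))), 0.5)
  # amplitude 0 gives a flat field
  expect_identical(makeBaseShape("A", 1, size = c(64, 64), amplitude = 0),
                   matrix(0, 64, 64))
})

test_that("draped cloth respects the obstacle constraint and contact logic", {
  # flat base, no folds: textile == base, contact everywhere
  flat <- matrix(0, 64, 64)
  d0 <- drapeCloth(flat, drapeParams(foldAmplitude = 0), seed = 1)
  expect_equal(d0$textile, flat)
  expect_true(all(d0$contact))
  # constraint holds for fuzzed parameterizations
  for (s in 1:5) {
    base <- makeBaseShape("F", s, size = c(64, 64))
    p <- drapeParams(nFolds = sample(2:10, 1),
                     foldAmplitude = runif(1, 0, 1.2),
                     foldWavelengthPx = runif(1, 12, 48),
                     membraneSmoothingIters = sample(5:40, 1))
    d <- drapeCloth(base, p, seed = s)
    expect_gte(min(d$textile - base), 0)
    expect_identical(d$contact, (d$textile - base) < p$contactEpsilon)
  }
  # a single tall bump with folds elsewhere: contact at the apex, none in
  # fold-dominated flats far from the bump
  n <- 96
  rr <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  bump <- 2 * exp(-((rr - 48)^2 + (cc - 48)^2) / (2 * 6^2))
  d <- drapeCloth(bump, drapeParams(foldAmplitude = 0.8), seed = 2)
  apex <- which(bump == max(bump), arr.ind = TRUE)[1, ]
  expect_true(d$contact[apex[1], apex[2]])
  expect_error(drapeCloth(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("Lambertian shading matches analytic cases", {
  flat <- matrix(1, 32, 32)
  expect_equal(renderLambertian(flat, c(0, 0, 1)), matrix(1, 32, 32))
  # 45-degree ramp under overhead light: cos(45) everywhere away from edges
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32, byrow = FALSE)
  ramp <- t(ramp)  # height increases along columns, slope 1
  img <- renderLambertian(ramp, c(0, 0, 1))
  expect_equal(img[10:20, 10:20],
               matrix(cos(pi / 4), 11, 11), tolerance = 1e-6)
  # any input stays in [0, 1]
  h <- makeBaseShape("L", 4, size = c(64, 64)) * 5
  img <- renderLambertian(h, c(1, -2, 0.5))
  expect_true(all(img >= 0 & img <= 1 + 1e-12))
  expect_error(renderLambertian(flat, c(0, 0, 0)), "nonzero")
})

test_that("ridge detection finds sinusoidal crests within 1 px", {
  n <- 96
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  lambda <- 24
  corr <- sin(2 * pi * cc / lambda)
  ridges <- detectRidges(corr, scale = 2)
  crestCols <- which(abs(sin(2 * pi * seq_len(n) / lambda) - 1) < 1e-9)
  hit <- which(ridges[20:70, , drop = FALSE], arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  dist <- vapply(hit[, 2] + 0, function(c) min(abs(c - crestCols)), numeric(1))
  expect_lte(max(dist), 1)
  # flat field has no ridges
  expect_false(any(detectRidges(matrix(0, 48, 48))))
  # two orthogonal corrugations: both crest sets are recovered, i.e. every
  # interior crest line of either orientation has ridge pixels within 1 px
  rr <- matrix(seq_len(n), n, n)
  both <- sin(2 * pi * cc / lambda) + sin(2 * pi * rr / lambda)
  r2 <- detectRidges(both, scale = 2)
  hit2 <- which(r2[20:70, 20:70, drop = FALSE], arr.ind = TRUE) + 19
  interior <- crestCols[crestCols > 20 & crestCols < 70]
  for (cl in interior) {
    expect_lte(min(abs(hit2[, 2] - cl)), 1)  # vertical crest line found
    expect_lte(min(abs(hit2[, 1] - cl)), 1)  # horizontal crest line found
  }
})

test_that("simulated annotators honor marking and flip probabilities", {
  study <- smallStudy(seed = 5)
  b <- bundles(study)[[1]]
  ridges <- detectRidges(depthTextile(b))
  contact <- (depthTextile(b) - depthBase(b)) < 0.02
  mask <- analysisMask(b)
  # mark_prob 1, flip 0, no dilation: fully decisive (disjoint maps)
  p1 <- simulateAnnotator(ridges, contact,
                          observerParams(markProb = 1, labelFlipProb = 0,
                                         strokeDilationPx = 0, seed = 2))
  expect_identical(decisiveness(p1, mask), 1)
  expect_identical(sum(fabricMap(p1) & contactMap(p1)), 0L)
  # mark_prob 0: empty maps, zero profligacy
  p0 <- simulateAnnotator(ridges, contact,
                          observerParams(markProb = 0, seed = 2))
  expect_identical(profligacy(p0, mask), 0)
  # determinism given seed
  pa <- simulateAnnotator(ridges, contact, observerParams(seed = 9))
  pb <- simulateAnnotator(ridges, contact, observerParams(seed = 9))
  expect_identical(fabricMap(pa), fabricMap(pb))
  expect_error(simulateAnnotator(ridges[1:10, ], contact),
               "coregistration")
})

test_that("contact structure is shared across drapings of one base", {
  # the structural premise of the similarity analyses: drapings of the same
  # base share contact maps more than drapings of different bases
  study <- smallStudy(seed = 2)
  cons <- lapply(bundles(study), function(b)
    as.numeric((depthTextile(b) - depthBase(b)) < 0.02))
  ids <- vapply(bundles(study), baseShapeId, character(1))
  n <- length(cons)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- cor(cons[[i]], cons[[j]])
    if (ids[i] == ids[j]) within <- c(within, r) else between <- c(between, r)
  }
  expect_gt(mean(within), mean(between))
  # fabric-cause ridge pixels sit higher above the base than contact ones
  b <- bundles(study)[[1]]
  ridges <- detectRidges(depthTextile(b))
  gap <- depthTextile(b) - depthBase(b)
  contact <- gap < 0.02
  expect_gt(mean(gap[ridges & !contact]), mean(gap[ridges & contact]))
})

test_that("simulated profilers recover profiles in the noise-free limit", {
  study <- smallStudy(seed = 4)
  b <- bundles(study)[[1]]
  w <- ncol(stimulusImage(b))
  row <- chooseRasterRows(b, n = 1)
  # noise 0 with control points at every column: near-perfect recovery
  pp <- simulateProfiler(b, row, noiseSd = 0, nControlPoints = w, seed = 1)
  tex <- sampleContour(pp@textilePoints, w)
  expect_gt(cor(tex, depthTextile(b)[row, ]), 0.99)
  bas <- sampleContour(pp@basePoints, w)
  expect_gt(cor(bas, depthBase(b)[row, ]), 0.99)
  # contours span the full width with >= 2 control points
  expect_gte(nrow(pp@textilePoints), 2)
  expect_identical(range(pp@textilePoints[, 1]), c(1, w))
  expect_error(simulateProfiler(b, nrow(stimulusImage(b)) + 5, seed = 1),
               "outside")
  # heavy noise drives correlation toward zero on average
  rs <- vapply(1:40, function(s) {
    p <- simulateProfiler(b, row, noiseSd = 3, seed = s)
    cor(sampleContour(p@textilePoints, w), depthTextile(b)[row, ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.35)
})
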