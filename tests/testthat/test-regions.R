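mkMeanMap <- function(v, sid = "S1", cause = "contact", n = 1L)
  new("MeanMap", stimulusId = sid, cause = cause, values = v,
      nParticipants = n)

test_that("8-connected labeling agrees with an independent flood fill", {
  set.seed(17)
  for (i in 1:10) {
    m <- matrix(runif(48 * 48) < 0.35, 48, 48)
    lab <- labelComponents(m, 8)
    oracle <- floodFillLabels(m, 8)
    expect_identical(max(lab), max(oracle))
    # identical partitions (labels may be permuted)
    expect_identical(lab > 0, oracle > 0)
    for (k in seq_len(max(lab)))
      expect_identical(length(unique(oracle[lab == k])), 1L)
  }
  # diagonal-only touching pixels belong to one 8-component
  d <- matrix(FALSE, 4, 4); d[1, 1] <- d[2, 2] <- TRUE
  expect_identical(max(labelComponents(d, 8)), 1L)
  expect_identical(max(labelComponents(d, 4)), 2L)
})

test_that("segmentation matches the flood-fill oracle on plateau maps", {
  cfg <- analysisConfig()
  segmentOracle <- function(v, cfg) {
    # independent reimplementation of the fixed pipeline with EBImage blur
    # but oracle labeling
    b <- EBImage::gblur(v, sigma = cfg@blurSigmaPx, boundary = "replicate")^2
    b <- (b - min(b)) / (max(b) - min(b))
    bin <- b >= cfg@binarizeThreshold
    kern <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
    bin <- EBImage::opening(bin * 1, kern) > 0
    max(floodFillLabels(bin, 8))
  }
  # one high plateau: exactly one region
  v <- matrix(0, 96, 96); v[31:70, 31:70] <- 1
  expect_identical(length(segmentMeanMap(mkMeanMap(v), cfg)), 1L)
  # two plateaus far apart (> 6 sigma): two regions
  v2 <- matrix(0, 160, 160); v2[11:40, 11:40] <- 1; v2[111:150, 111:150] <- 1
  expect_identical(length(segmentMeanMap(mkMeanMap(v2), cfg)), 2L)
  # all-zero map: constant, zero regions with a warning
  expect_warning(r0 <- segmentMeanMap(mkMeanMap(matrix(0, 64, 64)), cfg),
                 "constant")
  expect_identical(length(r0), 0L)
  # randomized plateau maps against the oracle, exactly
  for (s in 1:15) {
    v <- makePlateauMap(96, k = sample(1:4, 1), seed = s)
    if (max(v) == 0) next
    expect_identical(length(segmentMeanMap(mkMeanMap(v), cfg)),
                     segmentOracle(v, cfg))
  }
})

test_that("segmentation is translation-equivariant away from borders", {
  cfg <- analysisConfig()
  v <- matrix(0, 128, 128); v[41:60, 41:70] <- 1
  r1 <- segmentMeanMap(mkMeanMap(v), cfg)
  shift <- 9L
  v2 <- matrix(0, 128, 128)
  v2[(41 + shift):(60 + shift), (41 + shift):(70 + shift)] <- 1
  r2 <- segmentMeanMap(mkMeanMap(v2), cfg)
  expect_identical(length(r1), length(r2))
  expect_identical(r1[[1]]$pixels + shift, r2[[1]]$pixels)
})

test_that("skeletons of primitives match their constructions", {
  # long bar: one branch at depth 1
  m <- matrix(FALSE, 80, 80); m[11:18, 11:70] <- TRUE
  sk <- skeletonizeRegion(mkRegion(m), prunePx = 5)
  expect_identical(length(sk@branches), 1L)
  expect_identical(sk@branches[[1]]$depth, 1L)
  st <- shapescission:::skeletonStatistics(sk)
  expect_identical(unname(st["skelNumBranches"]), 1)
  expect_identical(unname(st["skelMaxDepth"]), 1)
  # symmetric Y at several rotations: 3 branches, equal child angles
  for (rot in c(0, 0.3, 1.1)) {
    sky <- skeletonizeRegion(mkRegion(yMask(rot = rot)), prunePx = 8)
    expect_identical(length(sky@branches), 3L)
    angs <- vapply(sky@branches, function(b) b$angleFromParent, numeric(1))
    angs <- angs[is.finite(angs)]
    expect_identical(length(angs), 2L)
    expect_lt(abs(diff(angs)), 5)
  }
  # disk: single short branch, total length below the diameter
  skd <- skeletonizeRegion(mkRegion(diskMask(60, 30, 30, 15)), prunePx = 5)
  expect_identical(length(skd@branches), 1L)
  expect_lt(skd@totalLength, 30)
  # total length scales linearly under 2x upsampling (+-10%)
  m2 <- matrix(FALSE, 160, 160); m2[21:36, 21:140] <- TRUE
  l1 <- skeletonizeRegion(mkRegion(m), 5)@totalLength
  l2 <- skeletonizeRegion(mkRegion(m2), 5)@totalLength
  expect_lt(abs(l2 / l1 - 2), 0.2)
})

test_that("region features match closed forms on primitives", {
  # 20x20 axis-aligned square on a flat two-layer bundle
  m <- matrix(FALSE, 40, 40); m[11:30, 11:30] <- TRUE
  f <- computeRegionFeatures(mkRegion(m), flatBundle(40, 1, 1))
  expect_identical(f$Area, 400)
  expect_equal(f$Solidity, 1, tolerance = 1e-9)
  expect_lt(f$Eccentricity, 0.05)
  expect_equal(f$Perimeter, 76, tolerance = 1)
  # centered region: zero peripherality; flat equal layers: zero depth gap
  expect_lt(f$Peripherality, 1e-9)
  expect_identical(f$depthDifferences, 0)
  expect_identical(f$stdDepths, 0)
  expect_identical(f$meanDepths, 1)
  # oriented bar: orientation within 2 degrees of construction
  for (angDeg in c(30, -50, 80)) {
    ang <- angDeg * pi / 180
    mb <- matrix(FALSE, 100, 100)
    for (t in seq(-35, 35, by = 0.2)) for (s in seq(-3, 3, by = 0.2)) {
      r <- round(50 - t * sin(ang) + s * cos(ang))
      c <- round(50 + t * cos(ang) + s * sin(ang))
      if (r >= 1 && r <= 100 && c >= 1 && c <= 100) mb[r, c] <- TRUE
    }
    fb <- computeRegionFeatures(mkRegion(mb), flatBundle(100))
    expect_lt(abs(fb$Orientation - angDeg), 2)
    expect_gt(fb$Eccentricity, 0.9)
  }
  # disk: perimeter/area ratio within 15% of 2/r
  fd <- computeRegionFeatures(mkRegion(diskMask(60, 30, 30, 15)),
                              flatBundle(60))
  expect_lt(abs(fd$perimAreaRatio - 2 / 15) / (2 / 15), 0.15)
  # depth features use the ground-truth geometry
  n <- 40
  tex <- matrix(seq(0, 3, length.out = n), n, n, byrow = TRUE)
  b <- stimulusBundle("S1", "A", tex, depthTextile = tex,
                      depthBase = matrix(0, n, n))
  fg <- computeRegionFeatures(mkRegion(m), b)
  expect_equal(fg$meanDepths, mean(tex[m]))
  expect_equal(fg$stdDepths, sd(tex[m]))
  expect_equal(fg$depthDifferences, mean(tex[m]))
})

test_that("the feature table covers every segmented region with its cause", {
  study <- smallStudy(seed = 1)
  cfg <- analysisConfig()
  ft <- assembleFeatureTable(study, cfg)
  expect_identical(attr(ft, "nRegions"), nrow(ft))
  expect_true(all(ft$cause %in% c("contact", "fabric")))
  expect_true(all(regionFeatureNames() %in% colnames(ft)))
  # row count equals the sum of per-map segmentation counts
  masks <- lapply(bundles(study), analysisMask)
  nOracle <- 0L
  for (sid in names(bundles(study))) {
    pairs <- Filter(function(p) stimulusId(p) == sid, strokeMaps(study))
    for (cause in c("contact", "fabric")) {
      mm <- meanMap(pairs, cause, masks[[sid]])
      nOracle <- nOracle + length(suppressWarnings(segmentMeanMap(mm, cfg)))
    }
  }
  expect_identical(nrow(ft), nOracle)
  # empty study: empty table
  empty <- new("ScissionStudy", bundles = bundles(study), strokes = list(),
               profiles = list(),
               profileDesign = data.frame(), seed = 1L, params = list())
  expect_identical(nrow(assembleFeatureTable(empty, cfg)), 0L)
})
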