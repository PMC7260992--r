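test_that("mean maps average binary maps per pixel", {
  n <- 16
  mask <- matrix(TRUE, n, n)
  f1 <- matrix(FALSE, n, n); f1[1:5, 1:5] <- TRUE
  f2 <- matrix(FALSE, n, n); f2[10:14, 10:14] <- TRUE
  p1 <- strokeMapPair("P1", "S1", f1, f1)
  p2 <- strokeMapPair("P2", "S1", f2, f2)
  # one participant: mean equals that binary map
  expect_identical(mapValues(meanMap(list(p1), "fabric", mask)), f1 * 1)
  # two participants with disjoint marks: values in {0, 0.5}
  mm <- meanMap(list(p1, p2), "fabric", mask)
  expect_true(all(mapValues(mm) %in% c(0, 0.5)))
  expect_identical(nParticipants(mm), 2L)
  # idempotence over identical participants
  mmk <- meanMap(list(p1, p1, p1), "contact", mask)
  expect_identical(mapValues(mmk), f1 * 1)
  expect_error(meanMap(list(), "fabric", mask), "empty")
  expect_error(meanMap(list(p1, strokeMapPair("P", "S2", f1, f1)),
                       "fabric", mask), "mixed stimulus ids")
})

test_that("inter-observer agreement matches its definition", {
  n <- 16
  mask <- matrix(TRUE, n, n)
  f <- matrix(FALSE, n, n); f[1:8, ] <- TRUE
  k <- !f
  a <- strokeMapPair("P1", "S1", f, k)
  b <- strokeMapPair("P2", "S1", f, k)
  expect_equal(interobserverAgreement(list(a, b), mask), 1)
  # complementary observers: one's fabric is the other's contact
  swapped <- strokeMapPair("P3", "S1", k, f)
  expect_equal(interobserverAgreement(list(a, swapped), mask), -1)
  expect_error(interobserverAgreement(list(a), mask), "at least 2")
  # independent brute-force oracle on simulated annotators
  study <- smallStudy(seed = 6)
  sid <- names(bundles(study))[1]
  pairs <- Filter(function(p) stimulusId(p) == sid, strokeMaps(study))
  msk <- analysisMask(bundles(study)[[sid]])
  got <- interobserverAgreement(pairs, msk)
  vecs <- lapply(pairs, function(p)
    c(as.numeric(fabricMap(p)[msk]), as.numeric(contactMap(p)[msk])))
  rs <- c()
  for (i in seq_len(length(vecs) - 1)) for (j in (i + 1):length(vecs)) {
    if (sd(vecs[[i]]) > 0 && sd(vecs[[j]]) > 0)
      rs <- c(rs, sum(scale(vecs[[i]]) * scale(vecs[[j]])) /
                (length(vecs[[i]]) - 1))
  }
  expect_equal(got, mean(rs), tolerance = 1e-12)
  # invariance to observer relabeling
  expect_equal(interobserverAgreement(rev(pairs), msk), got)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  study <- smallStudy(seed = 1)
  masks <- lapply(bundles(study), analysisMask)
  sids <- names(bundles(study))
  maps <- lapply(sids, function(sid)
    meanMap(Filter(function(p) stimulusId(p) == sid, strokeMaps(study)),
            "contact", masks[[sid]]))
  sim <- crossStimulusSimilarity(maps, masks)
  expect_identical(unname(diag(sim$r)), rep(1, length(sids)))
  expect_identical(sim$r, t(sim$r))
  expect_true(all(abs(sim$r) <= 1 + 1e-12))
  # permuted copy of a map decorrelates
  v <- mapValues(maps[[1]])
  set.seed(1)
  vp <- matrix(sample(v), nrow(v))
  mp <- new("MeanMap", stimulusId = "PERM", cause = "contact", values = vp,
            nParticipants = nParticipants(maps[[1]]))
  sim2 <- crossStimulusSimilarity(list(maps[[1]], mp))
  expect_lte(abs(sim2$r[1, 2]), 0.1)
})

test_that("classical MDS reproduces analytic configurations", {
  # all similarities 1: all points coincide
  r1 <- matrix(1, 3, 3)
  # cmdscale warns that the degenerate zero-dissimilarity case has no
  # positive eigenvalues; the embedding is still the coincident-points one
  pts <- suppressWarnings(
    mdsEmbed(structure(list(stimulus_ids = c("a", "b", "c"),
                            cause = "contact", r = r1),
                       class = "SimilarityMatrix")))$points
  expect_lt(max(dist(pts)), 1e-9)
  # two stimuli with r = 0: distance exactly 1
  r0 <- diag(2)
  pts2 <- mdsEmbed(structure(list(stimulus_ids = c("a", "b"),
                                  cause = "contact", r = r0),
                             class = "SimilarityMatrix"))$points
  expect_equal(as.numeric(dist(pts2)), 1, tolerance = 1e-9)
  expect_identical(ncol(pts2), 2L)  # zero-padded to requested dims
  # embedding distances reproduce d = 1 - r on a constructed PSD case
  x <- cbind(c(0, 1, 0.5, 2), c(0, 0, 1, 1))
  d <- as.matrix(dist(x)); d <- d / max(d)
  r <- 1 - d
  fit <- mdsEmbed(r, dims = 2)
  expect_equal(unname(as.matrix(dist(fit$points))), unname(d),
               tolerance = 1e-8)
  expect_error(mdsEmbed(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("weighted depth difference reduces to known cases", {
  n <- 32
  base <- matrix(0, n, n)
  tex <- base; tex[, 17:32] <- 1  # right half elevated
  b <- stimulusBundle("S1", "A", tex, depthTextile = tex, depthBase = base)
  mkMap <- function(v) new("MeanMap", stimulusId = "S1", cause = "contact",
                           values = v, nParticipants = 1L)
  # map nonzero only where textile == base: 0
  v <- matrix(0, n, n); v[, 1:16] <- 1
  expect_identical(weightedDepthDifference(mkMap(v), b), 0)
  # uniform map: plain mean of the gap over the mask
  u <- matrix(0.37, n, n)
  expect_equal(weightedDepthDifference(mkMap(u), b), mean(tex - base))
  # invariant to uniform rescaling of the map; linear in the depths
  v2 <- matrix(runif(n * n), n, n)
  expect_equal(weightedDepthDifference(mkMap(v2), b),
               weightedDepthDifference(mkMap(v2 * 0.25), b))
  b2 <- stimulusBundle("S1", "A", tex, depthTextile = tex * 3,
                       depthBase = base)
  expect_equal(weightedDepthDifference(mkMap(v2), b2),
               3 * weightedDepthDifference(mkMap(v2), b))
  expect_error(weightedDepthDifference(mkMap(matrix(0, n, n)), b),
               "all-zero")
})
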