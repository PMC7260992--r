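# Synthetic drapery generator and simulated observers.
#
# The generator provides the study conditions for every analysis stage:
# smooth random base reliefs, a constrained-diffusion cloth envelope draped
# over them (with known contact regions), Lambertian renderings, a
# deterministic ridge detector that plays the role of the "markable"
# geometric features, simulated painting-task annotators with controllable
# profligacy and label noise, and simulated two-layer depth-profile
# reporters. The default study mirrors the draped-object design: 3 base
# shapes x 4 drapings = 12 stimuli, 20 simulated painters, and 12 simulated
# profilers on 3 raster lines of one draping per base shape.

#' Drape parameters
#'
#' @param nFolds number of oriented sinusoidal fold components added to the
#'   cloth before relaxation.
#' @param foldAmplitude peak height of each fold component, in the same
#'   depth units as the base relief.
#' @param foldWavelengthPx typical fold wavelength in pixels.
#' @param membraneSmoothingIters relaxation iterations of the
#'   constrained-diffusion cloth model.
#' @param contactEpsilon gap (depth units) below which the cloth is counted
#'   as touching the base.
#' @return A list of class \code{"DrapeParams"}.
#' @export
drapeParams <- function(nFolds = 8L, foldAmplitude = 0.5,
                        foldWavelengthPx = 32, membraneSmoothingIters = 20L,
                        contactEpsilon = 0.02) {
  stopifnot(foldAmplitude >= 0, contactEpsilon > 0, foldWavelengthPx > 0)
  structure(list(nFolds = as.integer(nFolds), foldAmplitude = foldAmplitude,
                 foldWavelengthPx = foldWavelengthPx,
                 membraneSmoothingIters = as.integer(membraneSmoothingIters),
                 contactEpsilon = contactEpsilon),
            class = "DrapeParams")
}

#' Simulated-annotator parameters
#'
#' @param markProb probability that a ridge component is painted at all
#'   (controls profligacy).
#' @param labelFlipProb probability that a painted component is assigned to
#'   the wrong cause (label noise).
#' @param strokeDilationPx radius by which painted components are dilated,
#'   emulating stroke width.
#' @param seed integer seed.
#' @return A list of class \code{"ObserverParams"}.
#' @export
observerParams <- function(markProb = 0.7, labelFlipProb = 0.05,
                           strokeDilationPx = 2L, seed = 1L) {
  stopifnot(markProb >= 0, markProb <= 1, labelFlipProb >= 0,
            labelFlipProb <= 1, strokeDilationPx >= 0)
  structure(list(markProb = markProb, labelFlipProb = labelFlipProb,
                 strokeDilationPx = as.integer(strokeDilationPx),
                 seed = as.integer(seed)),
            class = "ObserverParams")
}

#' Generate a smooth random base relief
#'
#' A band-limited height field built from a seeded sum of Gaussian bumps and
#' one oriented ridge, standing in for the unfamiliar cardboard-and-wire
#' reliefs of the painting experiments. Deterministic given (baseId, seed);
#' distinct baseIds give essentially uncorrelated fields.
#'
#' @param baseId character label, e.g. "A".
#' @param seed integer seed.
#' @param size integer (height, width), each >= 64.
#' @param nBumps number of Gaussian bumps.
#' @param amplitude overall height scale; 0 gives a flat field.
#' @return Numeric matrix (height field, min 0).
#' @export
makeBaseShape <- function(baseId, seed, size = c(256L, 256L), nBumps = 10L,
                          amplitude = 1) {
  stopifnot(length(size) == 2L, all(size >= 64L))
  nr <- size[1]; nc <- size[2]
  if (amplitude == 0) return(matrix(0, nr, nc))
  withSeed(deriveSeed(seed, "base", baseId), {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    h <- matrix(0, nr, nc)
    for (i in seq_len(nBumps)) {
      r0 <- stats::runif(1, 0.08 * nr, 0.92 * nr)
      c0 <- stats::runif(1, 0.08 * nc, 0.92 * nc)
      sdev <- stats::runif(1, min(nr, nc) / 16, min(nr, nc) / 8)
      # mostly bumps, occasionally a dimple (reliefs have peaks and dales)
      amp <- stats::runif(1, 0.4, 1) * sample(c(1, 1, -0.7), 1)
      h <- h + amp * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sdev^2))
    }
    # one oriented ridge so bases differ in large-scale anisotropy; random
    # orientation AND offset, so distinct bases share no common structure
    th <- stats::runif(1, 0, pi)
    u <- (cc - stats::runif(1, 0.2 * nc, 0.8 * nc)) * cos(th) +
         (rr - stats::runif(1, 0.2 * nr, 0.8 * nr)) * sin(th)
    h <- h + 0.35 * exp(-u^2 / (2 * (min(nr, nc) / 12)^2))
    h <- h - min(h)
    amplitude * h / max(max(h), .Machine$double.eps)
  })
}

#' Drape a cloth height field over a base relief
#'
#' Constrained-diffusion cloth model: the cloth starts as the base plus a
#' seeded sum of oriented, rectified sinusoidal fold components, then relaxes
#' by repeated local averaging while the base is re-imposed as an obstacle
#' (\code{textile := max(textile, base)}) after every iteration. The fold
#' field is weighted by the cloth's slack, \eqn{(1 - z_{base}/\max
#' z_{base})^2}: where the cloth is stretched tight over high relief it
#' cannot fold, so folds live in the low-lying slack areas - which is what
#' makes the cloth settle onto the base at its peaks. The relaxation limit
#' is a membrane resting on the relief's high points and spanning the
#' valleys; contact is wherever the remaining gap falls below
#' \code{contactEpsilon}.
#'
#' @param base numeric matrix, base height field (finite).
#' @param params a \code{\link{drapeParams}} list.
#' @param seed integer seed for the fold field.
#' @return List with \code{textile} (numeric matrix, >= base everywhere) and
#'   \code{contact} (logical matrix).
#' @export
drapeCloth <- function(base, params = drapeParams(), seed = 1L) {
  if (!all(is.finite(base))) stop("base height field must be finite")
  nr <- nrow(base); nc <- ncol(base)
  folds <- matrix(0, nr, nc)
  if (params$foldAmplitude > 0 && params$nFolds > 0) {
    folds <- withSeed(deriveSeed(seed, "folds"), {
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      f <- matrix(0, nr, nc)
      for (i in seq_len(params$nFolds)) {
        th <- stats::runif(1, 0, pi)
        lam <- params$foldWavelengthPx * stats::runif(1, 0.7, 1.3)
        ph <- stats::runif(1, 0, 2 * pi)
        u <- cc * cos(th) + rr * sin(th)
        # rectified sine: ridge crests with flat troughs, like loose folds
        f <- f + pmax(0, sin(2 * pi * u / lam + ph))^2
      }
      f * (params$foldAmplitude / max(max(f), .Machine$double.eps))
    })
  }
  bmax <- max(base)
  slack <- if (bmax > 0) (1 - base / bmax)^2 else matrix(1, nr, nc)
  textile <- base + folds * slack
  for (i in seq_len(params$membraneSmoothingIters)) {
    textile <- boxBlur3(textile)
    textile <- pmax(textile, base)
  }
  textile <- pmax(textile, base)  # exact constraint even with 0 iterations
  list(textile = textile, contact = (textile - base) < params$contactEpsilon)
}

#' Render a height field as an ideal Lambertian surface
#'
#' Cosine shading from height-field normals computed by central differences:
#' \code{image = max(0, n . l)} with unit normal n and unit light direction
#' l. The light vector lives in (x = column, y = row, z = toward viewer)
#' coordinates.
#'
#' @param height numeric matrix.
#' @param lightDir length-3 numeric, need not be normalized; must be nonzero.
#' @return Numeric matrix with values in [0, 1].
#' @export
renderLambertian <- function(height, lightDir = c(0.3, -0.3, 1)) {
  if (sqrt(sum(lightDir^2)) <= 0) stop("light direction must be nonzero")
  l <- lightDir / sqrt(sum(lightDir^2))
  dzdx <- (shiftMat(height, 0, -1) - shiftMat(height, 0, 1)) / 2
  dzdy <- (shiftMat(height, -1, 0) - shiftMat(height, 1, 0)) / 2
  nrm <- sqrt(dzdx^2 + dzdy^2 + 1)
  img <- (-dzdx * l[1] - dzdy * l[2] + l[3]) / nrm
  pmax(img, 0)
}

#' Detect ridge lines of a height field
#'
#' Negative-second-derivative ridge operator: the field is smoothed at the
#' stated scale, the Hessian is computed by finite differences, and a pixel
#' is a ridge pixel when the smaller Hessian eigenvalue is sufficiently
#' negative and the smoothed height is a local maximum along the
#' corresponding principal-curvature direction. Deterministic.
#'
#' @param textile numeric matrix.
#' @param scale Gaussian smoothing sigma in pixels.
#' @param relThresh curvature threshold as a fraction of the strongest
#'   negative curvature present.
#' @return Logical matrix of ridge pixels.
#' @export
detectRidges <- function(textile, scale = 2, relThresh = 0.1) {
  h <- EBImage::gblur(textile, sigma = scale, boundary = "replicate")
  hx <- (shiftMat(h, 0, -1) - shiftMat(h, 0, 1)) / 2
  hy <- (shiftMat(h, -1, 0) - shiftMat(h, 1, 0)) / 2
  hxx <- shiftMat(h, 0, -1) - 2 * h + shiftMat(h, 0, 1)
  hyy <- shiftMat(h, -1, 0) - 2 * h + shiftMat(h, 1, 0)
  hxy <- (shiftMat(hx, -1, 0) - shiftMat(hx, 1, 0)) / 2
  tr2 <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  lmin <- tr2 - disc
  thr <- relThresh * max(-lmin, 0)
  if (thr <= 0) return(matrix(FALSE, nrow(h), ncol(h)))
  # principal-curvature direction (eigenvector for the most negative
  # eigenvalue), quantized to the nearest 8-neighbor offset
  vx <- hxy
  vy <- lmin - hxx
  flat <- abs(vx) + abs(vy) < 1e-12
  vx[flat] <- 1; vy[flat] <- 0
  ang <- atan2(vy, vx)
  sector <- (round(ang / (pi / 4)) %% 8) + 1
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  ridge <- matrix(FALSE, nrow(h), ncol(h))
  for (s in 1:8) {
    sel <- sector == s & lmin < -thr
    if (!any(sel)) next
    dr <- offs[s, 1]; dc <- offs[s, 2]
    fwd <- shiftMat(h, -dr, -dc)   # value at (r + dr, c + dc)
    bwd <- shiftMat(h, dr, dc)
    ridge[sel] <- h[sel] >= fwd[sel] & h[sel] > bwd[sel]
  }
  # the replicated boundary makes border pixels spurious self-maxima
  margin <- max(2L, ceiling(scale))
  ridge[c(seq_len(margin), nrow(h) - seq_len(margin) + 1L), ] <- FALSE
  ridge[, c(seq_len(margin), ncol(h) - seq_len(margin) + 1L)] <- FALSE
  ridge
}

#' Simulate one painting-task annotator
#'
#' Each connected ridge component is painted with probability
#' \code{markProb}; its true cause is "contact" when at least half of its
#' pixels lie in the ground-truth contact region, and that label is flipped
#' with probability \code{labelFlipProb}. Painted components are dilated by
#' the stroke radius. Deterministic given \code{params$seed}.
#'
#' @param ridgeMap logical matrix of markable ridge pixels.
#' @param contact logical matrix, ground-truth contact region.
#' @param params an \code{\link{observerParams}} list.
#' @param participantId,stimulusId identifiers stored in the result.
#' @return A \linkS4class{StrokeMapPair}.
#' @export
simulateAnnotator <- function(ridgeMap, contact, params = observerParams(),
                              participantId = "sim", stimulusId = "S1") {
  if (!identical(dim(ridgeMap), dim(contact)))
    stop("coregistration error: ridge map and contact map differ in shape")
  lab <- labelComponents(ridgeMap, connectivity = 8)
  ncomp <- max(lab)
  fab <- matrix(FALSE, nrow(ridgeMap), ncol(ridgeMap))
  con <- fab
  if (ncomp > 0) {
    withSeed(deriveSeed(params$seed, "annotator", participantId, stimulusId), {
      marked <- stats::runif(ncomp) < params$markProb
      flipped <- stats::runif(ncomp) < params$labelFlipProb
      contactFrac <- vapply(seq_len(ncomp), function(k)
        mean(contact[lab == k]), numeric(1))
      for (k in seq_len(ncomp)) {
        if (!marked[k]) next
        isContact <- contactFrac[k] >= 0.5
        if (flipped[k]) isContact <- !isContact
        if (isContact) con[lab == k] <- TRUE else fab[lab == k] <- TRUE
      }
    })
    if (params$strokeDilationPx > 0) {
      kern <- diskKernel(params$strokeDilationPx)
      if (any(fab)) fab <- EBImage::dilate(fab * 1, kern) > 0
      if (any(con)) con <- EBImage::dilate(con * 1, kern) > 0
    }
  }
  new("StrokeMapPair", participantId = as.character(participantId),
      stimulusId = as.character(stimulusId), fabric = fab, contact = con)
}

#' Random stroke pair with fixed marked counts
#'
#' Places the requested numbers of marks uniformly at random (without
#' replacement) within the mask, independently for the two maps. This is the
#' "white noise" annotator used as the profligacy-matched null and as the
#' false-positive control.
#'
#' @param mask logical matrix.
#' @param nFabric,nContact marked-pixel counts; each must not exceed the
#'   number of TRUE mask pixels.
#' @param seed integer seed.
#' @param participantId,stimulusId identifiers.
#' @return A \linkS4class{StrokeMapPair}.
#' @export
randomStrokePair <- function(mask, nFabric, nContact, seed = 1L,
                             participantId = "rand", stimulusId = "S1") {
  idx <- which(mask)
  nMax <- length(idx)
  if (nFabric > nMax || nContact > nMax)
    stop("marked counts exceed the number of mask pixels")
  withSeed(deriveSeed(seed, "randpair", participantId, stimulusId), {
    fab <- matrix(FALSE, nrow(mask), ncol(mask))
    con <- fab
    if (nFabric > 0) fab[idx[sample.int(nMax, nFabric)]] <- TRUE
    if (nContact > 0) con[idx[sample.int(nMax, nContact)]] <- TRUE
    new("StrokeMapPair", participantId = as.character(participantId),
        stimulusId = as.character(stimulusId), fabric = fab, contact = con)
  })
}

#' Simulate one two-layer depth-profile reporter
#'
#' Samples control points along the true textile and base profiles of one
#' raster line and perturbs them with smooth additive noise whose standard
#' deviation is \code{noiseSd} times the profile range. The hidden base
#' layer is not reported from its true relief: observers can only see it at
#' the contact regions, so the simulated percept blends the true relief with
#' a linear interpolation of the base depth between contact columns (a
#' low-pass fallback is used when a line has fewer than two contact
#' columns). The interpolation weight is \code{min(1, noiseSd / 0.1)}: an
#' ideal (noise-free) observer reports the relief veridically, while at the
#' default noise level and above the hidden spans are reported purely by
#' interpolation. The base layer also receives \code{baseNoiseFactor} times
#' the textile's noise. Both layers therefore converge to the truth as
#' \code{noiseSd} goes to 0, and the base layer is strictly harder at any
#' positive noise.
#'
#' @param bundle a \linkS4class{StimulusBundle}.
#' @param row raster row (1-based, inside the raster).
#' @param noiseSd noise standard deviation as a fraction of profile range.
#' @param nControlPoints number of control points per contour (>= 2).
#' @param seed integer seed.
#' @param contactEpsilon gap below which the base is visible at a column.
#' @param baseNoiseFactor multiplier on the base layer's noise.
#' @param participantId identifier.
#' @return A \linkS4class{ProfilePair}.
#' @export
simulateProfiler <- function(bundle, row, noiseSd = 0.1,
                             nControlPoints = 24L, seed = 1L,
                             contactEpsilon = 0.02, baseNoiseFactor = 1.5,
                             participantId = "simP") {
  nr <- nrow(bundle@image); w <- ncol(bundle@image)
  if (row < 1L || row > nr) stop("raster row outside the raster")
  stopifnot(nControlPoints >= 2L)
  truthT <- bundle@depthTextile[row, ]
  truthB <- bundle@depthBase[row, ]
  visible <- which(truthT - truthB < contactEpsilon)
  if (length(visible) >= 2L) {
    interpB <- stats::approx(visible, truthB[visible],
                             xout = seq_len(w), rule = 2)$y
  } else {
    # no contact along this line: fall back to a heavily smoothed percept
    win <- max(3L, round(w / 6)); if (win %% 2L == 0L) win <- win + 1L
    pad <- (win - 1L) %/% 2L
    padded <- c(rep(truthB[1], pad), truthB, rep(truthB[w], pad))
    sm <- stats::filter(padded, rep(1 / win, win), sides = 2)
    interpB <- as.numeric(sm[pad + seq_len(w)])
  }
  lambda <- min(1, noiseSd / 0.1)
  perceivedB <- (1 - lambda) * truthB + lambda * interpB
  xs <- round(seq(1, w, length.out = nControlPoints))
  xs <- unique(xs)
  withSeed(deriveSeed(seed, "profiler", participantId, bundle@stimulusId, row), {
    smoothNoise <- function(sdev) {
      if (sdev <= 0) return(numeric(length(xs)))
      nKnots <- max(4L, min(8L, length(xs)))
      kx <- seq(1, w, length.out = nKnots)
      ky <- stats::rnorm(nKnots)
      z <- stats::spline(kx, ky, xout = xs)$y
      s <- stats::sd(z)
      if (!is.finite(s) || s <= 0) return(numeric(length(xs)))
      z / s * sdev
    }
    rngT <- max(diff(range(truthT)), .Machine$double.eps)
    rngB <- max(diff(range(truthB)), .Machine$double.eps)
    yT <- truthT[xs] + smoothNoise(noiseSd * rngT)
    yB <- perceivedB[xs] + smoothNoise(baseNoiseFactor * noiseSd * rngB)
    profilePair(participantId, bundle@stimulusId, row,
                cbind(x = xs, y = yT), cbind(x = xs, y = yB))
  })
}

#' Choose raster lines with maximal two-layer separation variance
#'
#' Mirrors the experimental design of selecting rows with substantial
#' variation in the distance between the underlying and overlying surfaces:
#' rows are ranked by the variance of the depth gap, and only rows whose gap
#' actually ranges from contact to clear separation (between 5\% and 95\%
#' contact columns) are eligible, falling back to the plain variance ranking
#' if too few rows qualify.
#'
#' @param bundle a \linkS4class{StimulusBundle}.
#' @param n number of rows.
#' @param minSepFrac minimum separation between chosen rows as a fraction of
#'   image height.
#' @param contactEpsilon gap below which a column counts as contact.
#' @return Integer vector of rows.
#' @export
chooseRasterRows <- function(bundle, n = 3L, minSepFrac = 1 / 8,
                             contactEpsilon = 0.02) {
  gap <- bundle@depthTextile - bundle@depthBase
  gap[!bundle@mask] <- NA
  v <- apply(gap, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  cfrac <- rowMeans(gap < contactEpsilon, na.rm = TRUE)
  eligible <- is.finite(v) & cfrac >= 0.05 & cfrac <= 0.95
  minSep <- max(1L, round(minSepFrac * nrow(gap)))
  pick <- function(cand, rows) {
    for (r in cand) {
      if (all(abs(r - rows) >= minSep)) rows <- c(rows, r)
      if (length(rows) == n) break
    }
    rows
  }
  rows <- pick(which(eligible)[order(v[eligible], decreasing = TRUE)],
               integer(0))
  if (length(rows) < n)
    rows <- pick(order(v, decreasing = TRUE), rows)
  sort(rows)
}

#' Simulate a complete scission study
#'
#' Builds the default synthetic analogue of the draped-object experiments:
#' \code{nBases} base shapes x \code{drapesPerBase} drapings, rendered and
#' annotated by \code{nObservers} simulated painters, plus \code{nProfilers}
#' simulated profile reporters on \code{rowsPerStimulus} raster lines of the
#' first draping of each base shape.
#'
#' @param seed integer master seed.
#' @param nBases,drapesPerBase,nObservers study design.
#' @param size raster size (height, width).
#' @param drape a \code{\link{drapeParams}} list.
#' @param observer an \code{\link{observerParams}} list (its seed is
#'   overridden per participant from the master seed).
#' @param nProfilers,rowsPerStimulus,profileNoiseSd profile-task design.
#' @param lightDir rendering light direction.
#' @return A \linkS4class{ScissionStudy}.
#' @examples
#' study <- simulateStudy(seed = 1, nBases = 2, drapesPerBase = 2,
#'                        nObservers = 4, size = c(64, 64), nProfilers = 3)
#' @export
simulateStudy <- function(seed = 1L, nBases = 3L, drapesPerBase = 4L,
                          nObservers = 20L, size = c(256L, 256L),
                          drape = drapeParams(), observer = observerParams(),
                          nProfilers = 12L, rowsPerStimulus = 3L,
                          profileNoiseSd = 0.1,
                          lightDir = c(0.3, -0.3, 1)) {
  if (nObservers < 1L) stop("study needs at least one observer")
  baseIds <- LETTERS[seq_len(nBases)]
  bundlesL <- list()
  ridgeMaps <- list()
  for (b in baseIds) {
    base <- makeBaseShape(b, seed, size = size)
    for (d in seq_len(drapesPerBase)) {
      sid <- paste0(b, d)
      dr <- drapeCloth(base, drape, seed = deriveSeed(seed, "drape", sid))
      img <- renderLambertian(dr$textile, lightDir)
      bundlesL[[sid]] <- stimulusBundle(sid, b, img,
                                        depthTextile = dr$textile,
                                        depthBase = base)
      ridgeMaps[[sid]] <- detectRidges(dr$textile)
    }
  }
  strokes <- list()
  for (i in seq_len(nObservers)) {
    pid <- sprintf("P%02d", i)
    for (sid in names(bundlesL)) {
      op <- observer
      op$seed <- deriveSeed(seed, "observer", pid)
      bnd <- bundlesL[[sid]]
      contact <- (bnd@depthTextile - bnd@depthBase) < drape$contactEpsilon
      strokes[[length(strokes) + 1L]] <-
        simulateAnnotator(ridgeMaps[[sid]], contact, op,
                          participantId = pid, stimulusId = sid)
    }
  }
  profiles <- list()
  design <- data.frame(stimulus_id = character(0), raster_row = integer(0))
  if (nProfilers > 0L && rowsPerStimulus > 0L) {
    profStimuli <- paste0(baseIds, 1L)
    for (sid in profStimuli) {
      rows <- chooseRasterRows(bundlesL[[sid]], n = rowsPerStimulus)
      for (r in rows) {
        design <- rbind(design,
                        data.frame(stimulus_id = sid, raster_row = r))
        for (i in seq_len(nProfilers)) {
          pid <- sprintf("Q%02d", i)
          profiles[[length(profiles) + 1L]] <-
            simulateProfiler(bundlesL[[sid]], r, noiseSd = profileNoiseSd,
                             seed = deriveSeed(seed, "profiles"),
                             participantId = pid)
        }
      }
    }
  }
  new("ScissionStudy", bundles = bundlesL, strokes = strokes,
      profiles = profiles, profileDesign = design, seed = as.integer(seed),
      params = list(nBases = nBases, drapesPerBase = drapesPerBase,
                    nObservers = nObservers, size = size, drape = drape,
                    observer = observer, nProfilers = nProfilers,
                    rowsPerStimulus = rowsPerStimulus,
                    profileNoiseSd = profileNoiseSd))
}
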