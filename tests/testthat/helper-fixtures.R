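# Shared fixtures: all built in code at test time.

# Wrap a logical mask as a region record like segmentMeanMap produces.
mkRegion <- function(mask, sid = "S1", cause = "contact") {
  px <- which(mask, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  list(stimulusId = sid, cause = cause, label = 1L, pixels = px,
       dim = dim(mask), centroid = colMeans(px))
}

# Independent connected-component oracle: plain BFS flood fill,
# deliberately sharing no code with labelComponents().
floodFillLabels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0L) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[k, 1]; cc <- cur[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# Random plateau map: k rectangular plateaus of value 1 on a zero
# background; returns list(values, nPlateaus) where nPlateaus counts the
# plateaus actually distinct after placement (merged rectangles counted by
# the flood-fill oracle downstream).
makePlateauMap <- function(n = 96L, k = 2L, minSize = 14L, maxSize = 24L,
                           seed = 1L) {
  set.seed(seed)
  v <- matrix(0, n, n)
  for (i in seq_len(k)) {
    h <- sample(minSize:maxSize, 1); w <- sample(minSize:maxSize, 1)
    r0 <- sample(seq_len(n - h), 1); c0 <- sample(seq_len(n - w), 1)
    v[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1
  }
  v
}

# A filled disk mask.
diskMask <- function(n, r0, c0, radius) {
  m <- matrix(FALSE, n, n)
  for (r in seq_len(n)) for (c in seq_len(n))
    if ((r - r0)^2 + (c - c0)^2 <= radius^2) m[r, c] <- TRUE
  m
}

# A thick Y mask: three arms of the given length/halfwidth at angles
# rot, rot +/- 120 degrees from the center of an n x n frame.
yMask <- function(n = 120L, rot = 0, len = 40, halfwidth = 4) {
  m <- matrix(FALSE, n, n)
  ctr <- n / 2
  for (ang in rot + c(0, 2 * pi / 3, -2 * pi / 3)) {
    for (t in seq(0, len, by = 0.25)) {
      r <- round(ctr - t * cos(ang)); c <- round(ctr + t * sin(ang))
      for (dr in -halfwidth:halfwidth) for (dc in -halfwidth:halfwidth) {
        if (dr^2 + dc^2 > halfwidth^2) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= n) m[rr, cc] <- TRUE
      }
    }
  }
  m
}

# Flat-depth bundle wrapper for feature tests on constructed masks.
flatBundle <- function(n, depthT = 1, depthB = 0, sid = "S1") {
  stimulusBundle(sid, "X", matrix(0.5, n, n),
                 depthTextile = matrix(depthT, n, n),
                 depthBase = matrix(depthB, n, n))
}

# Small synthetic study used by several test files (memoised per session).
.studyCache <- new.env()
smallStudy <- function(seed = 1L, ...) {
  key <- paste0("s", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- simulateStudy(seed = seed, nBases = 3,
                                        drapesPerBase = 2, nObservers = 6,
                                        size = c(96, 96), nProfilers = 6, ...)
  .studyCache[[key]]
}
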