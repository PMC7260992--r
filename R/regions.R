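# Segmentation of consistently-marked regions and the 24 candidate region
# features (shape, depth and skeleton summary statistics).
#
# The segmentation pipeline is fixed: Gaussian blur (sigma 10 px) -> square
# (to emphasize higher values) -> min-max normalize to [0, 1] -> threshold
# at 0.3 -> binary opening with a radius-1 disk -> 8-connected components.
#
# Skeleton features are computed on a pruned medial-axis (thinning) skeleton
# organised as a branch tree; this replaces the MAP-skeleton toolbox the
# original analyses used, since the classifier consumes only the scalar
# branch-tree summaries, which are well defined on any pruned skeleton.

#' Names of the 24 candidate region features
#'
#' @return Character vector in canonical (tie-breaking) order.
#' @export
regionFeatureNames <- function() c(
  "Area", "Orientation", "Eccentricity", "Perimeter", "Solidity",
  "perimAreaRatio", "Peripherality", "meanDepths", "stdDepths",
  "depthDifferences", "skelNumBranches", "skelMaxDepth", "skelMeanDepth",
  "skelMeanBranchAngle", "skelMeanBranchPointDist",
  "skelMeanRelBranchLength", "skelTotalAbsTurnAngle",
  "skelTotalSignedTurnAngle", "skelMeanAbsTurnAngle", "skelStdAbsTurnAngle",
  "skelSkewAbsTurnAngle", "skelTotalLength", "skelMeanBranchLength",
  "skelStdBranchLength")

#' The fixed seven-feature classifier subset
#'
#' The reference subset of features used for causal classification when the
#' data-driven ranking is bypassed: orientation, eccentricity, solidity, the
#' three depth features and the mean branch angle.
#'
#' @return Character vector of 7 feature names.
#' @export
referenceSvmFeatures <- function() c(
  "Orientation", "Eccentricity", "Solidity", "meanDepths", "stdDepths",
  "depthDifferences", "skelMeanBranchAngle")

#' Segment consistently-marked regions from a mean map
#'
#' Applies the fixed preprocessing pipeline (blur, square, normalize,
#' threshold, opening) and labels 8-connected components. A constant map
#' cannot be normalized and yields zero regions with a warning.
#'
#' @param map a \linkS4class{MeanMap} (values in [0, 1]).
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return List of regions; each region is a list with fields
#'   \code{stimulusId}, \code{cause}, \code{label}, \code{pixels} (n x 2
#'   integer matrix of (row, col)), \code{dim} and \code{centroid}.
#' @export
segmentMeanMap <- function(map, cfg = analysisConfig()) {
  v <- map@values
  if (diff(range(v)) <= 0) {
    warning("constant mean map: normalization undefined, zero regions")
    return(list())
  }
  b <- EBImage::gblur(v, sigma = cfg@blurSigmaPx, boundary = "replicate")
  b <- b^2
  b <- normalize01(b)
  if (is.null(b)) {
    warning("blurred map is constant: zero regions")
    return(list())
  }
  bin <- b >= cfg@binarizeThreshold
  if (cfg@openingRadiusPx > 0 && any(bin))
    bin <- EBImage::opening(bin * 1, diamondKernel(cfg@openingRadiusPx)) > 0
  lab <- labelComponents(bin, connectivity = 8)
  n <- max(lab)
  lapply(seq_len(n), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    list(stimulusId = map@stimulusId, cause = map@cause, label = k,
         pixels = px, dim = dim(v), centroid = colMeans(px))
  })
}

# --- thinning -------------------------------------------------------------

# Zhang-Suen thinning of a binary matrix; returns a logical skeleton.
thinBinary <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask))
  # ring order N, NE, E, SE, S, SW, W, NW as (row, col) offsets
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(1:8, function(i)
        shiftMat0(m, -offs[i, 1], -offs[i, 2]))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8L) 1L else i + 1L
        A <- A + (nb[[i]] == 0L & nb[[j]] == 1L)
      }
      if (step == 1L) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L  # N*E*S
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L  # E*S*W
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L  # N*E*W
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L  # N*S*W
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Reduce a thinned skeleton to a minimal 8-connected set: sequentially
# remove any non-endpoint pixel whose marked neighbors remain mutually
# 8-connected without it (staircase doubles and redundant corners), so the
# branch decomposition is not fragmented by spurious unit junctions.
cleanSkeleton <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    idx <- which(skel, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      if (!skel[r, c]) next
      nbr <- matrix(0L, 0, 2)
      for (k in 1:8) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc])
          nbr <- rbind(nbr, c(rr, cc))
      }
      b <- nrow(nbr)
      if (b < 2L) next
      # are the neighbors one 8-connected component among themselves?
      comp <- rep(0L, b); comp[1] <- 1L
      queue <- 1L
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (v in seq_len(b)) {
          if (comp[v] == 0L &&
              max(abs(nbr[u, ] - nbr[v, ])) <= 1L) {
            comp[v] <- 1L; queue <- c(queue, v)
          }
        }
      }
      if (all(comp == 1L)) { skel[r, c] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  skel
}

# --- skeleton graph -------------------------------------------------------

# Adjacency of skeleton pixels (8-connectivity). coords: n x 2 matrix.
skelAdjacency <- function(coords, dims) {
  n <- nrow(coords)
  lin <- (coords[, 2] - 1L) * dims[1] + coords[, 1]
  id <- integer(dims[1] * dims[2])
  id[lin] <- seq_len(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- coords[i, 1]; c <- coords[i, 2]
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > dims[1] || cc < 1 || cc > dims[2]) next
      k <- id[(cc - 1L) * dims[1] + rr]
      if (k > 0L) out <- c(out, k)
    }
    nbrs[[i]] <- out
  }
  nbrs
}

stepLen <- function(a, b) sqrt(sum((a - b)^2))

# Decompose a skeleton (coords + adjacency) into branches: maximal paths
# between critical nodes (degree != 2). Returns list of integer index paths.
traceBranchPaths <- function(coords, nbrs) {
  n <- nrow(coords)
  deg <- lengths(nbrs)
  critical <- which(deg != 2L)
  if (length(critical) == 0L && n > 0L) critical <- 1L  # pure cycle
  paths <- list()
  seen <- new.env(hash = TRUE)
  edgeKey <- function(a, b) paste0(a, "_", b)
  for (s in critical) {
    if (deg[s] == 0L) {
      paths[[length(paths) + 1L]] <- s  # isolated pixel
      next
    }
    for (nb in nbrs[[s]]) {
      if (!is.null(seen[[edgeKey(s, nb)]])) next
      path <- c(s, nb)
      seen[[edgeKey(s, nb)]] <- TRUE
      seen[[edgeKey(nb, s)]] <- TRUE
      prev <- s; cur <- nb
      while (deg[cur] == 2L && cur != s) {
        nxt <- setdiff(nbrs[[cur]], prev)
        if (length(nxt) == 0L) break
        nxt <- nxt[1]
        seen[[edgeKey(cur, nxt)]] <- TRUE
        seen[[edgeKey(nxt, cur)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}

pathLength <- function(coords, path) {
  if (length(path) < 2L) return(0)
  sum(vapply(seq_len(length(path) - 1L), function(i)
    stepLen(coords[path[i], ], coords[path[i + 1L], ]), numeric(1)))
}

# Iteratively remove terminal spurs shorter than prunePx. Keeps at least
# one branch.
pruneSkeleton <- function(skel, prunePx) {
  repeat {
    coords <- which(skel, arr.ind = TRUE)
    if (nrow(coords) == 0L) return(skel)
    nbrs <- skelAdjacency(coords, dim(skel))
    paths <- traceBranchPaths(coords, nbrs)
    if (length(paths) <= 1L) return(skel)
    deg <- lengths(nbrs)
    removed <- FALSE
    for (p in paths) {
      len <- pathLength(coords, p)
      endA <- p[1]; endB <- p[length(p)]
      terminal <- deg[endA] == 1L || deg[endB] == 1L
      if (terminal && len < prunePx) {
        drop <- p
        # keep the junction end so the rest of the skeleton stays connected
        if (deg[endA] > 1L) drop <- drop[-1L]
        if (deg[endB] > 1L) drop <- drop[-length(drop)]
        if (length(drop) == 0L) next
        skel[coords[drop, , drop = FALSE]] <- FALSE
        removed <- TRUE
        break  # re-derive adjacency after each removal
      }
    }
    if (!removed) return(skel)
  }
}

# Longest geodesic path through the skeleton (pixel indices), by double BFS
# (Dijkstra with 1 / sqrt(2) weights).
longestSkelPath <- function(coords, nbrs) {
  n <- nrow(coords)
  dijkstra <- function(src) {
    dist <- rep(Inf, n); dist[src] <- 0
    parent <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    for (iter in seq_len(n)) {
      u <- which.min(ifelse(visited, Inf, dist))
      if (!is.finite(dist[u])) break
      visited[u] <- TRUE
      for (v in nbrs[[u]]) {
        w <- stepLen(coords[u, ], coords[v, ])
        if (dist[u] + w < dist[v]) { dist[v] <- dist[u] + w; parent[v] <- u }
      }
    }
    list(dist = dist, parent = parent)
  }
  a <- dijkstra(1L)
  u <- which.max(ifelse(is.finite(a$dist), a$dist, -Inf))
  b <- dijkstra(u)
  v <- which.max(ifelse(is.finite(b$dist), b$dist, -Inf))
  path <- v
  while (!is.na(b$parent[path[1]])) path <- c(b$parent[path[1]], path)
  path
}

# Direction (unit vector) of a path's initial stretch, from a principal-
# component line fit over up to k+1 pixels (robust to grid quantization),
# sign-aligned with the endpoint difference. The first `skip` pixels are
# excluded when the path is long enough: the medial axis bends inside a
# junction zone, which would bias the tangent.
pathDirection <- function(coords, path, k = 10L, skip = 3L) {
  n <- length(path)
  if (n - 1L < skip + 2L) skip <- 0L
  idx <- path[(1L + skip):min(n, 1L + skip + k)]
  if (length(idx) < 2L) return(c(0, 0))
  pts <- coords[idx, , drop = FALSE]
  d <- pts[nrow(pts), ] - pts[1L, ]
  if (sum(d^2) <= 0) return(c(0, 0))
  ctr <- sweep(pts, 2, colMeans(pts))
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  if (sum(v * d) < 0) v <- -v
  v
}

#' Skeletonize a segmented region into a branch tree
#'
#' Thins the filled region to a medial-axis skeleton, removes spurs shorter
#' than \code{prunePx}, decomposes the result into branches at junction
#' points, and roots the branch tree at the branch containing the midpoint
#' of the skeleton's longest geodesic path. Deterministic. Regions thinner
#' than the pruning scale degenerate to a single-branch skeleton, which is
#' allowed.
#'
#' @param region a region record from \code{\link{segmentMeanMap}}.
#' @param prunePx spur-pruning threshold in pixels.
#' @return A \linkS4class{SkeletonGraph}.
#' @export
skeletonizeRegion <- function(region, prunePx = 5) {
  dims <- region$dim
  px <- region$pixels
  # work in a padded bounding box for speed
  r0 <- max(1L, min(px[, 1]) - 2L); r1 <- min(dims[1], max(px[, 1]) + 2L)
  c0 <- max(1L, min(px[, 2]) - 2L); c1 <- min(dims[2], max(px[, 2]) + 2L)
  sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
  skel <- thinBinary(sub)
  skel <- cleanSkeleton(skel)
  skel <- pruneSkeleton(skel, prunePx)
  coords <- which(skel, arr.ind = TRUE)
  if (nrow(coords) == 0L) {  # degenerate: fall back to the region centroid
    coords <- matrix(round(colMeans(cbind(px[, 1] - r0 + 1L,
                                          px[, 2] - c0 + 1L))), 1, 2)
  }
  nbrs <- skelAdjacency(coords, dim(skel))
  deg <- lengths(nbrs)
  # junction pixels that touch each other act as ONE junction: cluster them
  # so a thick meeting point does not fragment the arms into mini-branches
  clusterOf <- rep(0L, nrow(coords))
  nextCluster <- 0L
  for (i in which(deg >= 3L)) {
    if (clusterOf[i] > 0L) next
    nextCluster <- nextCluster + 1L
    clusterOf[i] <- nextCluster
    queue <- i
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nbrs[[u]]) {
        if (deg[v] >= 3L && clusterOf[v] == 0L) {
          clusterOf[v] <- nextCluster
          queue <- c(queue, v)
        }
      }
    }
  }
  nodeKey <- function(i) {
    if (clusterOf[i] > 0L) paste0("J", clusterOf[i]) else paste0("P", i)
  }
  paths <- traceBranchPaths(coords, nbrs)
  # drop tiny intra-junction connectors (both ends in the same cluster)
  paths <- Filter(function(p) {
    a <- p[1]; b <- p[length(p)]
    !(clusterOf[a] > 0L && clusterOf[a] == clusterOf[b] && length(p) <= 3L)
  }, paths)
  if (length(paths) == 0L) paths <- list(1L)
  # root branch: the one containing the midpoint of the longest path
  main <- longestSkelPath(coords, nbrs)
  cum <- c(0, cumsum(vapply(seq_len(max(length(main) - 1L, 0L)), function(i)
    stepLen(coords[main[i], ], coords[main[i + 1L], ]), numeric(1))))
  midNode <- main[which.min(abs(cum - cum[length(cum)] / 2))]
  inBranch <- vapply(paths, function(p) midNode %in% p, logical(1))
  rootIdx <- if (any(inBranch)) which(inBranch)[1] else 1L
  # breadth-first orientation of the branch tree via shared end nodes
  # (junction clusters count as shared nodes)
  nb <- length(paths)
  branchRec <- vector("list", nb)
  assigned <- rep(FALSE, nb)
  rootPath <- paths[[rootIdx]]
  # orient the root deterministically: start at its lexicographically
  # smaller end pixel
  eA <- coords[rootPath[1], ]; eB <- coords[rootPath[length(rootPath)], ]
  if (eB[1] < eA[1] || (eB[1] == eA[1] && eB[2] < eA[2]))
    rootPath <- rev(rootPath)
  branchRec[[rootIdx]] <- list(path = rootPath, depth = 1L,
                               parent = NA_integer_)
  assigned[rootIdx] <- TRUE
  queue <- rootIdx
  while (length(queue)) {
    bi <- queue[1]; queue <- queue[-1]
    bp <- branchRec[[bi]]$path
    attachKeys <- c(nodeKey(bp[1]), nodeKey(bp[length(bp)]))
    for (bj in seq_len(nb)) {
      if (assigned[bj]) next
      pj <- paths[[bj]]
      endKeys <- c(nodeKey(pj[1]), nodeKey(pj[length(pj)]))
      hit <- which(endKeys %in% attachKeys)
      if (length(hit) == 0L) next
      if (hit[1] == 2L) pj <- rev(pj)
      branchRec[[bj]] <- list(path = pj,
                              depth = branchRec[[bi]]$depth + 1L,
                              parent = bi)
      assigned[bj] <- TRUE
      queue <- c(queue, bj)
    }
  }
  # any branches disconnected from the root's component: own roots (rare)
  for (bj in which(!assigned)) {
    branchRec[[bj]] <- list(path = paths[[bj]], depth = 1L,
                            parent = NA_integer_)
    assigned[bj] <- TRUE
  }
  # finalize: lengths, angles from parent, branch-point distances
  branches <- vector("list", nb)
  for (bi in seq_len(nb)) {
    rec <- branchRec[[bi]]
    p <- rec$path
    len <- pathLength(coords, p)
    angle <- NA_real_
    bpd <- NA_real_
    if (!is.na(rec$parent)) {
      pp <- branchRec[[rec$parent]]$path
      attach <- p[1]
      pos <- match(attach, pp)
      if (is.na(pos)) {
        # attachment via a junction cluster: use the parent's nearer end
        dHead <- stepLen(coords[attach, ], coords[pp[1], ])
        dTail <- stepLen(coords[attach, ], coords[pp[length(pp)], ])
        pos <- if (dHead < dTail) 1L else length(pp)
      }
      if (!is.na(pos)) {
        bpd <- if (pos == 1L) 0 else
          pathLength(coords, pp[seq_len(pos)])
        # parent tangent at the attachment, directed proximal -> distal
        if (pos == 1L) {
          dirParent <- pathDirection(coords, pp)
        } else {
          tailStart <- max(1L, pos - 10L)
          dirParent <- -pathDirection(coords, rev(pp[tailStart:pos]))
        }
        dirChild <- pathDirection(coords, p)
        if (sum(dirParent^2) > 0 && sum(dirChild^2) > 0) {
          cosang <- sum(dirParent * dirChild)
          cosang <- min(1, max(-1, cosang))
          angle <- acos(cosang) * 180 / pi
        }
      }
    }
    branches[[bi]] <- list(
      coords = coords[p, , drop = FALSE] + c(r0 - 1L, c0 - 1L)[col(coords[p, , drop = FALSE])],
      length = len, depth = rec$depth, parent = rec$parent,
      angleFromParent = angle, branchPointDist = bpd)
  }
  total <- sum(vapply(branches, `[[`, numeric(1), "length"))
  globalCoords <- cbind(coords[, 1] + r0 - 1L, coords[, 2] + c0 - 1L)
  new("SkeletonGraph", pixels = globalCoords, branches = branches,
      rootBranch = as.integer(rootIdx), totalLength = total)
}

# Signed turning angles (degrees) along a branch polyline, resampled at
# ~2 px arclength steps to soften the 45-degree grid quantization.
branchTurnAngles <- function(coordsMat, step = 2) {
  n <- nrow(coordsMat)
  if (n < 3L) return(numeric(0))
  seg <- sqrt(rowSums((coordsMat[-1, , drop = FALSE] -
                       coordsMat[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[n] < 2 * step) return(numeric(0))
  t <- seq(0, s[n], by = step)
  x <- stats::approx(s, coordsMat[, 1], xout = t)$y
  y <- stats::approx(s, coordsMat[, 2], xout = t)$y
  dx <- diff(x); dy <- diff(y)
  k <- length(dx)
  if (k < 2L) return(numeric(0))
  cross <- dx[-k] * dy[-1] - dy[-k] * dx[-1]
  dot <- dx[-k] * dx[-1] + dy[-k] * dy[-1]
  atan2(cross, dot) * 180 / pi
}

# Scalar summaries of a SkeletonGraph (the 14 skeleton features).
skeletonStatistics <- function(skel) {
  br <- skel@branches
  lens <- vapply(br, `[[`, numeric(1), "length")
  depths <- vapply(br, `[[`, numeric(1), "depth")
  angles <- vapply(br, `[[`, numeric(1), "angleFromParent")
  bpds <- vapply(br, `[[`, numeric(1), "branchPointDist")
  total <- skel@totalLength
  turns <- unlist(lapply(br, function(b) branchTurnAngles(b$coords)))
  absTurns <- abs(turns)
  meanOrNA <- function(x) if (length(x[is.finite(x)])) mean(x, na.rm = TRUE) else NA_real_
  c(skelNumBranches = length(br),
    skelMaxDepth = max(depths),
    skelMeanDepth = mean(depths),
    skelMeanBranchAngle = meanOrNA(angles),
    skelMeanBranchPointDist = meanOrNA(bpds),
    skelMeanRelBranchLength = if (total > 0) mean(lens / total) else NA_real_,
    skelTotalAbsTurnAngle = if (length(turns)) sum(absTurns) else NA_real_,
    skelTotalSignedTurnAngle = if (length(turns)) sum(turns) else NA_real_,
    skelMeanAbsTurnAngle = if (length(turns)) mean(absTurns) else NA_real_,
    skelStdAbsTurnAngle = if (length(absTurns) > 1) stats::sd(absTurns) else NA_real_,
    skelSkewAbsTurnAngle = momentSkewness(absTurns),
    skelTotalLength = total,
    skelMeanBranchLength = mean(lens),
    skelStdBranchLength = if (length(lens) > 1) stats::sd(lens) else NA_real_)
}

# Perimeter of a region mask: length of the closed oriented contour
# polyline traced through boundary pixel centers.
regionPerimeter <- function(mask) {
  if (sum(mask) <= 1L) return(0)
  oc <- EBImage::ocontour(mask * 1)
  if (length(oc) == 0L) return(0)
  p <- oc[[1]]
  if (nrow(p) < 2L) return(0)
  closed <- rbind(p, p[1, ])
  sum(sqrt(rowSums((closed[-1, , drop = FALSE] -
                    closed[-nrow(closed), , drop = FALSE])^2)))
}

#' Compute the 24 candidate features of a region
#'
#' Shape features (area, best-fitting-ellipse orientation and eccentricity,
#' perimeter, solidity, perimeter/area ratio, centroid distance from image
#' center), depth features computed from the bundle's ground-truth geometry
#' (mean and SD of the visible textile depth within the region, and the mean
#' textile-minus-base depth difference), and the skeleton branch-tree
#' summaries. Angles are reported in degrees; orientation follows the
#' best-fitting-ellipse convention, degrees in (-90, 90] from the image
#' x-axis (y up). Undefined values are recorded as NA and imputed later.
#'
#' @param region a region record from \code{\link{segmentMeanMap}}.
#' @param bundle the matching \linkS4class{StimulusBundle}.
#' @param skeleton a \linkS4class{SkeletonGraph}; computed on demand when
#'   omitted.
#' @return One-row data.frame: stimulus_id, cause, label, the 24 features.
#' @export
computeRegionFeatures <- function(region, bundle, skeleton = NULL) {
  if (is.null(skeleton)) skeleton <- skeletonizeRegion(region)
  px <- region$pixels
  n <- nrow(px)
  dims <- region$dim
  # moments with x = col, y = -row (image y-axis points down)
  x <- px[, 2]; y <- -px[, 1]
  mx <- mean(x); my <- mean(y)
  # 1/12 term: variance of a unit pixel, matching the ellipse convention
  mu20 <- mean((x - mx)^2) + 1 / 12
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else NA_real_
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (orient <= -90) orient <- orient + 180
  if (orient > 90) orient <- orient - 180
  sub <- matrix(FALSE, dims[1], dims[2])
  sub[px] <- TRUE
  perim <- regionPerimeter(sub)
  # convex hull over pixel corners so a filled rectangle has solidity 1
  corners <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] - 0.5, px[, 2] + 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  hullArea <- tryCatch({
    h <- grDevices::chull(corners)
    polygonArea(corners[h, , drop = FALSE])
  }, error = function(e) NA_real_)
  solidity <- if (is.finite(hullArea) && hullArea > 0)
    min(1, n / hullArea) else NA_real_
  center <- c((dims[1] + 1) / 2, (dims[2] + 1) / 2)
  periph <- sqrt(sum((region$centroid - center)^2))
  dt <- bundle@depthTextile[px]
  gap <- (bundle@depthTextile - bundle@depthBase)[px]
  feats <- c(Area = n, Orientation = orient, Eccentricity = ecc,
             Perimeter = perim, Solidity = solidity,
             perimAreaRatio = perim / n, Peripherality = periph,
             meanDepths = mean(dt),
             stdDepths = if (n > 1) stats::sd(dt) else NA_real_,
             depthDifferences = mean(gap),
             skeletonStatistics(skeleton))
  out <- data.frame(stimulus_id = region$stimulusId, cause = region$cause,
                    label = region$label, t(feats))
  rownames(out) <- NULL
  out
}

#' Assemble the region feature table for a whole study
#'
#' Builds the contact and fabric mean maps of every stimulus, segments them,
#' and computes the 24 features for each region, attaching the cause label
#' (which map the region came from). The row count is reported as the
#' \code{"nRegions"} attribute.
#'
#' @param study a \linkS4class{ScissionStudy}.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @param prunePx skeleton spur-pruning threshold.
#' @return data.frame, one row per region per cause-map per stimulus.
#' @export
assembleFeatureTable <- function(study, cfg = analysisConfig(), prunePx = 5) {
  rows <- list()
  for (b in study@bundles) {
    sid <- b@stimulusId
    pairs <- Filter(function(p) p@stimulusId == sid, study@strokes)
    if (length(pairs) == 0L) next
    for (cause in c("contact", "fabric")) {
      mm <- meanMap(pairs, cause, b@mask)
      regs <- withCallingHandlers(
        segmentMeanMap(mm, cfg),
        warning = function(w) invokeRestart("muffleWarning"))
      for (reg in regs) {
        sk <- skeletonizeRegion(reg, prunePx = prunePx)
        rows[[length(rows) + 1L]] <- computeRegionFeatures(reg, b, sk)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stimulus_id = character(0), cause = character(0),
               label = integer(0))
  attr(out, "nRegions") <- nrow(out)
  out
}
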