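# Mean-map analyses: inter-observer agreement, cross-stimulus correlation
# matrices with classical MDS, and response-weighted depth differences.

#' Mean map across participants
#'
#' Per-pixel fraction of participants marking the given cause. All input
#' pairs must refer to the same stimulus.
#'
#' @param pairs nonempty list of \linkS4class{StrokeMapPair}, one per
#'   participant.
#' @param cause "contact" or "fabric".
#' @param mask logical matrix; values outside it are zeroed.
#' @return A \linkS4class{MeanMap}.
#' @export
meanMap <- function(pairs, cause = c("contact", "fabric"), mask) {
  cause <- match.arg(cause)
  if (length(pairs) == 0L) stop("empty list of stroke-map pairs")
  sids <- unique(vapply(pairs, stimulusId, character(1)))
  if (length(sids) != 1L)
    stop("mixed stimulus ids: ", paste(sids, collapse = ", "))
  acc <- Reduce(`+`, lapply(pairs, function(p)
    (if (cause == "contact") p@contact else p@fabric) * 1))
  v <- acc / length(pairs)
  v[!mask] <- 0
  new("MeanMap", stimulusId = sids, cause = cause, values = v,
      nParticipants = length(pairs))
}

#' Mean pairwise inter-observer correlation for one stimulus
#'
#' For every unordered pair of observers, computes the Pearson correlation
#' between their concatenated masked (fabric, contact) response vectors and
#' returns the mean over pairs. Pairs in which either observer's vector is
#' constant (e.g. no markings at all) are skipped. With
#' \code{perCause = TRUE}, correlations are computed per cause map and
#' averaged.
#'
#' @param pairs list of \linkS4class{StrokeMapPair} for one stimulus, one
#'   per observer.
#' @param mask logical matrix.
#' @param perCause concatenate both causes (default) or correlate per cause.
#' @return Mean Pearson r (NA if no valid observer pair).
#' @export
interobserverAgreement <- function(pairs, mask, perCause = FALSE) {
  if (length(pairs) < 2L) stop("need at least 2 observers")
  m <- which(mask)
  vecs <- lapply(pairs, function(p) {
    if (perCause)
      list(fabric = as.numeric(p@fabric[m]), contact = as.numeric(p@contact[m]))
    else
      list(both = c(as.numeric(p@fabric[m]), as.numeric(p@contact[m])))
  })
  rs <- c()
  n <- length(pairs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    for (nm in names(vecs[[i]])) {
      a <- vecs[[i]][[nm]]; b <- vecs[[j]][[nm]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      rs <- c(rs, stats::cor(a, b))
    }
  }
  if (length(rs) == 0L) return(NA_real_)
  mean(rs)
}

#' Cross-stimulus similarity matrix of mean maps
#'
#' Pairwise Pearson correlation of the vectorized mean maps for one cause.
#' All maps must live on a common raster; each pair is correlated over the
#' union of the two stimuli's masks. Pairs involving a constant map are
#' recorded as NA.
#'
#' @param maps list of \linkS4class{MeanMap} for a single cause.
#' @param masks a single logical matrix, or a named list keyed by stimulus
#'   id; defaults to the full frame.
#' @return List of class \code{"SimilarityMatrix"} with elements
#'   \code{stimulus_ids}, \code{cause} and \code{r} (symmetric, unit
#'   diagonal).
#' @export
crossStimulusSimilarity <- function(maps, masks = NULL) {
  stopifnot(length(maps) >= 1L)
  causes <- unique(vapply(maps, mapCause, character(1)))
  if (length(causes) != 1L) stop("maps mix causes")
  dims <- lapply(maps, function(m) dim(m@values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("maps must share a common raster")
  ids <- vapply(maps, stimulusId, character(1))
  getMask <- function(sid) {
    if (is.null(masks)) matrix(TRUE, dims[[1]][1], dims[[1]][2])
    else if (is.list(masks)) masks[[sid]] else masks
  }
  n <- length(maps)
  r <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    m <- getMask(ids[i]) | getMask(ids[j])
    a <- maps[[i]]@values[m]; b <- maps[[j]]@values[m]
    rij <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
           else stats::cor(a, b)
    r[i, j] <- r[j, i] <- rij
  }
  dimnames(r) <- list(ids, ids)
  structure(list(stimulus_ids = ids, cause = causes, r = r),
            class = "SimilarityMatrix")
}

#' Classical MDS embedding of a similarity matrix
#'
#' Torgerson (classical metric) scaling of the dissimilarity
#' \eqn{d = 1 - r}: deterministic up to rotation/reflection, unlike
#' stress-minimizing variants. Negative dissimilarities (r slightly above 1
#' from numerical noise) are clipped to 0; NA entries are not allowed.
#'
#' @param sim a \code{"SimilarityMatrix"} (or a plain symmetric correlation
#'   matrix).
#' @param dims embedding dimension.
#' @return List with \code{points} (n x dims matrix, zero-padded when fewer
#'   positive eigenvalues exist) and \code{eig} (eigenvalue spectrum).
#' @export
mdsEmbed <- function(sim, dims = 2L) {
  r <- if (inherits(sim, "SimilarityMatrix")) sim$r else sim
  if (!isSymmetric(unname(r), tol = 1e-8)) stop("similarity matrix must be symmetric")
  if (any(is.na(r))) stop("similarity matrix contains NA entries")
  d <- 1 - r
  d[d < 0] <- 0
  fit <- stats::cmdscale(stats::as.dist(d), k = min(dims, nrow(r) - 1L),
                         eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims)
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  rownames(pts) <- rownames(r)
  list(points = pts, eig = fit$eig)
}

#' Response-weighted mean depth difference
#'
#' Mean of the per-pixel depth gap (textile minus base) over the mask,
#' weighted by the mean-map response fraction at each pixel:
#' \eqn{\sum m_i (z^{textile}_i - z^{base}_i) / \sum m_i}. Accurate
#' observers should produce a smaller value for contact maps than for
#' fabric maps.
#'
#' @param map a \linkS4class{MeanMap}.
#' @param bundle the matching \linkS4class{StimulusBundle}.
#' @return Numeric scalar.
#' @export
weightedDepthDifference <- function(map, bundle) {
  stopifnot(identical(dim(map@values), dim(bundle@image)))
  w <- map@values
  w[!bundle@mask] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("all-zero mean map: weighted depth difference undefined")
  gap <- bundle@depthTextile - bundle@depthBase
  sum(w * gap) / tot
}
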