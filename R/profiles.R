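# Two-layer depth-profile analysis: sampling piecewise-linear contours,
# joint 0-1 normalization that preserves the relative heights of the two
# layers, averaging across observers, and correlation against the
# ground-truth depth rows.

#' Sample a piecewise-linear contour at every column
#'
#' Linear interpolation between the sorted control points, with constant
#' extrapolation beyond the endpoints. Duplicate x positions with
#' conflicting heights are resolved by averaging, with a warning.
#'
#' @param points two-column (x, y) matrix with >= 2 control points.
#' @param width raster width; the contour is evaluated at columns 1..width.
#' @return Numeric vector of length \code{width}.
#' @export
sampleContour <- function(points, width) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2L, ncol(points) == 2L)
  x <- points[, 1]; y <- points[, 2]
  if (anyDuplicated(x)) {
    spread <- tapply(y, x, function(v) diff(range(v)))
    if (any(spread > 0))
      warning("duplicate x with conflicting heights: averaged")
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  o <- order(x)
  stats::approx(x[o], y[o], xout = seq_len(width), rule = 2)$y
}

#' Jointly normalize a two-layer profile response to [0, 1]
#'
#' Both sampled contours are rescaled by one shared offset and scale (the
#' min-max of their concatenation), so the relative heights of the drapery
#' and object responses - their cross-layer ordering and ratios of height
#' differences - are preserved. If both contours are constant and equal the
#' response carries no relief information and both are set to 0.5 by
#' convention.
#'
#' @param pair a \linkS4class{ProfilePair}.
#' @param width raster width.
#' @return List with numeric vectors \code{textile} and \code{base}.
#' @export
normalizeProfilePair <- function(pair, width) {
  tex <- sampleContour(pair@textilePoints, width)
  bas <- sampleContour(pair@basePoints, width)
  rng <- range(c(tex, bas))
  if (diff(rng) <= 0)
    return(list(textile = rep(0.5, width), base = rep(0.5, width)))
  list(textile = (tex - rng[1]) / diff(rng),
       base = (bas - rng[1]) / diff(rng))
}

#' Mean two-layer response across observers for one raster line
#'
#' Each participant's response is normalized jointly across its two layers,
#' then the column-wise mean is taken per layer.
#'
#' @param pairs nonempty list of \linkS4class{ProfilePair} for one stimulus
#'   and raster row.
#' @param width raster width.
#' @return List with \code{textile}, \code{base} (numeric vectors) and
#'   \code{n} (number of observers).
#' @export
meanProfileResponse <- function(pairs, width) {
  if (length(pairs) == 0L) stop("empty list of profile responses")
  normd <- lapply(pairs, normalizeProfilePair, width = width)
  list(textile = rowMeans(vapply(normd, `[[`, numeric(width), "textile")),
       base = rowMeans(vapply(normd, `[[`, numeric(width), "base")),
       n = length(pairs))
}

#' Score a mean profile response against the ground truth
#'
#' Pearson correlation (and two-tailed p) between the mean response and the
#' corresponding masked ground-truth depth row, for each of the two layers.
#' Pearson's affine invariance makes the score independent of the per-raster
#' normalization constants.
#'
#' @param meanResp result of \code{\link{meanProfileResponse}}.
#' @param bundle a \linkS4class{StimulusBundle}.
#' @param rasterRow image row.
#' @return data.frame with columns stimulus_id, raster_row, layer, r, p,
#'   n_columns.
#' @export
scoreProfiles <- function(meanResp, bundle, rasterRow) {
  m <- bundle@mask[rasterRow, ]
  out <- lapply(c("textile", "base"), function(layer) {
    truth <- if (layer == "textile") bundle@depthTextile[rasterRow, m]
             else bundle@depthBase[rasterRow, m]
    if (stats::sd(truth) == 0) stop("constant ground-truth row")
    resp <- meanResp[[layer]][m]
    ct <- stats::cor.test(resp, truth)
    data.frame(stimulus_id = bundle@stimulusId, raster_row = rasterRow,
               layer = layer, r = unname(ct$estimate), p = ct$p.value,
               n_columns = sum(m))
  })
  do.call(rbind, out)
}

#' Score all profile responses of a study
#'
#' Groups the study's profile responses by (stimulus, raster row), averages
#' across observers and scores both layers against the ground truth.
#'
#' @param study a \linkS4class{ScissionStudy}.
#' @return data.frame of per-line, per-layer scores.
#' @export
scoreStudyProfiles <- function(study) {
  if (length(study@profiles) == 0L) stop("study has no profile responses")
  keys <- vapply(study@profiles, function(p)
    paste(p@stimulusId, p@rasterRow, sep = "@"), character(1))
  out <- lapply(unique(keys), function(k) {
    grp <- study@profiles[keys == k]
    b <- study@bundles[[grp[[1]]@stimulusId]]
    mr <- meanProfileResponse(grp, ncol(b@image))
    scoreProfiles(mr, b, grp[[1]]@rasterRow)
  })
  do.call(rbind, out)
}
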