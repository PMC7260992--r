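# Readers and writers for the on-disk study layout.
#
# A bundle directory holds: image.png, mask.png, depth_textile.tif,
# depth_base.tif and meta.json. Depth rasters are stored normalized to
# [0, 1] as 32-bit float TIFF, with the affine recovery parameters
# (depth_min, depth_scale) recorded in the sidecar, so arbitrary depth units
# survive the round trip. Stroke maps are 8-bit PNGs (0/255); any nonzero
# pixel counts as marked.

#' Write a StimulusBundle to a directory
#'
#' @param bundle a \linkS4class{StimulusBundle}.
#' @param dirPath output directory (created if absent).
#' @return \code{dirPath}, invisibly.
#' @seealso \code{\link{readStimulusBundle}}
#' @export
writeStimulusBundle <- function(bundle, dirPath) {
  validObject(bundle)
  dir.create(dirPath, showWarnings = FALSE, recursive = TRUE)
  img <- pmin(pmax(bundle@image, 0), 1)
  png::writePNG(img, file.path(dirPath, "image.png"))
  png::writePNG(bundle@mask * 1, file.path(dirPath, "mask.png"))
  depths <- c(bundle@depthTextile, bundle@depthBase)
  dmin <- min(depths)
  dscale <- max(diff(range(depths)), .Machine$double.eps)
  tiff::writeTIFF((bundle@depthTextile - dmin) / dscale,
                  file.path(dirPath, "depth_textile.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF((bundle@depthBase - dmin) / dscale,
                  file.path(dirPath, "depth_base.tif"),
                  bits.per.sample = 32L)
  meta <- list(stimulus_id = bundle@stimulusId,
               base_shape_id = bundle@baseShapeId,
               depth_min = dmin, depth_scale = dscale,
               depth_units = "arbitrary")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dirPath, "meta.json"))
  invisible(dirPath)
}

#' Read a StimulusBundle from a directory
#'
#' Expects the layout written by \code{\link{writeStimulusBundle}}. Raises
#' "incomplete bundle" if any file is missing, "coregistration error" if the
#' rasters disagree in shape, and "layer-order violation" if the base depth
#' exceeds the textile depth beyond the 1\%-of-range tolerance.
#'
#' @param dirPath directory containing image.png, mask.png,
#'   depth_textile.tif, depth_base.tif, meta.json.
#' @return A validated \linkS4class{StimulusBundle}.
#' @export
readStimulusBundle <- function(dirPath) {
  files <- c("image.png", "mask.png", "depth_textile.tif", "depth_base.tif",
             "meta.json")
  missing <- files[!file.exists(file.path(dirPath, files))]
  if (length(missing))
    stop("incomplete bundle: missing ", paste(missing, collapse = ", "))
  meta <- jsonlite::fromJSON(file.path(dirPath, "meta.json"))
  asMatrix <- function(a) if (length(dim(a)) == 3L) a[, , 1] else a
  img <- asMatrix(png::readPNG(file.path(dirPath, "image.png")))
  mask <- asMatrix(png::readPNG(file.path(dirPath, "mask.png"))) > 0
  dt <- asMatrix(tiff::readTIFF(file.path(dirPath, "depth_textile.tif")))
  db <- asMatrix(tiff::readTIFF(file.path(dirPath, "depth_base.tif")))
  dt <- dt * meta$depth_scale + meta$depth_min
  db <- db * meta$depth_scale + meta$depth_min
  new("StimulusBundle", stimulusId = meta$stimulus_id,
      baseShapeId = meta$base_shape_id, image = img,
      mask = matrix(mask, nrow(img)), depthTextile = dt, depthBase = db)
}

#' Clip a stroke pair to a stimulus mask
#'
#' Markings outside the stimulus boundary contour carry no information;
#' every statistic in the package ignores them, and this clips them away
#' explicitly.
#'
#' @param pair a \linkS4class{StrokeMapPair}.
#' @param mask logical matrix.
#' @return The clipped \linkS4class{StrokeMapPair}.
#' @export
clipToMask <- function(pair, mask) {
  stopifnot(identical(dim(mask), dim(pair@fabric)))
  new("StrokeMapPair", participantId = pair@participantId,
      stimulusId = pair@stimulusId, fabric = pair@fabric & mask,
      contact = pair@contact & mask)
}

#' Write a StrokeMapPair as two PNG stroke maps
#'
#' Files are named \code{{participant}_{stimulus}_{fabric|contact}.png}.
#' When a mask is supplied, markings outside it are clipped before writing,
#' so the round trip returns the clipped pair.
#'
#' @param pair a \linkS4class{StrokeMapPair}.
#' @param dirPath output directory.
#' @param mask optional logical matrix to clip against.
#' @return Character vector of the two file paths, invisibly.
#' @export
writeStrokeMaps <- function(pair, dirPath, mask = NULL) {
  validObject(pair)
  if (!is.null(mask)) pair <- clipToMask(pair, mask)
  dir.create(dirPath, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_%s", pair@participantId, pair@stimulusId)
  paths <- file.path(dirPath, sprintf("%s_%s.png", stem, c("fabric", "contact")))
  png::writePNG(pair@fabric * 1, paths[1])
  png::writePNG(pair@contact * 1, paths[2])
  invisible(paths)
}

#' Read a StrokeMapPair written by writeStrokeMaps
#'
#' @param dirPath directory holding the stroke-map PNGs.
#' @param participantId,stimulusId identifiers used in the file names.
#' @param mask optional logical matrix to clip against on load.
#' @return A \linkS4class{StrokeMapPair}.
#' @export
readStrokeMaps <- function(dirPath, participantId, stimulusId, mask = NULL) {
  stem <- sprintf("%s_%s", participantId, stimulusId)
  paths <- file.path(dirPath, sprintf("%s_%s.png", stem, c("fabric", "contact")))
  if (!all(file.exists(paths)))
    stop("incomplete stroke-map pair for ", stem)
  asMatrix <- function(a) if (length(dim(a)) == 3L) a[, , 1] else a
  f <- asMatrix(png::readPNG(paths[1])) > 0
  k <- asMatrix(png::readPNG(paths[2])) > 0
  strokeMapPair(participantId, stimulusId, f, k, mask = mask)
}

#' Write a full synthetic study tree
#'
#' Writes one bundle directory per stimulus, all stroke maps, the profile
#' responses as a CSV, and ground_truth.csv with per-stimulus contact
#' fractions.
#'
#' @param study a \linkS4class{ScissionStudy}.
#' @param dirPath output directory.
#' @return \code{dirPath}, invisibly.
#' @export
writeStudy <- function(study, dirPath) {
  dir.create(dirPath, showWarnings = FALSE, recursive = TRUE)
  for (b in study@bundles)
    writeStimulusBundle(b, file.path(dirPath, "stimuli", b@stimulusId))
  for (p in study@strokes)
    writeStrokeMaps(p, file.path(dirPath, "strokes"),
                    mask = study@bundles[[p@stimulusId]]@mask)
  gt <- do.call(rbind, lapply(study@bundles, function(b) {
    gap <- b@depthTextile - b@depthBase
    eps <- study@params$drape$contactEpsilon
    data.frame(stimulus_id = b@stimulusId, base_shape_id = b@baseShapeId,
               contact_fraction = mean(gap[b@mask] < eps),
               mean_depth_gap = mean(gap[b@mask]))
  }))
  utils::write.csv(gt, file.path(dirPath, "ground_truth.csv"),
                   row.names = FALSE)
  if (length(study@profiles)) {
    resp <- do.call(rbind, lapply(study@profiles, function(pp) {
      rbind(
        data.frame(participant = pp@participantId, stimulus = pp@stimulusId,
                   raster_row = pp@rasterRow, layer = "textile",
                   point_index = seq_len(nrow(pp@textilePoints)),
                   x = pp@textilePoints[, 1], y = pp@textilePoints[, 2]),
        data.frame(participant = pp@participantId, stimulus = pp@stimulusId,
                   raster_row = pp@rasterRow, layer = "base",
                   point_index = seq_len(nrow(pp@basePoints)),
                   x = pp@basePoints[, 1], y = pp@basePoints[, 2]))
    }))
    utils::write.csv(resp, file.path(dirPath, "profile_responses.csv"),
                     row.names = FALSE)
  }
  invisible(dirPath)
}
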