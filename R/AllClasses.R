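#' @import methods
NULL

#' Analysis configuration
#'
#' Container for the pipeline constants shared by all analysis stages:
#' bootstrap repetitions for the profligacy-matched null, the Gaussian blur
#' width and binarization threshold used when segmenting mean maps, the
#' morphological opening radius, the number of features handed to the SVM,
#' the hyperparameter-search budget, and the master RNG seed from which every
#' stochastic stage derives its own seed.
#'
#' @slot bootstrapReps integer, repetitions of the bootstrap null (default 10000).
#' @slot blurSigmaPx numeric, Gaussian blur sigma in pixels (default 10).
#' @slot binarizeThreshold numeric, threshold applied to the blurred, squared,
#'   0-1 normalized mean map (default 0.3).
#' @slot openingRadiusPx integer, radius of the disk structuring element used
#'   to remove tiny regions (default 1).
#' @slot topKFeatures integer, number of top-ranked features used by the
#'   classifier (default 7).
#' @slot hyperparamIters integer, iterations of the SVM hyperparameter search
#'   (default 50).
#' @slot rngSeed integer, master seed.
#'
#' @export
setClass("AnalysisConfig",
  representation(
    bootstrapReps = "integer",
    blurSigmaPx = "numeric",
    binarizeThreshold = "numeric",
    openingRadiusPx = "integer",
    topKFeatures = "integer",
    hyperparamIters = "integer",
    rngSeed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (object@bootstrapReps < 1L) msg <- c(msg, "bootstrapReps must be >= 1")
  if (object@blurSigmaPx <= 0) msg <- c(msg, "blurSigmaPx must be > 0")
  if (object@binarizeThreshold <= 0 || object@binarizeThreshold >= 1)
    msg <- c(msg, "binarizeThreshold must be in (0, 1)")
  if (object@openingRadiusPx < 0L) msg <- c(msg, "openingRadiusPx must be >= 0")
  if (object@topKFeatures < 1L) msg <- c(msg, "topKFeatures must be >= 1")
  if (object@hyperparamIters < 1L) msg <- c(msg, "hyperparamIters must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' Defaults reproduce the published analysis constants: 10,000 bootstrap
#' repetitions, blur sigma 10 px, binarization threshold 0.3, radius-1 disk
#' opening, top-7 feature selection and a 50-iteration hyperparameter search.
#'
#' @param bootstrapReps,blurSigmaPx,binarizeThreshold,openingRadiusPx
#'   see slot documentation in \linkS4class{AnalysisConfig}.
#' @param topKFeatures,hyperparamIters,rngSeed see slot documentation.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig(rngSeed = 7L)
#' @export
analysisConfig <- function(bootstrapReps = 10000L, blurSigmaPx = 10,
                           binarizeThreshold = 0.3, openingRadiusPx = 1L,
                           topKFeatures = 7L, hyperparamIters = 50L,
                           rngSeed = 1L) {
  new("AnalysisConfig",
      bootstrapReps = as.integer(bootstrapReps),
      blurSigmaPx = as.numeric(blurSigmaPx),
      binarizeThreshold = as.numeric(binarizeThreshold),
      openingRadiusPx = as.integer(openingRadiusPx),
      topKFeatures = as.integer(topKFeatures),
      hyperparamIters = as.integer(hyperparamIters),
      rngSeed = as.integer(rngSeed))
}

#' Stimulus bundle: rendering, mask and coregistered two-layer depth maps
#'
#' One draped stimulus: the Lambertian rendering shown to observers, the
#' analysis mask (pixels inside the stimulus boundary contour), and the
#' coregistered ground-truth height fields of the overlying textile and the
#' underlying base shape, all on one raster grid. Depth is encoded
#' "larger = closer to the viewer" (height above the ground plane).
#'
#' The textile must lie on or above the base everywhere inside the mask, up
#' to a scan-noise tolerance of 1\% of the bundle's depth range; violations
#' beyond that raise a "layer-order violation" at validation time.
#'
#' @slot stimulusId character, e.g. "A2" = second draping of base shape A.
#' @slot baseShapeId character, e.g. "A".
#' @slot image numeric matrix, rendering (arbitrary gray units).
#' @slot mask logical matrix, TRUE inside the stimulus boundary.
#' @slot depthTextile numeric matrix, textile height field.
#' @slot depthBase numeric matrix, base-shape height field.
#'
#' @export
setClass("StimulusBundle",
  representation(
    stimulusId = "character",
    baseShapeId = "character",
    image = "matrix",
    mask = "matrix",
    depthTextile = "matrix",
    depthBase = "matrix"
  )
)

setValidity("StimulusBundle", function(object) {
  d <- dim(object@image)
  if (!identical(dim(object@mask), d) ||
      !identical(dim(object@depthTextile), d) ||
      !identical(dim(object@depthBase), d))
    return("coregistration error: rasters have mismatched dimensions")
  if (!is.logical(object@mask))
    return("mask must be a logical matrix")
  if (!any(object@mask))
    return("mask must contain at least one TRUE pixel")
  gap <- object@depthBase[object@mask] - object@depthTextile[object@mask]
  rng <- diff(range(c(object@depthTextile[object@mask],
                      object@depthBase[object@mask])))
  eps <- 0.01 * max(rng, .Machine$double.eps)
  if (any(gap > eps))
    return(sprintf(
      "layer-order violation: depth_base exceeds depth_textile by up to %.3g (tolerance %.3g)",
      max(gap), eps))
  TRUE
})

#' Construct a StimulusBundle
#'
#' @param stimulusId,baseShapeId identifiers (e.g. "A2", "A").
#' @param image numeric matrix rendering.
#' @param mask logical matrix; defaults to the full frame.
#' @param depthTextile,depthBase numeric height-field matrices, same grid.
#' @return A validated \linkS4class{StimulusBundle}.
#' @export
stimulusBundle <- function(stimulusId, baseShapeId, image, mask = NULL,
                           depthTextile, depthBase) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  new("StimulusBundle", stimulusId = as.character(stimulusId),
      baseShapeId = as.character(baseShapeId), image = image,
      mask = mask, depthTextile = depthTextile, depthBase = depthBase)
}

#' Stroke map pair: one participant's binary two-cause annotations
#'
#' Binary fabric and contact painting responses of one participant for one
#' stimulus. Markings outside the stimulus mask carry no information and are
#' clipped when the pair is constructed against a bundle (see
#' \code{\link{clipToMask}}); all downstream statistics additionally apply
#' the mask.
#'
#' @slot participantId character.
#' @slot stimulusId character.
#' @slot fabric logical matrix, TRUE where the participant marked a ridge as
#'   caused by the cloth's own folds.
#' @slot contact logical matrix, TRUE where marked as caused by the hidden
#'   base shape pressing the cloth.
#'
#' @export
setClass("StrokeMapPair",
  representation(
    participantId = "character",
    stimulusId = "character",
    fabric = "matrix",
    contact = "matrix"
  )
)

setValidity("StrokeMapPair", function(object) {
  if (!identical(dim(object@fabric), dim(object@contact)))
    return("coregistration error: fabric and contact maps differ in shape")
  if (!is.logical(object@fabric) || !is.logical(object@contact))
    return("stroke maps must be logical matrices")
  TRUE
})

#' Construct a StrokeMapPair
#'
#' @param participantId,stimulusId identifiers.
#' @param fabric,contact logical matrices (anything coercible; nonzero = marked).
#' @param mask optional logical matrix; when given, markings outside it are
#'   clipped.
#' @return A \linkS4class{StrokeMapPair}.
#' @export
strokeMapPair <- function(participantId, stimulusId, fabric, contact,
                          mask = NULL) {
  f <- matrix(as.logical(fabric != 0), nrow(fabric))
  k <- matrix(as.logical(contact != 0), nrow(contact))
  if (!is.null(mask)) { f <- f & mask; k <- k & mask }
  new("StrokeMapPair", participantId = as.character(participantId),
      stimulusId = as.character(stimulusId), fabric = f, contact = k)
}

#' Mean map: per-pixel fraction of participants marking one cause
#'
#' @slot stimulusId character.
#' @slot cause character, "contact" or "fabric".
#' @slot values numeric matrix in [0, 1]; zero outside the mask.
#' @slot nParticipants integer.
#'
#' @export
setClass("MeanMap",
  representation(
    stimulusId = "character",
    cause = "character",
    values = "matrix",
    nParticipants = "integer"
  )
)

setValidity("MeanMap", function(object) {
  if (!object@cause %in% c("contact", "fabric"))
    return("cause must be 'contact' or 'fabric'")
  v <- object@values
  if (any(v < -1e-9 | v > 1 + 1e-9))
    return("mean map values must lie in [0, 1]")
  if (object@nParticipants < 1L)
    return("nParticipants must be >= 1")
  TRUE
})

#' Skeleton branch tree of a segmented region
#'
#' Medial branch tree obtained by thinning a region to its skeleton, pruning
#' short spurs and rooting the resulting branch decomposition at the branch
#' containing the midpoint of the skeleton's longest path. Each branch stores
#' its ordered pixel polyline (proximal end first), arclength, graph depth
#' (root = 1), parent index, angle from the parent at the attachment point
#' (degrees) and the arclength along the parent at which it emerges.
#'
#' @slot pixels integer matrix (row, col) of skeleton pixels.
#' @slot branches list of per-branch records.
#' @slot rootBranch integer index into \code{branches}.
#' @slot totalLength numeric, summed branch arclength in pixels.
#'
#' @export
setClass("SkeletonGraph",
  representation(
    pixels = "matrix",
    branches = "list",
    rootBranch = "integer",
    totalLength = "numeric"
  )
)

#' Two-layer piecewise-linear depth-profile response
#'
#' One participant's reconstruction of both surface layers along one raster
#' line: control points of the piecewise-linear contour for the directly
#' visible textile and for the hidden base shape. Heights use the same
#' convention as the depth maps (larger = closer to the viewer).
#'
#' @slot participantId character.
#' @slot stimulusId character.
#' @slot rasterRow integer, image row of the highlighted raster line.
#' @slot textilePoints numeric matrix with columns x (image column) and y
#'   (reported height).
#' @slot basePoints numeric matrix, same layout, for the hidden layer.
#'
#' @export
setClass("ProfilePair",
  representation(
    participantId = "character",
    stimulusId = "character",
    rasterRow = "integer",
    textilePoints = "matrix",
    basePoints = "matrix"
  )
)

setValidity("ProfilePair", function(object) {
  for (nm in c("textilePoints", "basePoints")) {
    p <- slot(object, nm)
    if (ncol(p) != 2L) return(sprintf("%s must have two columns (x, y)", nm))
    if (nrow(p) < 2L) return(sprintf("%s needs at least 2 control points", nm))
  }
  TRUE
})

#' Construct a ProfilePair
#' @param participantId,stimulusId identifiers.
#' @param rasterRow image row along which depth was reported.
#' @param textilePoints,basePoints two-column (x, y) control-point matrices.
#' @return A \linkS4class{ProfilePair}.
#' @export
profilePair <- function(participantId, stimulusId, rasterRow,
                        textilePoints, basePoints) {
  new("ProfilePair", participantId = as.character(participantId),
      stimulusId = as.character(stimulusId), rasterRow = as.integer(rasterRow),
      textilePoints = as.matrix(textilePoints),
      basePoints = as.matrix(basePoints))
}

#' Synthetic scission study
#'
#' The full synthetic analogue of the draped-object experiments: a set of
#' \linkS4class{StimulusBundle}s (base shapes x drapings), simulated-observer
#' \linkS4class{StrokeMapPair}s for every stimulus, and simulated two-layer
#' \linkS4class{ProfilePair} responses along selected raster lines, together
#' with the generating parameters and seed.
#'
#' @slot bundles named list of \linkS4class{StimulusBundle}.
#' @slot strokes list of \linkS4class{StrokeMapPair} (all participants x
#'   stimuli).
#' @slot profiles list of \linkS4class{ProfilePair}.
#' @slot profileDesign data.frame with columns stimulus_id and raster_row.
#' @slot seed integer master seed.
#' @slot params list of generator settings.
#'
#' @export
setClass("ScissionStudy",
  representation(
    bundles = "list",
    strokes = "list",
    profiles = "list",
    profileDesign = "data.frame",
    seed = "integer",
    params = "list"
  )
)
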