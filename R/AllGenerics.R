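#' @rdname accessors
#' @export
setGeneric("stimulusId", function(x) standardGeneric("stimulusId"))
#' @rdname accessors
#' @export
setGeneric("baseShapeId", function(x) standardGeneric("baseShapeId"))
#' @rdname accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("stimulusImage", function(x) standardGeneric("stimulusImage"))
#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))
#' @rdname accessors
#' @export
setGeneric("depthTextile", function(x) standardGeneric("depthTextile"))
#' @rdname accessors
#' @export
setGeneric("depthBase", function(x) standardGeneric("depthBase"))
#' @rdname accessors
#' @export
setGeneric("fabricMap", function(x) standardGeneric("fabricMap"))
#' @rdname accessors
#' @export
setGeneric("contactMap", function(x) standardGeneric("contactMap"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("mapCause", function(x) standardGeneric("mapCause"))
#' @rdname accessors
#' @export
setGeneric("nParticipants", function(x) standardGeneric("nParticipants"))
#' @rdname accessors
#' @export
setGeneric("bundles", function(x) standardGeneric("bundles"))
#' @rdname accessors
#' @export
setGeneric("strokeMaps", function(x) standardGeneric("strokeMaps"))
#' @rdname accessors
#' @export
setGeneric("profileResponses", function(x) standardGeneric("profileResponses"))

#' Accessors for shapescission data classes
#'
#' Getter functions for the slots of \linkS4class{StimulusBundle},
#' \linkS4class{StrokeMapPair}, \linkS4class{MeanMap},
#' \linkS4class{ProfilePair} and \linkS4class{ScissionStudy}; use these
#' rather than reaching into slots.
#'
#' @param x an object of one of the classes above.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("stimulusId", "StimulusBundle", function(x) x@stimulusId)
#' @rdname accessors
setMethod("stimulusId", "StrokeMapPair", function(x) x@stimulusId)
#' @rdname accessors
setMethod("stimulusId", "MeanMap", function(x) x@stimulusId)
#' @rdname accessors
setMethod("stimulusId", "ProfilePair", function(x) x@stimulusId)
#' @rdname accessors
setMethod("baseShapeId", "StimulusBundle", function(x) x@baseShapeId)
#' @rdname accessors
setMethod("participantId", "StrokeMapPair", function(x) x@participantId)
#' @rdname accessors
setMethod("participantId", "ProfilePair", function(x) x@participantId)
#' @rdname accessors
setMethod("stimulusImage", "StimulusBundle", function(x) x@image)
#' @rdname accessors
setMethod("analysisMask", "StimulusBundle", function(x) x@mask)
#' @rdname accessors
setMethod("depthTextile", "StimulusBundle", function(x) x@depthTextile)
#' @rdname accessors
setMethod("depthBase", "StimulusBundle", function(x) x@depthBase)
#' @rdname accessors
setMethod("fabricMap", "StrokeMapPair", function(x) x@fabric)
#' @rdname accessors
setMethod("contactMap", "StrokeMapPair", function(x) x@contact)
#' @rdname accessors
setMethod("mapValues", "MeanMap", function(x) x@values)
#' @rdname accessors
setMethod("mapCause", "MeanMap", function(x) x@cause)
#' @rdname accessors
setMethod("nParticipants", "MeanMap", function(x) x@nParticipants)
#' @rdname accessors
setMethod("bundles", "ScissionStudy", function(x) x@bundles)
#' @rdname accessors
setMethod("strokeMaps", "ScissionStudy", function(x) x@strokes)
#' @rdname accessors
setMethod("profileResponses", "ScissionStudy", function(x) x@profiles)

setMethod("show", "StimulusBundle", function(object) {
  d <- dim(object@image)
  cat(sprintf("StimulusBundle '%s' (base shape '%s')\n", object@stimulusId,
              object@baseShapeId))
  cat(sprintf("  raster: %d x %d, %d masked pixels\n", d[1], d[2],
              sum(object@mask)))
  gap <- object@depthTextile - object@depthBase
  cat(sprintf("  depth gap (textile - base): [%.3g, %.3g]\n",
              min(gap[object@mask]), max(gap[object@mask])))
})

setMethod("show", "StrokeMapPair", function(object) {
  cat(sprintf("StrokeMapPair participant '%s', stimulus '%s'\n",
              object@participantId, object@stimulusId))
  cat(sprintf("  fabric: %d px marked; contact: %d px marked; overlap: %d px\n",
              sum(object@fabric), sum(object@contact),
              sum(object@fabric & object@contact)))
})

setMethod("show", "MeanMap", function(object) {
  cat(sprintf("MeanMap stimulus '%s', cause '%s' (%d participants)\n",
              object@stimulusId, object@cause, object@nParticipants))
  cat(sprintf("  values in [%.3f, %.3f], %d nonzero px\n",
              min(object@values), max(object@values), sum(object@values > 0)))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d branches, total length %.1f px, max depth %d\n",
              length(object@branches), object@totalLength,
              if (length(object@branches))
                max(vapply(object@branches, `[[`, 1, "depth")) else 0L))
})

setMethod("show", "ProfilePair", function(object) {
  cat(sprintf("ProfilePair participant '%s', stimulus '%s', row %d\n",
              object@participantId, object@stimulusId, object@rasterRow))
  cat(sprintf("  textile: %d control points; base: %d control points\n",
              nrow(object@textilePoints), nrow(object@basePoints)))
})

setMethod("show", "ScissionStudy", function(object) {
  cat(sprintf("ScissionStudy: %d stimuli, %d stroke-map pairs, %d profile responses (seed %d)\n",
              length(object@bundles), length(object@strokes),
              length(object@profiles), object@seed))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  bootstrapReps=%d  blurSigmaPx=%g  binarizeThreshold=%g\n",
              object@bootstrapReps, object@blurSigmaPx,
              object@binarizeThreshold))
  cat(sprintf("  openingRadiusPx=%d  topKFeatures=%d  hyperparamIters=%d  rngSeed=%d\n",
              object@openingRadiusPx, object@topKFeatures,
              object@hyperparamIters, object@rngSeed))
})
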