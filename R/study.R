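# Full-study orchestration: simulate -> consistency -> mean-map analyses ->
# regions -> classification -> profiles, from one seed, producing a single
# report list.

#' Run the complete analysis on a synthetic study
#'
#' Simulates a study (unless one is supplied) and runs every stage of the
#' pipeline: per-participant profligacy/decisiveness with the
#' profligacy-matched bootstrap null and group test, inter-observer
#' agreement, cross-stimulus similarity matrices with classical MDS and a
#' k-means base-shape recovery score, response-weighted depth differences,
#' region segmentation and feature extraction, feature ranking,
#' leave-one-stimulus-out SVM classification, and two-layer profile scoring.
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param study optional pre-built \linkS4class{ScissionStudy}; when NULL
#'   one is simulated with \code{\link{simulateStudy}} and \code{...}.
#' @param cfg an \linkS4class{AnalysisConfig}; its \code{rngSeed} is set to
#'   \code{seed}.
#' @param bootstrapReps bootstrap repetitions for the consistency stage
#'   (defaults to \code{cfg@bootstrapReps}).
#' @param ... passed to \code{\link{simulateStudy}}.
#' @return A nested report list with elements \code{consistency},
#'   \code{groupTest}, \code{agreement}, \code{similarity}, \code{mds},
#'   \code{depthDifference}, \code{regions}, \code{ranking}, \code{loso},
#'   \code{profiles} and \code{meta}.
#' @examples
#' \donttest{
#' rep <- runStudy(seed = 1, nObservers = 6, size = c(96, 96),
#'                 bootstrapReps = 200)
#' rep$loso$overall
#' }
#' @export
runStudy <- function(seed = 1L, study = NULL, cfg = analysisConfig(),
                     bootstrapReps = NULL, ...) {
  cfg@rngSeed <- as.integer(seed)
  if (is.null(bootstrapReps)) bootstrapReps <- cfg@bootstrapReps
  if (is.null(study)) study <- simulateStudy(seed = seed, ...)
  if (length(study@strokes) == 0L) stop("study has no participants")
  masks <- lapply(study@bundles, analysisMask)

  ## consistency stage
  scores <- consistencyScores(study@strokes, masks, reps = bootstrapReps,
                              seed = deriveSeed(seed, "consistency"))
  grp <- groupPairedTest(scores)

  ## mean maps and agreement
  sids <- names(study@bundles)
  byStim <- lapply(sids, function(sid)
    Filter(function(p) p@stimulusId == sid, study@strokes))
  names(byStim) <- sids
  agreement <- vapply(sids, function(sid)
    interobserverAgreement(byStim[[sid]], masks[[sid]]), numeric(1))
  mmContact <- lapply(sids, function(sid)
    meanMap(byStim[[sid]], "contact", masks[[sid]]))
  mmFabric <- lapply(sids, function(sid)
    meanMap(byStim[[sid]], "fabric", masks[[sid]]))

  ## similarity + MDS + base-shape recovery
  simContact <- crossStimulusSimilarity(mmContact, masks)
  simFabric <- crossStimulusSimilarity(mmFabric, masks)
  mdsC <- mdsEmbed(simContact)
  mdsF <- mdsEmbed(simFabric)
  baseIds <- vapply(study@bundles, baseShapeId, character(1))
  nBase <- length(unique(baseIds))
  km <- withSeed(deriveSeed(seed, "kmeans"),
                 stats::kmeans(mdsC$points, centers = nBase, nstart = 10))
  ari <- mclust::adjustedRandIndex(km$cluster, baseIds)
  rC <- simContact$r; rF <- simFabric$r
  sameBase <- outer(baseIds, baseIds, `==`)
  off <- !diag(TRUE, length(sids))
  withinBetween <- c(within = mean(rC[sameBase & off], na.rm = TRUE),
                     between = mean(rC[!sameBase], na.rm = TRUE))

  ## response-weighted depth differences
  dd <- do.call(rbind, lapply(seq_along(sids), function(i)
    data.frame(stimulus_id = sids[i],
               contact_value = weightedDepthDifference(mmContact[[i]],
                                                       study@bundles[[i]]),
               fabric_value = weightedDepthDifference(mmFabric[[i]],
                                                      study@bundles[[i]]))))
  dd$fabric_above_contact <- dd$fabric_value > dd$contact_value

  ## regions + features + classifier
  featTab <- assembleFeatureTable(study, cfg)
  loso <- NULL; ranking <- NULL
  if (nrow(featTab) > 0 && length(unique(featTab$cause)) == 2L &&
      length(unique(featTab$stimulus_id)) >= 2L) {
    loso <- losoPredict(featTab, cfg)
    ranking <- loso$ranking
  }

  ## profiles
  prof <- if (length(study@profiles)) scoreStudyProfiles(study) else NULL

  list(
    consistency = scores,
    groupTest = grp,
    agreement = list(perStimulus = agreement, mean = mean(agreement)),
    similarity = list(contact = simContact, fabric = simFabric,
                      contactWithinBetween = withinBetween),
    mds = list(contact = mdsC, fabric = mdsF, kmeansClusters = km$cluster,
               adjustedRand = ari),
    depthDifference = dd,
    regions = list(table = featTab, n = nrow(featTab)),
    ranking = ranking,
    loso = loso,
    profiles = prof,
    meta = list(seed = as.integer(seed), bootstrapReps = bootstrapReps,
                nStimuli = length(sids),
                nParticipants = length(unique(vapply(study@strokes,
                                                     participantId,
                                                     character(1))))))
}
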