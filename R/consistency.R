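# Internal-consistency statistics for two-cause painting annotations.
#
# Profligacy P = N(fabric u contact) / Nmax measures willingness to mark;
# decisiveness D = 1 - N(fabric n contact) / Nmax measures how mutually
# exclusive the two causal attributions are. Because sparse random maps
# rarely overlap, D must be judged against a profligacy-matched null:
# random ("white noise") mark placement preserving each map's exact marked
# count, whose decisiveness has the analytic expectation
# E[D] = 1 - Nf * Nc / Nmax^2 (the overlap is hypergeometric).

#' Profligacy of a stroke-map pair
#'
#' Proportion of maskable pixels marked in either map:
#' \eqn{P = N(I_{fabric} \cup I_{contact}) / N_{max}}, where \eqn{N_{max}}
#' is the number of pixels inside the stimulus boundary contour.
#'
#' @param pair a \linkS4class{StrokeMapPair}.
#' @param mask logical matrix with at least one TRUE pixel.
#' @return Numeric in [0, 1].
#' @export
profligacy <- function(pair, mask) {
  stopifnot(identical(dim(mask), dim(pair@fabric)))
  nMax <- sum(mask)
  if (nMax == 0L) stop("empty mask")
  sum((pair@fabric | pair@contact) & mask) / nMax
}

#' Decisiveness of a stroke-map pair
#'
#' \eqn{D = 1 - N(I_{fabric} \cap I_{contact}) / N_{max}}: the fraction of
#' maskable pixels NOT assigned to both causes at once. D = 1 means fully
#' mutually exclusive attributions.
#'
#' @inheritParams profligacy
#' @return Numeric in [0, 1].
#' @export
decisiveness <- function(pair, mask) {
  stopifnot(identical(dim(mask), dim(pair@fabric)))
  nMax <- sum(mask)
  if (nMax == 0L) stop("empty mask")
  1 - sum(pair@fabric & pair@contact & mask) / nMax
}

#' Profligacy-matched bootstrap null for decisiveness
#'
#' For each repetition, places the pair's exact marked counts (N_fabric,
#' N_contact) uniformly at random without replacement within the mask,
#' independently for the two maps, and records the resulting decisiveness.
#' The sample mean converges to the analytic
#' \eqn{1 - N_f N_c / N_{max}^2}.
#'
#' @param pair a \linkS4class{StrokeMapPair} (masked counts are used).
#' @param mask logical matrix.
#' @param reps number of repetitions (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of length \code{reps}.
#' @export
bootstrapNull <- function(pair, mask, reps = 10000L, seed = 1L) {
  stopifnot(reps >= 1L)
  nMax <- sum(mask)
  if (nMax == 0L) stop("empty mask")
  nF <- sum(pair@fabric & mask)
  nC <- sum(pair@contact & mask)
  bootstrapNullCounts(nF, nC, nMax, reps, seed)
}

# Count-level core of the bootstrap null: marks are index sets in 1..nMax
# (the mask pixels); only the overlap size matters for D.
bootstrapNullCounts <- function(nF, nC, nMax, reps, seed = 1L) {
  if (nF > nMax || nC > nMax) stop("marked counts exceed the mask size")
  withSeed(deriveSeed(seed, "bootnull", nF, nC, nMax), {
    inFab <- logical(nMax)
    out <- numeric(reps)
    for (r in seq_len(reps)) {
      idxF <- sample.int(nMax, nF)
      idxC <- sample.int(nMax, nC)
      inFab[idxF] <- TRUE
      out[r] <- 1 - sum(inFab[idxC]) / nMax
      inFab[idxF] <- FALSE
    }
    out
  })
}

#' One-tailed empirical p-value against a bootstrap null
#'
#' \eqn{p = (1 + \#\{D_{null} \ge D_{obs}\}) / (1 + reps)} — the add-one
#' convention avoids exact zeros and matches the direction of the
#' prediction that real observers are MORE decisive than chance.
#'
#' @param observedD observed decisiveness.
#' @param nullD numeric vector of null decisiveness values.
#' @return Numeric p-value in (0, 1].
#' @export
participantSignificance <- function(observedD, nullD) {
  if (length(nullD) == 0L) stop("empty null sample")
  (1 + sum(nullD >= observedD)) / (1 + length(nullD))
}

#' Consistency scores for a set of stroke-map pairs
#'
#' Computes, for every participant x stimulus pair, the marked-pixel counts,
#' profligacy, decisiveness, the profligacy-matched bootstrap null and the
#' one-tailed empirical p-value. The per-row null samples are attached as
#' \code{attr(result, "null")} (a list of numeric vectors aligned with the
#' rows) for use by \code{\link{groupPairedTest}}.
#'
#' @param pairs list of \linkS4class{StrokeMapPair}.
#' @param masks a single logical matrix, or a named list of masks keyed by
#'   stimulus id.
#' @param reps bootstrap repetitions.
#' @param seed integer master seed; each row consumes a derived seed.
#' @return data.frame with columns participant_id, stimulus_id, N_fabric,
#'   N_contact, N_union, N_intersect, N_max, P, D, null_mean, null_sd,
#'   p_value.
#' @export
consistencyScores <- function(pairs, masks, reps = 10000L, seed = 1L) {
  getMask <- function(sid) {
    if (is.list(masks)) masks[[sid]] else masks
  }
  nulls <- vector("list", length(pairs))
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    mask <- getMask(p@stimulusId)
    nMax <- sum(mask)
    nF <- sum(p@fabric & mask)
    nC <- sum(p@contact & mask)
    nI <- sum(p@fabric & p@contact & mask)
    nU <- nF + nC - nI
    nullD <- bootstrapNullCounts(nF, nC, nMax, reps,
                                 seed = deriveSeed(seed, p@participantId,
                                                   p@stimulusId))
    D <- 1 - nI / nMax
    nulls[[i]] <- nullD
    rows[[i]] <- data.frame(
      participant_id = p@participantId, stimulus_id = p@stimulusId,
      N_fabric = nF, N_contact = nC, N_union = nU, N_intersect = nI,
      N_max = nMax, P = nU / nMax, D = D,
      null_mean = mean(nullD), null_sd = stats::sd(nullD),
      p_value = participantSignificance(D, nullD))
  }
  out <- do.call(rbind, rows)
  attr(out, "null") <- nulls
  out
}

#' Group-level paired test of decisiveness against the bootstrap null
#'
#' Each participant's decisiveness values and null samples are first pooled
#' over that participant's stimuli (observed D averaged across stimuli; null
#' samples averaged repetition-wise across stimuli, giving a null
#' distribution for the pooled D). A one-sample t test on the per-participant
#' differences (observed minus null mean) then tests, one-tailed, whether
#' observers are more decisive than their profligacy-matched simulations.
#' Per-participant one-tailed empirical p-values are also counted at the
#' 0.05 and 0.01 levels.
#'
#' @param scores result of \code{\link{consistencyScores}} (with its
#'   \code{"null"} attribute).
#' @return List with \code{t}, \code{df}, \code{p} (one-tailed),
#'   \code{nSig05}, \code{nSig01} and a per-participant data.frame.
#' @export
groupPairedTest <- function(scores) {
  nulls <- attr(scores, "null")
  if (is.null(nulls)) stop("scores must carry the bootstrap null attribute")
  participants <- unique(scores$participant_id)
  if (length(participants) < 2L) stop("need at least 2 participants")
  per <- lapply(participants, function(pid) {
    rows <- which(scores$participant_id == pid)
    dObs <- mean(scores$D[rows])
    nullMat <- do.call(cbind, nulls[rows])
    pooledNull <- rowMeans(nullMat)
    data.frame(participant_id = pid, D = dObs,
               null_mean = mean(pooledNull),
               p_value = participantSignificance(dObs, pooledNull))
  })
  per <- do.call(rbind, per)
  diffs <- per$D - per$null_mean
  tt <- stats::t.test(diffs, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       nSig05 = sum(per$p_value < 0.05),
       nSig01 = sum(per$p_value < 0.01),
       perParticipant = per)
}
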