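# Causal classification of segmented regions: imputation and 0-1
# normalization over ALL regions (deliberately reproducing the published
# global preprocessing; a strict per-fold mode is available), informativeness
# ranking by difference of class means, top-k selection, and
# leave-one-stimulus-out SVM prediction.

#' Impute and normalize a feature table
#'
#' Per feature: missing values are replaced with the mean of the non-missing
#' values across all regions, then the feature is min-max normalized to
#' [0, 1] across all regions. Entirely-missing features are dropped with a
#' warning; constant features become all-zero and are flagged in the
#' \code{"zeroVariance"} attribute.
#'
#' @param table feature data.frame (from \code{\link{assembleFeatureTable}}).
#' @param features feature column names; defaults to the 24 canonical names
#'   present in the table.
#' @return The table with normalized feature columns; attributes
#'   \code{"dropped"} and \code{"zeroVariance"} list affected features.
#' @export
imputeAndNormalize <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(regionFeatureNames(), colnames(table))
  dropped <- character(0)
  zeroVar <- character(0)
  for (f in features) {
    v <- table[[f]]
    ok <- is.finite(v)
    if (!any(ok)) {
      warning("feature entirely missing, dropped: ", f)
      table[[f]] <- NULL
      dropped <- c(dropped, f)
      next
    }
    v[!ok] <- mean(v[ok])
    rng <- range(v)
    if (diff(rng) <= 0) {
      v[] <- 0
      zeroVar <- c(zeroVar, f)
    } else {
      v <- (v - rng[1]) / diff(rng)
    }
    table[[f]] <- v
  }
  attr(table, "dropped") <- dropped
  attr(table, "zeroVariance") <- zeroVar
  attr(table, "features") <- setdiff(features, dropped)
  table
}

#' Rank features by informativeness
#'
#' Informativeness is the signed difference of class means of the normalized
#' feature values (fabric mean minus contact mean); features are ordered by
#' absolute difference, descending, with ties broken by the canonical
#' feature order. The top \code{topK} are marked selected.
#'
#' @param table normalized feature table (see
#'   \code{\link{imputeAndNormalize}}) with a \code{cause} column containing
#'   both classes.
#' @param features feature names to rank; defaults to those recorded by
#'   normalization.
#' @param topK number of features to select.
#' @return data.frame with columns feature, signed_mean_diff, rank,
#'   selected; ordered by rank.
#' @export
rankFeatures <- function(table, features = NULL, topK = 7L) {
  if (is.null(features)) features <- attr(table, "features")
  if (is.null(features))
    features <- intersect(regionFeatureNames(), colnames(table))
  if (length(unique(table$cause)) < 2L)
    stop("feature table contains a single class")
  isFab <- table$cause == "fabric"
  diffs <- vapply(features, function(f)
    mean(table[[f]][isFab]) - mean(table[[f]][!isFab]), numeric(1))
  ord <- order(-abs(diffs), seq_along(features))
  out <- data.frame(feature = features[ord],
                    signed_mean_diff = unname(diffs[ord]),
                    rank = seq_along(ord))
  out$selected <- out$rank <= topK
  rownames(out) <- NULL
  out
}

# Fit an SVM with one hyperparameter draw. x: numeric matrix (rows =
# regions), y: factor with levels contact/fabric.
fitSvmModel <- function(x, y, par) {
  scale <- if (isTRUE(par$standardize)) apply(x, 2, stats::sd) > 1e-12 else FALSE
  args <- list(x = x, y = y, type = "C-classification",
               kernel = par$kernel, cost = par$cost, scale = scale)
  if (par$kernel == "radial") args$gamma <- par$gamma
  if (par$kernel == "polynomial") {
    args$degree <- par$degree
    args$coef0 <- 1
  }
  do.call(e1071::svm, args)
}

#' Randomized hyperparameter search for the causal SVM
#'
#' Seeded random search over the stated space: kernel in {linear,
#' polynomial (order 2-4), radial}; margin-penalty constant log-uniform in
#' [1e-3, 1e3]; kernel scale (radial only) log-uniform in [1e-3, 1e3];
#' standardize in {TRUE, FALSE}. The objective is stratified k-fold
#' cross-validated accuracy on the training regions. Deterministic given the
#' seed.
#'
#' @param x numeric feature matrix.
#' @param y factor of causes (2 levels).
#' @param iters search iterations (>= 1).
#' @param seed integer seed.
#' @param nFolds CV folds.
#' @return List with the chosen kernel, cost, gamma, degree, standardize,
#'   and the achieved \code{cvAccuracy}; also \code{searchType =
#'   "randomized"}.
#' @export
tuneHyperparameters <- function(x, y, iters = 50L, seed = 1L, nFolds = 5L) {
  stopifnot(iters >= 1L)
  y <- droplevels(as.factor(y))
  n <- length(y)
  withSeed(deriveSeed(seed, "tune"), {
    # stratified fold assignment
    folds <- integer(n)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    draws <- lapply(seq_len(iters), function(i) {
      kernel <- sample(c("linear", "polynomial", "radial"), 1)
      list(kernel = kernel,
           cost = 10^stats::runif(1, -3, 3),
           gamma = 10^stats::runif(1, -3, 3),
           degree = if (kernel == "polynomial") sample(2:4, 1) else NA,
           standardize = sample(c(TRUE, FALSE), 1))
    })
    best <- NULL; bestAcc <- -Inf
    for (par in draws) {
      accs <- vapply(seq_len(nFolds), function(k) {
        tr <- folds != k; te <- !tr
        if (length(unique(y[tr])) < 2L || !any(te)) return(NA_real_)
        fit <- tryCatch(fitSvmModel(x[tr, , drop = FALSE], y[tr], par),
                        error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        pred <- tryCatch(
          stats::predict(fit, x[te, , drop = FALSE]),
          error = function(e) NULL)
        if (is.null(pred)) return(NA_real_)
        mean(pred == y[te])
      }, numeric(1))
      acc <- mean(accs, na.rm = TRUE)
      if (is.finite(acc) && acc > bestAcc) { bestAcc <- acc; best <- par }
    }
    if (is.null(best))
      best <- list(kernel = "linear", cost = 1, gamma = NA, degree = NA,
                   standardize = TRUE)
    best$cvAccuracy <- if (is.finite(bestAcc)) bestAcc else NA_real_
    best$searchType <- "randomized"
    best
  })
}

#' Leave-one-stimulus-out SVM prediction of causal assignment
#'
#' For each stimulus, an SVM is tuned and trained on the regions of all
#' OTHER stimuli (using the selected normalized features) and predicts the
#' causal assignment of the held-out stimulus's regions, so no model ever
#' sees its own stimulus. Folds whose training set contains a single class
#' are skipped with a warning.
#'
#' @param table feature table (raw; normalization and imputation are applied
#'   internally, globally across all regions unless \code{strict}).
#' @param cfg an \linkS4class{AnalysisConfig} (top-k, search iterations,
#'   seed).
#' @param features character vector of feature names to use; when NULL, the
#'   top \code{cfg@topKFeatures} from \code{\link{rankFeatures}} are used.
#' @param strict recompute imputation/normalization within each training
#'   fold instead of globally (avoids the mild preprocessing leakage of the
#'   global convention).
#' @return List of class \code{"LosoResult"}: \code{predictions} (per-region
#'   data.frame with predicted cause and correctness), \code{perStimulus}
#'   accuracies, \code{overall} accuracy, \code{foldParams},
#'   \code{ranking}, \code{features}.
#' @export
losoPredict <- function(table, cfg = analysisConfig(), features = NULL,
                        strict = FALSE) {
  stimuli <- unique(table$stimulus_id)
  if (length(stimuli) < 2L) stop("need at least 2 stimuli for LOSO")
  normAll <- imputeAndNormalize(table)
  ranking <- rankFeatures(normAll, topK = cfg@topKFeatures)
  if (is.null(features))
    features <- ranking$feature[ranking$selected]
  preds <- rep(NA_character_, nrow(table))
  foldParams <- list()
  for (sid in stimuli) {
    te <- table$stimulus_id == sid
    if (strict) {
      normTr <- imputeAndNormalize(table[!te, , drop = FALSE])
      # apply training-fold statistics to the held-out rows
      xTr <- as.matrix(normTr[, features, drop = FALSE])
      xTe <- as.matrix(table[te, features, drop = FALSE])
      for (j in seq_along(features)) {
        v <- table[[features[j]]][!te]
        ok <- is.finite(v)
        mu <- mean(v[ok]); v[!ok] <- mu
        rng <- range(v)
        raw <- xTe[, j]
        raw[!is.finite(raw)] <- mu
        xTe[, j] <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else 0
      }
    } else {
      xTr <- as.matrix(normAll[!te, features, drop = FALSE])
      xTe <- as.matrix(normAll[te, features, drop = FALSE])
    }
    yTr <- factor(table$cause[!te], levels = c("contact", "fabric"))
    if (length(unique(yTr)) < 2L) {
      warning("single-class training fold skipped for stimulus ", sid)
      next
    }
    par <- tuneHyperparameters(xTr, yTr, iters = cfg@hyperparamIters,
                               seed = deriveSeed(cfg@rngSeed, "loso", sid))
    fit <- fitSvmModel(xTr, yTr, par)
    preds[te] <- as.character(stats::predict(fit, xTe))
    foldParams[[sid]] <- par
  }
  predictions <- data.frame(stimulus_id = table$stimulus_id,
                            label = table$label, cause = table$cause,
                            predicted = preds,
                            correct = preds == table$cause)
  scored <- !is.na(predictions$predicted)
  perStim <- stats::aggregate(correct ~ stimulus_id,
                              data = predictions[scored, , drop = FALSE],
                              FUN = mean)
  names(perStim)[2] <- "accuracy"
  structure(list(predictions = predictions, perStimulus = perStim,
                 overall = mean(predictions$correct[scored]),
                 n = sum(scored), foldParams = foldParams,
                 ranking = ranking, features = features),
            class = "LosoResult")
}

#' @export
print.LosoResult <- function(x, ...) {
  cat(sprintf("Leave-one-stimulus-out SVM: %.1f%% correct over %d regions (%d stimuli)\n",
              100 * x$overall, x$n, nrow(x$perStimulus)))
  cat("features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
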