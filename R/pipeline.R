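#' @include classify.R featselect.R outliers.R features.R synthdata.R
NULL

#' Run the full negative-emotion classification pipeline
#'
#' extract -> normalize -> clean -> select -> LOOCV, for one subject. The
#' input is either a pair of recordings (see [buildFeatureMatrix()]) or an
#' already-extracted [FeatureMatrix-class] (raw or normalized). As in the
#' original protocol, normalization bounds, the outlier fit and the feature
#' selection are computed once on the subject's full window set, not inside
#' each cross-validation fold; this leaks a small amount of label
#' information into selection. `strictCV = TRUE` refits the feature
#' selection inside every fold instead, for comparison.
#'
#' @param recordings named list with `basic` and `negative` recordings, or
#'   `NULL` when `featureMatrix` is given.
#' @param featureMatrix a [FeatureMatrix-class] entry point that skips
#'   extraction.
#' @param spec a [windowSpec()].
#' @param quantile chi-square quantile for [removeOutliers()].
#' @param nBins,pseudoCount histogram settings for [selectFeatures()].
#' @param classifiers subset of `c("mlp", "lda", "qda")`.
#' @param seed base seed for perceptron training (per-fold seeds derive from
#'   it).
#' @param strictCV refit feature selection within each LOOCV fold.
#' @return List with `featureMatrix` (normalized), `outlierMask`,
#'   `selection` (a [SelectedFeatureSet-class]; for `strictCV` the
#'   full-data selection reported for reference), and `reports` (named list
#'   of [EvaluationReport-class], one per classifier).
#' @examples
#' \donttest{
#' p <- simParams(durationS = 900)
#' recs <- list(basic = simulateRecording(p, "basic", seed = 1),
#'              negative = simulateRecording(p, "negative", seed = 1))
#' res <- runPipeline(recs, spec = windowSpec(selectionCount = 20), seed = 1)
#' res$reports$mlp
#' }
#' @export
runPipeline <- function(recordings = NULL, featureMatrix = NULL,
                        spec = windowSpec(), quantile = 0.975,
                        nBins = 10L, pseudoCount = 1,
                        classifiers = c("mlp", "lda", "qda"), seed = 1L,
                        strictCV = FALSE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (is.null(featureMatrix)) {
    if (is.null(recordings)) stop("provide recordings or a featureMatrix")
    featureMatrix <- buildFeatureMatrix(recordings, spec)
  }
  if (nrow(normBounds(featureMatrix)) != 2L)
    featureMatrix <- normalizeMinmax(featureMatrix)
  cleaned <- removeOutliers(featureMatrix, quantile = quantile)
  fm <- cleaned$matrix
  sel <- selectFeatures(fm, nBins = nBins, pseudoCount = pseudoCount)
  y <- conditionLabels(fm)
  X <- featureValues(fm)
  reports <- list()
  for (m in classifiers) {
    if (strictCV && m == "mlp") {
      reports[[m]] <- strictLoocvMLP(X, y, nBins, pseudoCount, seed)
    } else {
      Xs <- X[, selectedFeatures(sel), drop = FALSE]
      cfg <- if (m == "mlp") mlpConfig(ncol(Xs), seed = seed) else NULL
      reports[[m]] <- loocv(Xs, y, method = m, config = cfg)
    }
  }
  list(featureMatrix = featureMatrix, outlierMask = cleaned$mask,
       selection = sel, reports = reports)
}

# LOOCV that refits feature selection on each fold's training rows, so the
# held-out window never informs its own feature set.
strictLoocvMLP <- function(X, y, nBins, pseudoCount, seed) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    selI <- selectFeatures(Xtr, labels = ytr, nBins = nBins,
                           pseudoCount = pseudoCount)
    keep <- selectedFeatures(selI)
    cfg <- mlpConfig(length(keep), seed = seed + i)
    model <- trainMLP(Xtr[, keep, drop = FALSE], ytr, cfg)
    pred[i] <- predict(model, X[i, keep, drop = FALSE])
  }
  confusion <- c(TP = sum(pred == 1 & y == 1), FN = sum(pred == 0 & y == 1),
                 FP = sum(pred == 1 & y == 0), TN = sum(pred == 0 & y == 0))
  new("EvaluationReport", classifier = "mlp (strict CV)",
      confusion = stats::setNames(as.integer(confusion), names(confusion)),
      metrics = metricsFromConfusion(confusion), folds = as.integer(n),
      config = list(strictCV = TRUE, seed = seed))
}
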