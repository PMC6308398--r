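#' @include physioaffect-package.R
NULL

CHANNEL_KINDS <- c("ECG", "SKT", "EDA")
CONDITIONS <- c("basic", "negative")

#' SignalRecord: one channel of a physiological recording
#'
#' Holds the samples of a single channel (ECG, SKT or EDA) together with its
#' sampling rate, physical units and recording metadata.
#'
#' @slot channel character, one of `"ECG"`, `"SKT"`, `"EDA"`.
#' @slot fs sampling rate in Hz.
#' @slot samples numeric vector of samples.
#' @slot units character, e.g. `"mV"`, `"degC"`, `"uS"`.
#' @slot subjectId character subject identifier.
#' @slot condition `"basic"` or `"negative"`.
#'
#' @seealso [simulateRecording()], [detectRPeaks()], [downsampleLowpass()]
#' @export
setClass("SignalRecord",
  representation(
    channel = "character",
    fs = "numeric",
    samples = "numeric",
    units = "character",
    subjectId = "character",
    condition = "character"
  ),
  prototype(subjectId = "S1", condition = "basic")
)

setValidity("SignalRecord", function(object) {
  msg <- NULL
  if (!(object@channel %in% CHANNEL_KINDS))
    msg <- c(msg, sprintf("channel must be one of %s", paste(CHANNEL_KINDS, collapse = ", ")))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!(object@condition %in% CONDITIONS))
    msg <- c(msg, "condition must be 'basic' or 'negative'")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (is.null(msg)) TRUE else msg
})

#' RPeakSeries: detected R-peak times of an ECG channel
#'
#' @slot peakTimes numeric, strictly increasing R-peak times in seconds.
#' @slot fs sampling rate (Hz) of the source ECG.
#' @export
setClass("RPeakSeries",
  representation(peakTimes = "numeric", fs = "numeric"))

setValidity("RPeakSeries", function(object) {
  if (length(object@peakTimes) > 1L && any(diff(object@peakTimes) <= 0))
    return("peakTimes must be strictly increasing")
  if (any(object@peakTimes < 0)) return("peakTimes must be non-negative")
  TRUE
})

#' RRSeries: inter-beat (RR) interval series
#'
#' Intervals are in milliseconds; each interval is stamped with the midpoint
#' time (seconds) of the two peaks that define it. Intervals outside the
#' physiologic band (300, 2000) ms are flagged unusable and excluded from
#' feature computation.
#'
#' @slot intervals numeric RR intervals in ms.
#' @slot times numeric midpoint times in seconds.
#' @slot usable logical, TRUE where the interval is physiologically plausible.
#' @export
setClass("RRSeries",
  representation(intervals = "numeric", times = "numeric", usable = "logical"))

setValidity("RRSeries", function(object) {
  n <- length(object@intervals)
  if (length(object@times) != n || length(object@usable) != n)
    return("intervals, times and usable must have equal length")
  if (any(object@intervals <= 0 | object@intervals >= 5000))
    return("intervals must lie in (0, 5000) ms")
  TRUE
})

#' FeatureMatrix: windowed feature vectors with labels
#'
#' Rows are windows, columns are the 16 named autonomic features. Row
#' metadata carries subject, condition and window index. After
#' [normalizeMinmax()] the per-feature normalization bounds are stored so
#' values can be mapped back to physical units.
#'
#' @slot values numeric matrix (windows x features).
#' @slot windowInfo data.frame with columns subject_id, condition,
#'   window_index (one row per matrix row).
#' @slot normBounds numeric matrix (2 x features; rows "min","max") or a
#'   0-row matrix before normalization.
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    windowInfo = "data.frame",
    normBounds = "matrix"
  ),
  prototype(normBounds = matrix(numeric(0), nrow = 0, ncol = 0))
)

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  if (nrow(object@values) != nrow(object@windowInfo))
    msg <- c(msg, "values and windowInfo must have the same number of rows")
  need <- c("subject_id", "condition", "window_index")
  if (!all(need %in% names(object@windowInfo)))
    msg <- c(msg, "windowInfo must have subject_id, condition, window_index")
  else if (!all(object@windowInfo$condition %in% CONDITIONS))
    msg <- c(msg, "condition must be 'basic' or 'negative'")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values must have feature column names")
  if (nrow(object@normBounds) == 2L &&
      ncol(object@normBounds) != ncol(object@values))
    msg <- c(msg, "normBounds must have one column per feature")
  if (is.null(msg)) TRUE else msg
})

#' ClassGaussian: fitted multivariate normal for one emotion class
#'
#' @slot center numeric mean vector.
#' @slot covariance ridge-regularized covariance matrix.
#' @slot ridge ridge coefficient lambda used (fraction of mean diagonal).
#' @slot n number of rows the fit used.
#' @export
setClass("ClassGaussian",
  representation(center = "numeric", covariance = "matrix",
                 ridge = "numeric", n = "integer"))

setValidity("ClassGaussian", function(object) {
  d <- length(object@center)
  if (!all(dim(object@covariance) == c(d, d)))
    return("covariance must be square and match center length")
  if (max(abs(object@covariance - t(object@covariance))) > 1e-8)
    return("covariance must be symmetric")
  TRUE
})

#' OutlierMask: result of Mahalanobis window cleaning
#'
#' @slot keep logical, TRUE for retained rows.
#' @slot distanceSq numeric squared Mahalanobis distance of each row to its
#'   own class distribution.
#' @slot threshold numeric squared-distance threshold (chi-square quantile).
#' @slot quantile the chi-square quantile used.
#' @export
setClass("OutlierMask",
  representation(keep = "logical", distanceSq = "numeric",
                 threshold = "numeric", quantile = "numeric"))

setValidity("OutlierMask", function(object) {
  if (length(object@keep) != length(object@distanceSq))
    return("keep and distanceSq must have equal length")
  TRUE
})

#' FeatureRanking: per-feature Kullback-Leibler divergence and order
#'
#' KLD is computed with p = the negative-emotion class distribution and
#' q = the basic class distribution; features are ordered by descending KLD.
#'
#' @slot feature character feature names in descending-importance order.
#' @slot kld numeric KLD (bits) aligned with `feature`.
#' @export
setClass("FeatureRanking",
  representation(feature = "character", kld = "numeric"))

setValidity("FeatureRanking", function(object) {
  if (length(object@feature) != length(object@kld))
    return("feature and kld must have equal length")
  if (any(object@kld < -1e-12)) return("kld must be non-negative")
  if (is.unsorted(rev(object@kld))) return("kld must be in descending order")
  TRUE
})

#' IGCurve: cumulative information gain as ranked features are added
#'
#' @slot ig numeric cumulative information gain (bits) for k = 1..d features.
#' @slot hS numeric label entropy H(S) in bits.
#' @slot cp numeric convergence-point value, (max IG - min IG) / 4.
#' @slot kStar integer convergence index (number of features selected).
#' @export
setClass("IGCurve",
  representation(ig = "numeric", hS = "numeric", cp = "numeric",
                 kStar = "integer"))

setValidity("IGCurve", function(object) {
  if (length(object@ig) < 1L) return("ig must be non-empty")
  if (any(object@ig < -1e-9) || any(object@ig > object@hS + 1e-9))
    return("ig must lie in [0, H(S)]")
  if (object@kStar < 1L || object@kStar > length(object@ig))
    return("kStar out of range")
  TRUE
})

#' SelectedFeatureSet: full output of the feature-selection stage
#'
#' @slot ranking a [FeatureRanking-class].
#' @slot igCurve an [IGCurve-class].
#' @slot selected character, the names of the selected features (the top
#'   kStar of the ranking).
#' @export
setClass("SelectedFeatureSet",
  representation(ranking = "FeatureRanking", igCurve = "IGCurve",
                 selected = "character"))

#' MLPModel: trained one-hidden-layer perceptron
#'
#' @slot W1 input-to-hidden weights (d x h).
#' @slot b1 hidden biases.
#' @slot W2 hidden-to-output weights (h x 1).
#' @slot b2 output bias.
#' @slot config the training configuration list (see [mlpConfig()]).
#' @slot featureNames column names seen at training time.
#' @export
setClass("MLPModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 config = "list", featureNames = "character"))

#' GaussianClassifier: linear or quadratic discriminant model
#'
#' Equal-prior Gaussian discriminant; `pooled = TRUE` gives LDA (shared
#' covariance), `pooled = FALSE` gives QDA (per-class covariance).
#'
#' @slot class0 [ClassGaussian-class] for the basic class (label 0).
#' @slot class1 [ClassGaussian-class] for the negative class (label 1).
#' @slot pooled logical.
#' @slot featureNames column names seen at training time.
#' @export
setClass("GaussianClassifier",
  representation(class0 = "ClassGaussian", class1 = "ClassGaussian",
                 pooled = "logical", featureNames = "character"))

#' EvaluationReport: confusion counts and classification metrics
#'
#' Metrics are accuracy, sensitivity, specificity, positive predictive value
#' and negative predictive value, all as fractions in \[0, 1\]. The positive
#' class is negative emotion (label 1).
#'
#' @slot classifier character label ("mlp", "lda", "qda", ...).
#' @slot confusion named integer vector TP, FN, FP, TN.
#' @slot metrics named numeric vector accuracy, sensitivity, specificity,
#'   ppv, npv.
#' @slot folds integer number of cross-validation folds (n for LOOCV).
#' @slot config list echo of the classifier configuration.
#' @export
setClass("EvaluationReport",
  representation(classifier = "character", confusion = "integer",
                 metrics = "numeric", folds = "integer", config = "list"))

setValidity("EvaluationReport", function(object) {
  if (!all(c("TP", "FN", "FP", "TN") %in% names(object@confusion)))
    return("confusion must have TP, FN, FP, TN")
  if (any(object@confusion < 0L)) return("confusion counts must be >= 0")
  TRUE
})
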