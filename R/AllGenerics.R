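#' @include AllClasses.R
NULL

#' Accessors for physioaffect S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `samples()`, `samplingRate()`, `channelKind()`, `featureValues()`,
#' `windowInfo()`, `normBounds()`, `peakTimes()`, `rrIntervals()`,
#' `selectedFeatures()`, `igCurve()`, `featureRanking()`, `confusionCounts()`,
#' `classMetrics()`.
#'
#' @param object an object of the matching class.
#' @return The slot content (vector, matrix or data.frame).
#' @name accessors
#' @aliases samples samplingRate channelKind featureValues windowInfo
#'   normBounds peakTimes rrIntervals selectedFeatures igCurve featureRanking
#'   confusionCounts classMetrics
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelKind", function(object) standardGeneric("channelKind"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("windowInfo", function(object) standardGeneric("windowInfo"))
#' @rdname accessors
#' @export
setGeneric("normBounds", function(object) standardGeneric("normBounds"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(object, usableOnly = TRUE) standardGeneric("rrIntervals"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("igCurve", function(object) standardGeneric("igCurve"))
#' @rdname accessors
#' @export
setGeneric("featureRanking", function(object) standardGeneric("featureRanking"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("classMetrics", function(object) standardGeneric("classMetrics"))

#' @rdname accessors
setMethod("samples", "SignalRecord", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "SignalRecord", function(object) object@fs)
#' @rdname accessors
setMethod("channelKind", "SignalRecord", function(object) object@channel)
#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(object) object@values)
#' @rdname accessors
setMethod("windowInfo", "FeatureMatrix", function(object) object@windowInfo)
#' @rdname accessors
setMethod("normBounds", "FeatureMatrix", function(object) object@normBounds)
#' @rdname accessors
setMethod("peakTimes", "RPeakSeries", function(object) object@peakTimes)
#' @rdname accessors
setMethod("rrIntervals", "RRSeries", function(object, usableOnly = TRUE) {
  if (usableOnly) object@intervals[object@usable] else object@intervals
})
#' @rdname accessors
setMethod("selectedFeatures", "SelectedFeatureSet", function(object) object@selected)
#' @rdname accessors
setMethod("igCurve", "SelectedFeatureSet", function(object) object@igCurve)
#' @rdname accessors
setMethod("featureRanking", "SelectedFeatureSet", function(object) object@ranking)
#' @rdname accessors
setMethod("confusionCounts", "EvaluationReport", function(object) object@confusion)
#' @rdname accessors
setMethod("classMetrics", "EvaluationReport", function(object) object@metrics)

setMethod("show", "SignalRecord", function(object) {
  cat(sprintf("SignalRecord: %s [%s], %s/%s\n", object@channel, object@units,
              object@subjectId, object@condition))
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n", length(object@samples),
              object@fs, length(object@samples) / object@fs))
})

setMethod("show", "RPeakSeries", function(object) {
  cat(sprintf("RPeakSeries: %d peaks over %.1f s\n", length(object@peakTimes),
              if (length(object@peakTimes)) max(object@peakTimes) else 0))
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf("RRSeries: %d intervals (%d usable), mean %.1f ms\n",
              length(object@intervals), sum(object@usable),
              mean(object@intervals[object@usable])))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d windows x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              if (nrow(object@normBounds) == 2L) "normalized" else "raw"))
  tab <- table(object@windowInfo$condition)
  cat("  windows per condition: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
})

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (descending KLD, bits):\n")
  print(round(stats::setNames(object@kld, object@feature), 4))
})

setMethod("show", "IGCurve", function(object) {
  cat(sprintf("IGCurve: H(S) = %.4f bits, CP = %.4f, k* = %d\n",
              object@hS, object@cp, object@kStar))
  print(round(object@ig, 4))
})

setMethod("show", "SelectedFeatureSet", function(object) {
  cat(sprintf("SelectedFeatureSet: %d of %d features\n",
              length(object@selected), length(object@ranking@feature)))
  cat("  ", paste(object@selected, collapse = ", "), "\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s], %d folds\n", object@classifier, object@folds))
  cat(sprintf("  TP=%d FN=%d FP=%d TN=%d\n", object@confusion["TP"],
              object@confusion["FN"], object@confusion["FP"], object@confusion["TN"]))
  m <- object@metrics
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | PPV %.3f | NPV %.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["ppv"], m["npv"]))
})
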