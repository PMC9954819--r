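#' @name accessors
#' @title Accessors for deepeeg containers
#' @description Slot accessors for [EEGRecording-class], [SegmentSet-class],
#'   [NormalizationParams-class], [ConfusionMatrix-class] and
#'   [MetricSet-class] objects.
#' @param x a deepeeg S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))
#' @rdname accessors
#' @export
setGeneric("segmentTensor", function(x) standardGeneric("segmentTensor"))
#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("normalizationParams",
           function(x) standardGeneric("normalizationParams"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))
#' @rdname accessors
#' @export
setGeneric("pooledConfusion", function(x) standardGeneric("pooledConfusion"))
#' @rdname accessors
#' @export
setGeneric("meanMetrics", function(x) standardGeneric("meanMetrics"))

setMethod("signalMatrix", "EEGRecording", function(x) x@signal)
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
setMethod("annotations", "EEGRecording", function(x) x@annotations)
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
setMethod("nChannels", "EEGRecording", function(x) nrow(x@signal))
setMethod("nSamples", "EEGRecording", function(x) ncol(x@signal))
setMethod("recordDuration", "EEGRecording",
          function(x) ncol(x@signal) / x@fs)

setMethod("segmentTensor", "SegmentSet", function(x) x@tensor)
setMethod("segmentLabels", "SegmentSet", function(x) x@labels)
setMethod("segmentLength", "SegmentSet", function(x) x@segmentLength)
setMethod("samplingRate", "SegmentSet", function(x) x@fs)
setMethod("nSegments", "SegmentSet", function(x) dim(x@tensor)[1])
setMethod("nChannels", "SegmentSet", function(x) dim(x@tensor)[2])
setMethod("normalizationParams", "SegmentSet", function(x) x@normalization)

setMethod("counts", "ConfusionMatrix", function(x)
  c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))
setMethod("metricValues", "MetricSet", function(x)
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    precision = x@precision, specificity = x@specificity, f1 = x@f1))
setMethod("foldResults", "CVResult", function(x) x@folds)
setMethod("pooledConfusion", "CVResult", function(x) x@pooled)
setMethod("meanMetrics", "CVResult", function(x) x@meanMetrics)

#' Subset a SegmentSet by segment index
#'
#' @param x a [SegmentSet-class].
#' @param i integer or logical index over segments.
#' @param j,...,drop ignored.
#' @return A [SegmentSet-class] with the selected segments (normalisation
#'   parameters are carried over unchanged).
#' @export
setMethod("[", "SegmentSet", function(x, i, j, ..., drop = FALSE) {
  .segmentSet(x@tensor[i, , , drop = FALSE], x@labels[i], x@fs,
              x@segmentLength, x@normalization)
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, nrow(object@signal), ncol(object@signal),
              object@fs, ncol(object@signal) / object@fs))
  n <- nrow(object@annotations)
  if (n == 0) cat("  no seizure annotations\n")
  else cat(sprintf("  %d seizure interval(s): %s\n", n,
                   paste(sprintf("[%g, %g)", object@annotations$onset_s,
                                 object@annotations$offset_s),
                         collapse = ", ")))
})

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("SegmentSet: %d segments x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], object@segmentLength, object@fs))
  cat(sprintf("  labels: %d ictal / %d interictal; %s\n",
              sum(object@labels == 1L), sum(object@labels == 0L),
              if (is.null(object@normalization)) "unnormalised"
              else "normalised"))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive = ictal)\n")
  cat(sprintf("  tp=%d fn=%d fp=%d tn=%d (total %d)\n", object@tp,
              object@fn, object@fp, object@tn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "MetricSet", function(object) {
  v <- metricValues(object)
  cat("MetricSet (%):",
      paste(sprintf("%s=%s", names(v),
                    ifelse(is.na(v), "NA", formatMetric(v))),
            collapse = " "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold cross-validation (seed %d, config %s)\n",
              object@k, object@seed, object@fingerprint))
  cat("  mean fold metrics: ")
  show(object@meanMetrics)
})
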