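#' @import methods
#' @importFrom stats rnorm runif sd fft predict glm binomial rpois
#' @importFrom utils head tail write.csv
#' @useDynLib deepeeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.emptyAnnotations <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' Multichannel EEG recording
#'
#' Container for a multichannel scalp EEG signal: a channels-by-samples
#' matrix in microvolts, its sampling rate, channel names, and seizure
#' annotations as half-open intervals `[onset_s, offset_s)` in seconds from
#' record start.
#'
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one name per channel.
#' @slot annotations data.frame with columns `onset_s`, `offset_s`, `label`
#'   (currently always `"ictal"`), sorted by onset.
#' @slot subjectId subject identifier.
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(signal = "matrix", fs = "numeric",
                 channelNames = "character", annotations = "data.frame",
                 subjectId = "character"))

setValidity("EEGRecording", function(object) {
  msgs <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (nrow(object@signal) < 1)
    msgs <- c(msgs, "at least one channel required")
  if (length(object@channelNames) != nrow(object@signal))
    msgs <- c(msgs, "channelNames length must equal number of channels")
  ann <- object@annotations
  if (!all(c("onset_s", "offset_s", "label") %in% names(ann)))
    msgs <- c(msgs, "annotations must have onset_s, offset_s, label columns")
  else if (nrow(ann) > 0) {
    dur <- ncol(object@signal) / object@fs
    if (any(ann$onset_s < 0) || any(ann$offset_s > dur + 1e-9))
      msgs <- c(msgs, "annotation intervals must lie within the recording")
    if (any(ann$onset_s >= ann$offset_s))
      msgs <- c(msgs, "annotation onset must precede offset")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames optional channel names; defaults to `CH01`, `CH02`, ...
#' @param annotations data.frame of seizure intervals (columns `onset_s`,
#'   `offset_s`, `label`); defaults to none.
#' @param subjectId subject identifier string.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- eegRecording(matrix(rnorm(2 * 256), nrow = 2), fs = 256)
#' nSamples(rec)
#' @export
eegRecording <- function(signal, fs, channelNames = NULL,
                         annotations = NULL, subjectId = "unknown") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(channelNames))
    channelNames <- sprintf("CH%02d", seq_len(nrow(signal)))
  if (is.null(annotations)) annotations <- .emptyAnnotations()
  annotations <- annotations[order(annotations$onset_s), , drop = FALSE]
  rownames(annotations) <- NULL
  new("EEGRecording", signal = signal, fs = as.numeric(fs),
      channelNames = as.character(channelNames), annotations = annotations,
      subjectId = subjectId)
}

#' Set of fixed-length labeled EEG segments
#'
#' Stack of non-overlapping, fixed-length 2D segments (channels x samples)
#' cut from one or more recordings, with binary labels (1 = ictal,
#' 0 = interictal) and, once normalised, the normalisation parameters used.
#'
#' @slot tensor numeric array `[n_segments x n_channels x segment_samples]`.
#' @slot labels integer vector of 0/1 labels, one per segment.
#' @slot fs sampling rate, Hz.
#' @slot segmentLength segment length in seconds.
#' @slot normalization `NULL` before normalisation, afterwards a
#'   [NormalizationParams-class] object.
#'
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(tensor = "array", labels = "integer", fs = "numeric",
                 segmentLength = "numeric", normalization = "ANY"))

setValidity("SegmentSet", function(object) {
  msgs <- character(0)
  d <- dim(object@tensor)
  if (length(d) != 3)
    msgs <- c(msgs, "tensor must be 3-dimensional")
  else {
    if (length(object@labels) != d[1])
      msgs <- c(msgs, "labels length must equal number of segments")
    if (d[1] > 0 && abs(d[3] - object@fs * object@segmentLength) > 1e-9)
      msgs <- c(msgs, "segment_samples must equal fs * segmentLength")
  }
  if (!all(object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0 (interictal) or 1 (ictal)")
  if (length(msgs)) msgs else TRUE
})

.segmentSet <- function(tensor, labels, fs, segmentLength,
                        normalization = NULL) {
  new("SegmentSet", tensor = tensor, labels = as.integer(labels),
      fs = as.numeric(fs), segmentLength = as.numeric(segmentLength),
      normalization = normalization)
}

#' Normalisation parameters
#'
#' Per-channel z-score statistics (fitted over all pooled segments of a
#' training set) and the post-z-score global extrema used by min-max
#' scaling to [0, 1]. Kept so held-out data can be transformed with the
#' training-set statistics.
#'
#' @slot mu per-channel mean, microvolts.
#' @slot sigma per-channel standard deviation, microvolts.
#' @slot globalMin,globalMax post-z-score extrema used by min-max scaling
#'   (`NA` until the min-max stage has been fitted).
#'
#' @exportClass NormalizationParams
setClass("NormalizationParams",
  representation(mu = "numeric", sigma = "numeric",
                 globalMin = "numeric", globalMax = "numeric"))

setValidity("NormalizationParams", function(object) {
  msgs <- character(0)
  if (length(object@mu) != length(object@sigma))
    msgs <- c(msgs, "mu and sigma must have one entry per channel")
  if (any(object@sigma <= 0))
    msgs <- c(msgs, "sigma must be positive for all channels")
  if (!is.na(object@globalMin) && !is.na(object@globalMax) &&
      object@globalMin >= object@globalMax)
    msgs <- c(msgs, "globalMin must be below globalMax")
  if (length(msgs)) msgs else TRUE
})

#' Binary confusion matrix
#'
#' Counts of true positives, true negatives, false positives and false
#' negatives; the positive class is ictal (label 1). The sole source of
#' the five classification metrics.
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(counts < 0)) return("counts must be nonnegative")
  if (sum(counts) < 1) return("at least one counted sample required")
  TRUE
})

#' Classification metric set
#'
#' The five confusion-matrix metrics, as percentages on [0, 100]. A metric
#' whose denominator is zero is undefined and stored as `NA` (never 0).
#'
#' @slot accuracy,precision,sensitivity,specificity,f1 percentages or `NA`.
#' @exportClass MetricSet
setClass("MetricSet",
  representation(accuracy = "numeric", precision = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 f1 = "numeric"))

setValidity("MetricSet", function(object) {
  v <- c(object@accuracy, object@precision, object@sensitivity,
         object@specificity, object@f1)
  v <- v[!is.na(v)]
  if (length(v) && (any(v < -1e-9) || any(v > 100 + 1e-9)))
    return("metrics must be percentages in [0, 100]")
  TRUE
})

#' Cross-validation result
#'
#' Per-fold confusion matrices and metrics from a stratified k-fold run,
#' together with the pooled confusion matrix, the unweighted mean of the
#' fold metrics (the headline figures), and the provenance (k, seed,
#' configuration fingerprint).
#'
#' @slot folds list, one element per fold, each with `fold`, `confusion`
#'   ([ConfusionMatrix-class]), `metrics` ([MetricSet-class]), and
#'   `history` (training history data.frame).
#' @slot pooled pooled [ConfusionMatrix-class] over all folds.
#' @slot meanMetrics unweighted mean [MetricSet-class] across folds.
#' @slot k number of folds.
#' @slot seed seed that produced the fold assignment and training runs.
#' @slot fingerprint short string identifying the model/training config.
#' @exportClass CVResult
setClass("CVResult",
  representation(folds = "list", pooled = "ConfusionMatrix",
                 meanMetrics = "MetricSet", k = "integer",
                 seed = "integer", fingerprint = "character"))

setValidity("CVResult", function(object) {
  if (length(object@folds) != object@k)
    return("exactly k fold entries required")
  TRUE
})
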