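# Segmentation, normalisation and class balancing.
#
# Recordings are cut into non-overlapping windows of 1, 2 or 4 s starting
# at t = 0. A window is labeled ictal (1) only when it lies entirely
# inside an annotated seizure interval and interictal (0) only when it is
# entirely outside all of them; windows straddling a seizure boundary are
# discarded to avoid label noise. Normalisation is per-channel z-scoring
# over all pooled segments followed by global min-max scaling to [0, 1];
# the fitted parameters are reusable on held-out data (values outside the
# training range are clipped).

#' Cut a recording into fixed-length labeled segments
#'
#' @param rec an [EEGRecording-class].
#' @param segment_length_s window length in seconds (1, 2 or 4 in the
#'   standard pipeline; any length yielding a whole number of samples is
#'   accepted).
#' @return A [SegmentSet-class]. A recording shorter than one window
#'   yields an empty set with a warning.
#' @export
segmentRecording <- function(rec, segment_length_s) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  segSamp <- segment_length_s * fs
  if (abs(segSamp - round(segSamp)) > 1e-9)
    stop("segment_length_s * fs must be a whole number of samples")
  segSamp <- as.integer(round(segSamp))
  sig <- signalMatrix(rec)
  nSeg <- floor(ncol(sig) / segSamp)
  ann <- annotations(rec)
  if (nSeg < 1) {
    warning("recording shorter than one segment; returning empty set")
    return(.segmentSet(array(0, c(0, nrow(sig), segSamp)), integer(0), fs,
                       segment_length_s))
  }
  keep <- logical(nSeg)
  labels <- integer(nSeg)
  for (k in seq_len(nSeg)) {
    s <- (k - 1) * segment_length_s
    e <- k * segment_length_s
    if (nrow(ann) == 0) { keep[k] <- TRUE; labels[k] <- 0L; next }
    inside <- any(s >= ann$onset_s - 1e-9 & e <= ann$offset_s + 1e-9)
    outside <- all(e <= ann$onset_s + 1e-9 | s >= ann$offset_s - 1e-9)
    if (inside) { keep[k] <- TRUE; labels[k] <- 1L }
    else if (outside) { keep[k] <- TRUE; labels[k] <- 0L }
    # else: straddles a seizure boundary -> dropped
  }
  kept <- which(keep)
  tensor <- array(0, c(length(kept), nrow(sig), segSamp))
  for (j in seq_along(kept)) {
    k <- kept[j]
    tensor[j, , ] <- sig[, ((k - 1) * segSamp + 1):(k * segSamp)]
  }
  .segmentSet(tensor, labels[kept], fs, segment_length_s)
}

#' Combine several SegmentSets
#'
#' @param sets list of compatible [SegmentSet-class] objects (same
#'   channel count, rate and window length).
#' @return The concatenated [SegmentSet-class].
#' @export
combineSegmentSets <- function(sets) {
  sets <- Filter(function(s) nSegments(s) > 0, sets)
  if (length(sets) == 0) stop("no non-empty SegmentSets to combine")
  d1 <- dim(segmentTensor(sets[[1]]))
  for (s in sets[-1]) {
    if (!all(dim(segmentTensor(s))[2:3] == d1[2:3]) ||
        samplingRate(s) != samplingRate(sets[[1]]))
      stop("SegmentSets are not compatible")
  }
  ns <- vapply(sets, nSegments, integer(1))
  tensor <- array(0, c(sum(ns), d1[2], d1[3]))
  at <- 0
  for (s in sets) {
    tensor[at + seq_len(nSegments(s)), , ] <- segmentTensor(s)
    at <- at + nSegments(s)
  }
  .segmentSet(tensor, unlist(lapply(sets, segmentLabels)),
              samplingRate(sets[[1]]), segmentLength(sets[[1]]))
}

#' Z-score segments per channel
#'
#' Centres and scales each channel using its mean and standard deviation
#' pooled over all segments and samples, as done when normalising a full
#' training set in one batch.
#'
#' @param segments a [SegmentSet-class].
#' @return List with `segments` (standardised) and `params` (a
#'   [NormalizationParams-class] with min-max extrema still unset,
#'   reusable on held-out data via [applyNormalization()]).
#' @export
zscoreSegments <- function(segments) {
  x <- segmentTensor(segments)
  nc <- dim(x)[2]
  mu <- numeric(nc); sigma <- numeric(nc)
  for (c in seq_len(nc)) {
    v <- as.vector(x[, c, ])
    mu[c] <- mean(v)
    sigma[c] <- stats::sd(v)
    if (!is.finite(sigma[c]) || sigma[c] < 1e-12)
      stop(sprintf("degenerate channel %d: zero variance, cannot z-score", c))
    x[, c, ] <- (x[, c, ] - mu[c]) / sigma[c]
  }
  params <- new("NormalizationParams", mu = mu, sigma = sigma,
                globalMin = NA_real_, globalMax = NA_real_)
  list(segments = .segmentSet(x, segmentLabels(segments),
                              samplingRate(segments),
                              segmentLength(segments), params),
       params = params)
}

#' Min-max scale z-scored segments to [0, 1]
#'
#' With `params = NULL` the global extrema are fitted on the data (which
#' then spans exactly `[0, 1]`); with fitted parameters the transform is
#' applied and out-of-range values are clipped to the boundaries.
#'
#' @param segments a [SegmentSet-class] (typically already z-scored).
#' @param params optional [NormalizationParams-class] with fitted extrema.
#' @return List with `segments` (scaled, carrying the full
#'   [NormalizationParams-class]) and `params`.
#' @export
minmaxScale <- function(segments, params = NULL) {
  x <- segmentTensor(segments)
  if (is.null(params)) {
    lo <- min(x); hi <- max(x)
    if (!(hi > lo)) stop("degenerate range: max must exceed min")
    base <- normalizationParams(segments)
    params <- new("NormalizationParams",
                  mu = if (is.null(base)) rep(0, dim(x)[2]) else base@mu,
                  sigma = if (is.null(base)) rep(1, dim(x)[2]) else base@sigma,
                  globalMin = lo, globalMax = hi)
  } else {
    lo <- params@globalMin; hi <- params@globalMax
    if (is.na(lo) || is.na(hi) || !(hi > lo))
      stop("params must carry fitted min-max extrema")
  }
  x <- (x - lo) / (hi - lo)
  x[x < 0] <- 0
  x[x > 1] <- 1
  list(segments = .segmentSet(x, segmentLabels(segments),
                              samplingRate(segments),
                              segmentLength(segments), params),
       params = params)
}

#' Apply fitted normalisation to held-out segments
#'
#' Z-scores with the training-set channel statistics, then min-max scales
#' with the training-set extrema, clipping to `[0, 1]`.
#'
#' @param segments an unnormalised [SegmentSet-class].
#' @param params a fitted [NormalizationParams-class].
#' @return The transformed [SegmentSet-class].
#' @export
applyNormalization <- function(segments, params) {
  x <- segmentTensor(segments)
  for (c in seq_len(dim(x)[2]))
    x[, c, ] <- (x[, c, ] - params@mu[c]) / params@sigma[c]
  x <- (x - params@globalMin) / (params@globalMax - params@globalMin)
  x[x < 0] <- 0
  x[x > 1] <- 1
  .segmentSet(x, segmentLabels(segments), samplingRate(segments),
              segmentLength(segments), params)
}

#' Balance ictal and interictal classes by undersampling
#'
#' The majority class is down-sampled uniformly at random without
#' replacement to the minority count; the minority class is untouched.
#' The combined set is then shuffled, all deterministically under `seed`.
#'
#' @param segments a [SegmentSet-class] with both classes present.
#' @param seed RNG seed.
#' @return The balanced [SegmentSet-class].
#' @export
balanceClasses <- function(segments, seed = 1) {
  labels <- segmentLabels(segments)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be nonempty to balance")
  nmin <- min(length(pos), length(neg))
  withSeed(seed, {
    if (length(pos) > nmin) pos <- sort(sample(pos, nmin))
    if (length(neg) > nmin) neg <- sort(sample(neg, nmin))
    idx <- sample(c(pos, neg))
  })
  segments[idx]
}

#' Expose segments as model-input planes
#'
#' Each segment becomes a single-plane 2D image of height `n_channels`
#' and width `segment_samples`; the batch dimension leads.
#'
#' @param segments a normalised [SegmentSet-class].
#' @return Numeric array `[n_segments x n_channels x segment_samples]`.
#' @export
reshapeForModel <- function(segments) {
  segmentTensor(segments)
}

# Internal layout used by the network kernels: (H, W, C=1, N).
.toModelTensor <- function(x) {
  d <- dim(x)
  aperm(array(x, c(d[1], d[2], d[3], 1)), c(2, 3, 4, 1))
}
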