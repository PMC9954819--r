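# Band-power features and a logistic baseline.
#
# Classical spectral features: log power per channel in the five EEG
# bands. The logistic baseline on these features is deliberately simple
# and serves as an independent separability check for synthetic
# benchmarks — if it separates a dataset and the deep model does not,
# the deep model (not the data) is at fault.

#' Log band-power features per segment
#'
#' @param segments a [SegmentSet-class].
#' @return Matrix `[n_segments x (n_channels * 5)]` of log10 band powers
#'   (delta, theta, alpha, beta, gamma per channel).
#' @export
bandPowerFeatures <- function(segments) {
  x <- segmentTensor(segments)
  fs <- samplingRate(segments)
  d <- dim(x)
  bands <- eegBands()
  feats <- matrix(0, d[1], d[2] * length(bands))
  for (s in seq_len(d[1])) {
    col <- 1
    for (c in seq_len(d[2])) {
      pg <- periodogram(x[s, c, ], fs)
      for (b in bands) {
        sel <- pg$freq >= b[1] & pg$freq <= b[2]
        feats[s, col] <- log10(sum(pg$power[sel]) + 1e-12)
        col <- col + 1
      }
    }
  }
  colnames(feats) <- as.vector(outer(names(bands), seq_len(d[2]),
                                     function(b, c) sprintf("ch%d_%s", c, b)))
  feats
}

#' Cross-validated logistic band-power baseline
#'
#' Fits `glm(label ~ band powers, binomial)` on each training split of a
#' stratified k-fold partition and scores the held-out split.
#'
#' @param segments a labeled [SegmentSet-class].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return List with `accuracy` (mean fold accuracy, percent) and
#'   `foldAccuracy`.
#' @export
bandPowerBaseline <- function(segments, k = 5, seed = 1) {
  labels <- segmentLabels(segments)
  feats <- bandPowerFeatures(segments)
  fold <- kfoldSplit(labels, k, seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    df <- data.frame(y = labels, feats)
    fit <- suppressWarnings(glm(y ~ ., data = df[tr, , drop = FALSE],
                                family = binomial()))
    p <- suppressWarnings(predict(fit, df[!tr, , drop = FALSE],
                                  type = "response"))
    acc[f] <- mean((p > 0.5) == (labels[!tr] == 1))
  }
  list(accuracy = 100 * mean(acc), foldAccuracy = 100 * acc)
}

#' Training configuration for the synthetic benchmark
#'
#' The standard configuration used when training on
#' [makeBenchmarkSegments()] data: Adam starting at learning rate 1e-3,
#' halved every 3 epochs, batch size 50, 8 epochs, lambda 1. The initial
#' rate is ten times the package default because a 320-segment training
#' split at batch size 50 yields only ~50 optimisation steps over 8
#' epochs — two orders of magnitude fewer than a full-corpus training
#' run — and the decay damps post-convergence oscillation at that
#' aggressive rate.
#'
#' @param seed training seed.
#' @param epochs number of epochs (default 8).
#' @return A [TrainConfig-class].
#' @export
benchmarkTrainConfig <- function(seed = 1, epochs = 8) {
  trainConfig(optimizer = "adam", learningRate = 1e-3, batchSize = 50,
              epochs = epochs, lambda = 1, seed = seed, lrDecay = 0.5,
              lrDecayEvery = 3)
}

#' Seeded synthetic seizure-detection benchmark
#'
#' Generates a balanced set of labeled segments from synthetic records
#' with one ictal episode each: records are synthesised until both
#' classes reach `nSegments / 2`, segmented, balanced by undersampling
#' and subsampled to the exact target size. The default configuration —
#' 400 balanced 4-s segments over 8 channels with an ictal amplitude
#' gain of 5 — is the package's standard end-to-end benchmark; it is
#' linearly separable in band-power space (see [bandPowerBaseline()]),
#' so a competent classifier should approach 100% accuracy.
#'
#' @param nSegments total segments (half ictal, half interictal).
#' @param nChannels channel count.
#' @param segmentLength window length, seconds.
#' @param gain ictal amplitude gain over background.
#' @param seed cohort seed.
#' @return An unnormalised, balanced [SegmentSet-class].
#' @export
makeBenchmarkSegments <- function(nSegments = 400, nChannels = 8,
                                  segmentLength = 4, gain = 5, seed = 1) {
  target <- nSegments %/% 2
  spec <- synthSpec(nChannels = nChannels, ictalAmpGain = gain, seed = seed)
  duration <- 23 * segmentLength       # ~30% ictal -> ~5 clean ictal windows
  sets <- list()
  batch <- 0
  nPos <- 0; nNeg <- 0
  while (nPos < target || nNeg < target) {
    batch <- batch + 1
    if (batch > 50) stop("benchmark generation failed to reach class targets")
    spec@seed <- deriveSeed(seed, 1000 + batch)
    recs <- generateLabeledDataset(spec, n_records = 10,
                                   seizure_fraction = 1, duration)
    segs <- lapply(recs, segmentRecording, segment_length_s = segmentLength)
    sets <- c(sets, segs)
    allLabs <- unlist(lapply(sets, segmentLabels))
    nPos <- sum(allLabs == 1L); nNeg <- sum(allLabs == 0L)
  }
  pool <- combineSegmentSets(sets)
  labs <- segmentLabels(pool)
  withSeed(deriveSeed(seed, 77), {
    keep <- c(sample(which(labs == 1L), target),
              sample(which(labs == 0L), target))
    pool[sample(keep)]
  })
}
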