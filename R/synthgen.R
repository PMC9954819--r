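# Synthetic multichannel EEG.
#
# Background = per-band FFT-filtered Gaussian noise (delta/theta/alpha/
# beta/gamma) plus a small 10-Hz sinusoidal alpha component, mixed across
# channels by a random orthogonal matrix so channels share sources, then
# scaled to a target RMS in microvolts. Ictal episodes are amplitude-
# ramped spike-wave trains added on top of background; artifacts follow
# the standard scalp-EEG taxonomy (20-60 Hz band-limited EMG noise,
# sparse sub-2-Hz frontal eye-blink transients, i.i.d. Gaussian white
# noise). Everything is deterministic under the spec seed; no claim of
# biophysical realism is made.

#' Synthetic EEG specification
#'
#' @slot fs sampling rate, Hz.
#' @slot nChannels number of channels.
#' @slot bandPowers named relative powers for the delta (0.5-4 Hz), theta
#'   (4-8), alpha (8-13), beta (13-30) and gamma (30+) bands.
#' @slot ictalRateHz dominant spike-wave discharge frequency, Hz.
#' @slot ictalAmpGain in-seizure RMS amplitude as a multiple of background
#'   RMS (must exceed 1).
#' @slot artifactConfig named list of artifact amplitudes in microvolts:
#'   `emg`, `eyeblink`, `whitenoise` (0 disables a family).
#' @slot rmsUv background RMS amplitude per channel, microvolts.
#' @slot seed RNG seed for the cohort stream.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(fs = "numeric", nChannels = "integer",
                 bandPowers = "numeric", ictalRateHz = "numeric",
                 ictalAmpGain = "numeric", artifactConfig = "list",
                 rmsUv = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
  msgs <- character(0)
  if (object@fs <= 0) msgs <- c(msgs, "fs must be positive")
  if (object@nChannels < 1) msgs <- c(msgs, "need at least one channel")
  bp <- object@bandPowers
  if (!all(names(eegBands()) %in% names(bp)))
    msgs <- c(msgs, "bandPowers must name delta, theta, alpha, beta, gamma")
  else if (any(bp < 0)) msgs <- c(msgs, "bandPowers must be nonnegative")
  if (object@ictalAmpGain <= 1)
    msgs <- c(msgs, "ictalAmpGain must exceed 1")
  # highest synthesized frequency must stay below Nyquist
  bands <- eegBands()
  if (all(names(bands) %in% names(bp))) {
    active <- names(bp)[bp > 0]
    if (length(active)) {
      hi <- max(vapply(bands[active], function(b) b[1], numeric(1)))
      if (object@fs <= 2 * hi)
        msgs <- c(msgs, "fs must exceed twice the highest active band edge")
    }
  }
  if (length(msgs)) msgs else TRUE
})

.default1020 <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1",
                  "O2", "F7", "F8", "T3", "T4", "T5", "T6", "FZ", "CZ",
                  "PZ", "A1", "A2", "T1", "T2")

#' Construct a synthetic-EEG specification
#'
#' Defaults emulate a 23-channel, 256-Hz scalp recording with a broadly
#' 1/f-like band profile, 3-Hz spike-wave discharges at five times the
#' background amplitude, and all artifact families off.
#'
#' @param fs sampling rate, Hz.
#' @param nChannels channel count.
#' @param bandPowers named relative band powers (delta, theta, alpha,
#'   beta, gamma).
#' @param ictalRateHz discharge repetition rate, Hz.
#' @param ictalAmpGain in-seizure RMS gain over background (> 1).
#' @param artifactConfig list of artifact amplitudes in microvolts
#'   (`emg`, `eyeblink`, `whitenoise`); 0 disables.
#' @param rmsUv background per-channel RMS, microvolts.
#' @param seed RNG seed.
#' @return A [SynthSpec-class].
#' @examples
#' spec <- synthSpec(nChannels = 8, seed = 42)
#' rec <- generateBackground(spec, duration_s = 10)
#' @export
synthSpec <- function(fs = 256, nChannels = 23,
                      bandPowers = c(delta = 1, theta = 0.7, alpha = 1,
                                     beta = 0.4, gamma = 0.15),
                      ictalRateHz = 3, ictalAmpGain = 5,
                      artifactConfig = list(emg = 0, eyeblink = 0,
                                            whitenoise = 0),
                      rmsUv = 20, seed = 1) {
  new("SynthSpec", fs = fs, nChannels = as.integer(nChannels),
      bandPowers = bandPowers, ictalRateHz = ictalRateHz,
      ictalAmpGain = ictalAmpGain, artifactConfig = artifactConfig,
      rmsUv = rmsUv, seed = as.integer(seed))
}

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf("SynthSpec: %d channels @ %g Hz, ictal %g Hz x%g, seed %d\n",
              object@nChannels, object@fs, object@ictalRateHz,
              object@ictalAmpGain, object@seed))
})

# Unit-variance Gaussian noise restricted to [lo, hi] Hz by hard FFT
# masking; returns zeros for an empty band.
.bandNoise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  sp <- fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided symmetric frequencies
  mask <- freq >= lo & freq <= hi
  sp[!mask] <- 0
  y <- Re(fft(sp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate interictal background EEG
#'
#' Channels are random orthogonal mixtures of shared band-limited noise
#' sources (plus a weak 10-Hz sinusoid when alpha power is nonzero),
#' globally scaled to the spec's RMS target. The result carries no
#' seizure annotations.
#'
#' @param spec a [SynthSpec-class].
#' @param duration_s duration in seconds (`duration_s * fs` must be a
#'   whole number of samples).
#' @param subjectId subject identifier for the returned recording.
#' @return An [EEGRecording-class].
#' @export
generateBackground <- function(spec, duration_s, subjectId = "synth") {
  stopifnot(is(spec, "SynthSpec"))
  validObject(spec)
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- duration_s * spec@fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * fs must be a whole number of samples")
  n <- as.integer(round(n))
  nc <- spec@nChannels
  bands <- eegBands()
  bp <- spec@bandPowers[names(bands)]
  withSeed(spec@seed, {
    src <- matrix(0, nc, n)
    tgrid <- (seq_len(n) - 1) / spec@fs
    for (s in seq_len(nc)) {
      acc <- numeric(n)
      for (b in names(bands)) {
        if (bp[[b]] > 0) {
          edges <- bands[[b]]
          hi <- min(edges[2], 0.45 * spec@fs)
          acc <- acc + sqrt(bp[[b]]) * .bandNoise(n, spec@fs, edges[1], hi)
        }
      }
      if (bp[["alpha"]] > 0)
        acc <- acc + 0.3 * sqrt(bp[["alpha"]]) *
          sin(2 * pi * 10 * tgrid + runif(1, 0, 2 * pi))
      src[s, ] <- acc
    }
    mix <- qr.Q(qr(matrix(rnorm(nc * nc), nc, nc)))
    sig <- mix %*% src
    sig <- sig * (spec@rmsUv / mean(apply(sig, 1, rmsValue)))
    chn <- if (nc <= length(.default1020)) .default1020[seq_len(nc)]
           else sprintf("CH%02d", seq_len(nc))
    eegRecording(sig, spec@fs, chn, subjectId = subjectId)
  })
}

# One cycle-resolved spike-wave waveform on time grid t (seconds): a slow
# wave at the fundamental plus weaker sharp harmonics, Hann-ramped over
# the first and last 10% of the interval.
.spikeWave <- function(t, rate) {
  w <- sin(2 * pi * rate * t) +
    0.5 * sin(2 * pi * 2 * rate * t + pi / 3) +
    0.25 * sin(2 * pi * 3 * rate * t + pi / 5)
  dur <- max(t) - min(t)
  ramp <- pmin(1, pmin(t - min(t), max(t) - t) / (0.1 * dur + 1e-12))
  w * ramp
}

#' Inject an ictal spike-wave episode into a recording
#'
#' Adds an amplitude-ramped spike-wave train (dominant frequency
#' `ictalRateHz`) to every channel over `[onset_s, offset_s)` and appends
#' the corresponding seizure annotation. The discharge amplitude is chosen
#' so the in-interval RMS is `ictalAmpGain` times the out-of-interval RMS.
#'
#' @param rec an [EEGRecording-class].
#' @param onset_s,offset_s half-open episode interval, seconds from start;
#'   must lie inside the recording and not overlap an existing annotation.
#' @param spec a [SynthSpec-class] (rate, gain and seed are used).
#' @return The modified [EEGRecording-class] with one added annotation.
#' @export
injectIctal <- function(rec, onset_s, offset_s, spec) {
  stopifnot(is(rec, "EEGRecording"), is(spec, "SynthSpec"))
  dur <- recordDuration(rec)
  if (offset_s <= onset_s) stop("ictal interval must have positive length")
  if (onset_s < 0 || offset_s > dur + 1e-9)
    stop("ictal interval must lie within the recording")
  ann <- annotations(rec)
  if (nrow(ann) && any(onset_s < ann$offset_s & offset_s > ann$onset_s))
    stop("ictal interval overlaps an existing annotation; labels must stay unambiguous")
  fs <- samplingRate(rec)
  sig <- signalMatrix(rec)
  idx <- (floor(onset_s * fs) + 1):floor(offset_s * fs)
  out <- setdiff(seq_len(ncol(sig)), idx)
  gain <- spec@ictalAmpGain
  tgrid <- (idx - 1) / fs
  wave <- .spikeWave(tgrid, spec@ictalRateHz)
  waveRms <- rmsValue(wave)
  withSeed(deriveSeed(spec@seed, round(onset_s * 1000)), {
    for (ch in seq_len(nrow(sig))) {
      rmsOut <- rmsValue(sig[ch, out])
      amp <- sqrt(max(gain^2 - 1, 0)) * rmsOut / waveRms
      sig[ch, idx] <- sig[ch, idx] +
        amp * runif(1, 0.95, 1.05) * wave * sign(runif(1) - 0.5)
    }
  })
  ann <- rbind(ann, data.frame(onset_s = onset_s, offset_s = offset_s,
                               label = "ictal", stringsAsFactors = FALSE))
  eegRecording(sig, fs, channelNames(rec), ann, subjectId(rec))
}

#' Add EMG, eye-blink and white-noise artifacts
#'
#' EMG is band-limited (20-60 Hz) Gaussian noise added to all channels;
#' eye blinks are sparse 400-ms raised-cosine transients (spectral energy
#' below 2 Hz) on the frontal channels (names starting `FP`, else the
#' first two); white noise is i.i.d. Gaussian on all channels. An
#' amplitude of 0 disables a family; all-zero amplitudes return the input
#' unchanged.
#'
#' @param rec an [EEGRecording-class].
#' @param artifactConfig named list with microvolt amplitudes `emg`,
#'   `eyeblink`, `whitenoise`; defaults taken from `spec`.
#' @param spec a [SynthSpec-class] (seed; default artifact amplitudes).
#' @return The contaminated [EEGRecording-class] (annotations unchanged).
#' @export
addArtifacts <- function(rec, artifactConfig = NULL, spec = synthSpec()) {
  stopifnot(is(rec, "EEGRecording"))
  cfg <- if (is.null(artifactConfig)) spec@artifactConfig else artifactConfig
  for (k in c("emg", "eyeblink", "whitenoise"))
    if (is.null(cfg[[k]])) cfg[[k]] <- 0
  sig <- signalMatrix(rec)
  fs <- samplingRate(rec)
  n <- ncol(sig)
  nc <- nrow(sig)
  withSeed(deriveSeed(spec@seed, 104729), {
    if (cfg$emg > 0) {
      for (ch in seq_len(nc))
        sig[ch, ] <- sig[ch, ] +
          cfg$emg * .bandNoise(n, fs, 20, min(60, 0.45 * fs))
    }
    if (cfg$eyeblink > 0) {
      frontal <- grep("^FP", channelNames(rec))
      if (length(frontal) == 0) frontal <- seq_len(min(2, nc))
      blinkLen <- round(0.4 * fs)
      nBlinks <- max(1, rpois(1, 0.15 * n / fs))
      starts <- sort(sample.int(n - blinkLen, nBlinks))
      bump <- (1 - cos(2 * pi * seq_len(blinkLen) / blinkLen)) / 2
      for (st in starts) {
        span <- st:(st + blinkLen - 1)
        for (ch in frontal)
          sig[ch, span] <- sig[ch, span] +
            3 * cfg$eyeblink * bump * runif(1, 0.8, 1.2)
      }
    }
    if (cfg$whitenoise > 0)
      sig <- sig + matrix(rnorm(nc * n, sd = cfg$whitenoise), nc, n)
  })
  eegRecording(sig, fs, channelNames(rec), annotations(rec), subjectId(rec))
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_records` recordings; a seeded random subset of size
#' `round(n_records * seizure_fraction)` each contains exactly one
#' annotated ictal episode (duration 20-40% of the record, position
#' random). Per-record RNG substreams are derived from the spec seed by
#' counter, so the cohort is reproducible independent of generation order.
#'
#' @param spec a [SynthSpec-class].
#' @param n_records number of recordings (> 0).
#' @param seizure_fraction fraction of records carrying a seizure, in
#'   `[0, 1]`.
#' @param duration_s record duration, seconds.
#' @return List of [EEGRecording-class] objects.
#' @export
generateLabeledDataset <- function(spec, n_records, seizure_fraction,
                                   duration_s) {
  stopifnot(is(spec, "SynthSpec"))
  if (n_records <= 0) stop("n_records must be positive")
  if (seizure_fraction < 0 || seizure_fraction > 1)
    stop("seizure_fraction must lie in [0, 1]")
  nSeiz <- round(n_records * seizure_fraction)
  seizIdx <- withSeed(deriveSeed(spec@seed, 15485863),
                      sort(sample.int(n_records, nSeiz)))
  lapply(seq_len(n_records), function(i) {
    subSeed <- deriveSeed(spec@seed, i)
    recSpec <- spec
    recSpec@seed <- subSeed
    rec <- generateBackground(recSpec, duration_s,
                              subjectId = sprintf("synth%03d", i))
    if (i %in% seizIdx) {
      rec <- withSeed(deriveSeed(subSeed, 2), {
        sdur <- runif(1, 0.2, 0.4) * duration_s
        onset <- runif(1, 0.05 * duration_s, 0.95 * duration_s - sdur)
        # snap to the sample grid so segment containment is exact
        onset <- floor(onset * spec@fs) / spec@fs
        sdur <- floor(sdur * spec@fs) / spec@fs
        injectIctal(rec, onset, onset + sdur, recSpec)
      })
    }
    if (any(unlist(spec@artifactConfig) > 0))
      rec <- addArtifacts(rec, spec = recSpec)
    rec
  })
}

#' Write a cohort as EDF plus annotation summaries
#'
#' Each recording becomes `<subjectId>.edf` plus `<subjectId>-summary.txt`
#' in the CHB-MIT dialect, so synthetic data exercises the same ingestion
#' path as real recordings.
#'
#' @param records list of [EEGRecording-class] objects.
#' @param dir output directory (created if missing).
#' @return Character vector of EDF paths, invisibly.
#' @export
writeCohort <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(records, function(rec) {
    base <- file.path(dir, subjectId(rec))
    writeEDF(rec, paste0(base, ".edf"))
    writeAnnotationSummary(rec, paste0(base, "-summary.txt"),
                           edfName = paste0(subjectId(rec), ".edf"))
    paste0(base, ".edf")
  }, character(1))
  invisible(paths)
}

#' Read a cohort written by writeCohort
#'
#' @param dir directory containing `*.edf` + `*-summary.txt` pairs.
#' @return List of annotated [EEGRecording-class] objects.
#' @export
readCohort <- function(dir) {
  edfs <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  lapply(edfs, function(p) {
    rec <- readEDF(p)
    summ <- sub("\\.edf$", "-summary.txt", p)
    if (file.exists(summ))
      rec <- setAnnotations(rec, parseAnnotationSummary(summ))
    rec
  })
}
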