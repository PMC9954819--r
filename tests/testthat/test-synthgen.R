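# Synthetic EEG generator: spectra, ictal injection, artifacts, cohorts.

test_that("alpha-only background peaks inside the alpha band on every channel", {
  spec <- synthSpec(nChannels = 6,
                    bandPowers = c(delta = 0, theta = 0, alpha = 1,
                                   beta = 0, gamma = 0), seed = 4)
  rec <- generateBackground(spec, duration_s = 10)
  for (ch in seq_len(nChannels(rec))) {
    peak <- deepeeg:::dominantFrequency(signalMatrix(rec)[ch, ], 256)
    expect_gte(peak, 8)
    expect_lte(peak, 13)
  }
})

test_that("background has the requested dimensions, RMS and determinism", {
  spec <- synthSpec(nChannels = 4, seed = 9)
  rec <- generateBackground(spec, duration_s = 10)
  expect_equal(nSamples(rec), 2560)
  expect_equal(nChannels(rec), 4)
  expect_equal(nrow(annotations(rec)), 0)
  rms <- mean(apply(signalMatrix(rec), 1, function(x) sqrt(mean(x^2))))
  expect_equal(rms, 20, tolerance = 0.2)
  rec2 <- generateBackground(spec, duration_s = 10)
  expect_identical(signalMatrix(rec), signalMatrix(rec2))
  spec2 <- synthSpec(nChannels = 4, seed = 10)
  expect_false(identical(signalMatrix(rec),
                         signalMatrix(generateBackground(spec2, 10))))
})

test_that("a spec violating Nyquist is rejected", {
  expect_error(synthSpec(fs = 16), "Nyquist|band edge")
})

test_that("ictal injection raises RMS, sets the discharge frequency and annotates", {
  spec <- synthSpec(nChannels = 4, ictalAmpGain = 5, ictalRateHz = 3,
                    seed = 21)
  rec <- generateBackground(spec, duration_s = 30)
  out <- injectIctal(rec, 10, 20, spec)
  ann <- annotations(out)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$onset_s, 10)
  expect_equal(ann$offset_s, 20)
  sig <- signalMatrix(out)
  idx <- (10 * 256 + 1):(20 * 256)
  for (ch in seq_len(4)) {
    rmsIn <- sqrt(mean(sig[ch, idx]^2))
    rmsOut <- sqrt(mean(sig[ch, -idx]^2))
    expect_gte(rmsIn, (5 / 2) * rmsOut)
    peak <- deepeeg:::dominantFrequency(sig[ch, idx], 256)
    expect_gte(peak, 2.5)
    expect_lte(peak, 3.5)
  }
})

test_that("degenerate or overlapping ictal intervals are rejected", {
  spec <- synthSpec(nChannels = 2, seed = 2)
  rec <- generateBackground(spec, duration_s = 20)
  expect_error(injectIctal(rec, 5, 5, spec), "positive length")
  expect_error(injectIctal(rec, 5, 30, spec), "within the recording")
  rec <- injectIctal(rec, 5, 9, spec)
  expect_error(injectIctal(rec, 8, 12, spec), "overlap")
})

test_that("EMG artifact power concentrates in the 20-60 Hz band", {
  spec <- synthSpec(nChannels = 3, seed = 13)
  rec <- generateBackground(spec, duration_s = 8)
  noisy <- addArtifacts(rec, list(emg = 10), spec)
  added <- signalMatrix(noisy) - signalMatrix(rec)
  for (ch in 1:3) {
    frac <- deepeeg:::bandPowerFraction(added[ch, ], 256, 20, 60)
    expect_gte(frac, 0.9)
  }
})

test_that("eye blinks are slow transients on frontal channels only", {
  spec <- synthSpec(nChannels = 4, seed = 14)
  rec <- generateBackground(spec, duration_s = 20)
  noisy <- addArtifacts(rec, list(eyeblink = 30), spec)
  added <- signalMatrix(noisy) - signalMatrix(rec)
  frontal <- grep("^FP", channelNames(rec))
  expect_equal(frontal, c(1, 2))
  expect_true(all(abs(added[-frontal, ]) < 1e-12))
  for (ch in frontal) {
    expect_gt(max(abs(added[ch, ])), 0)
    peak <- deepeeg:::dominantFrequency(added[ch, ], 256)
    expect_lt(peak, 2)
  }
})

test_that("added white noise matches its nominal variance", {
  spec <- synthSpec(nChannels = 1, seed = 15)
  rec <- generateBackground(spec, duration_s = 400)   # 102400 samples
  noisy <- addArtifacts(rec, list(whitenoise = 1), spec)
  added <- signalMatrix(noisy) - signalMatrix(rec)
  v <- stats::var(as.vector(added))
  expect_gte(v, 0.97)
  expect_lte(v, 1.03)
})

test_that("all-zero artifact amplitudes are a no-op", {
  spec <- synthSpec(nChannels = 2, seed = 16)
  rec <- generateBackground(spec, duration_s = 5)
  same <- addArtifacts(rec, list(emg = 0, eyeblink = 0, whitenoise = 0),
                       spec)
  expect_identical(signalMatrix(same), signalMatrix(rec))
})

test_that("labeled cohorts honour the seizure fraction and seed", {
  spec <- synthSpec(nChannels = 2, seed = 31)
  recs <- generateLabeledDataset(spec, n_records = 20,
                                 seizure_fraction = 0.5, duration_s = 20)
  nSeiz <- vapply(recs, function(r) nrow(annotations(r)), integer(1))
  expect_equal(sum(nSeiz > 0), 10)
  expect_true(all(nSeiz %in% c(0L, 1L)))
  recs2 <- generateLabeledDataset(spec, 20, 0.5, 20)
  expect_identical(lapply(recs, signalMatrix), lapply(recs2, signalMatrix))
  expect_identical(lapply(recs, annotations), lapply(recs2, annotations))
  none <- generateLabeledDataset(spec, 5, 0, 20)
  expect_true(all(vapply(none, function(r) nrow(annotations(r)) == 0,
                         logical(1))))
  expect_error(generateLabeledDataset(spec, 0, 0.5, 20), "positive")
})

test_that("ictal segments separate from background in band-power space at gain 3", {
  segs <- makeBenchmarkSegments(nSegments = 60, nChannels = 4,
                                segmentLength = 1, gain = 3, seed = 19)
  oracle <- bandPowerBaseline(segs, k = 3, seed = 19)
  expect_gte(oracle$accuracy, 99)
})

test_that("cohorts survive the EDF + summary round trip", {
  spec <- synthSpec(nChannels = 3, seed = 41)
  recs <- generateLabeledDataset(spec, 3, 2 / 3, 30)
  dir <- withr::local_tempdir()
  writeCohort(recs, dir)
  back <- readCohort(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(nSamples(back[[i]]), nSamples(recs[[i]]))
    expect_equal(nrow(annotations(back[[i]])), nrow(annotations(recs[[i]])))
    if (nrow(annotations(recs[[i]]))) {
      expect_equal(annotations(back[[i]])$onset_s,
                   annotations(recs[[i]])$onset_s, tolerance = 1e-5)
    }
    expect_lt(max(abs(signalMatrix(back[[i]]) - signalMatrix(recs[[i]]))),
              2000 / 2^16)
  }
})
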