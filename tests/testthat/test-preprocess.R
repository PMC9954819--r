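# Segmentation, normalisation, balancing, reshaping.

test_that("segment count is floor(duration / window) without annotations", {
  set.seed(1)
  rec <- eegRecording(matrix(rnorm(2 * 6041), 2), fs = 256)  # 23.6 s
  segs <- segmentRecording(rec, 4)
  expect_equal(nSegments(segs), 5)
  expect_true(all(segmentLabels(segs) == 0L))
  expect_equal(dim(segmentTensor(segs)), c(5, 2, 1024))
})

test_that("segments fully inside an ictal interval are labeled 1", {
  set.seed(2)
  fs <- 16
  rec <- eegRecording(matrix(rnorm(1 * 10 * fs), 1), fs = fs,
                      annotations = data.frame(onset_s = 4, offset_s = 8,
                                               label = "ictal"))
  segs <- segmentRecording(rec, 2)
  expect_equal(segmentLabels(segs), c(0L, 0L, 1L, 1L, 0L))
})

test_that("boundary-straddling segments are dropped", {
  set.seed(3)
  fs <- 16
  rec <- eegRecording(matrix(rnorm(10 * fs), 1), fs = fs,
                      annotations = data.frame(onset_s = 3, offset_s = 5,
                                               label = "ictal"))
  # [0,4) and [4,8) straddle the interval; [8,12) is incomplete
  segs <- segmentRecording(rec, 4)
  expect_equal(nSegments(segs), 0)
})

test_that("retained segments reassemble the raw samples exactly", {
  set.seed(4)
  fs <- 32
  sig <- matrix(rnorm(3 * 10 * fs), 3)
  rec <- eegRecording(sig, fs = fs,
                      annotations = data.frame(onset_s = 4, offset_s = 8,
                                               label = "ictal"))
  segs <- segmentRecording(rec, 2)
  expect_equal(nSegments(segs), 5)
  rebuilt <- do.call(cbind, lapply(1:5, function(i) {
    m <- segmentTensor(segs)[i, , ]
    m
  }))
  expect_identical(rebuilt, sig[, 1:(5 * 2 * fs)])
})

test_that("a too-short recording warns and returns an empty set", {
  rec <- eegRecording(matrix(rnorm(32), 1), fs = 32)
  expect_warning(segs <- segmentRecording(rec, 4), "shorter")
  expect_equal(nSegments(segs), 0)
})

test_that("z-scoring yields pooled zero mean and unit sd per channel", {
  set.seed(5)
  segs <- deepeeg:::.segmentSet(
    array(rnorm(100 * 3 * 64, mean = 7, sd = 3), c(100, 3, 64)),
    rep(c(0L, 1L), 50), 64, 1)
  res <- zscoreSegments(segs)
  x <- segmentTensor(res$segments)
  for (c in 1:3) {
    v <- as.vector(x[, c, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(stats::sd(v) - 1), 1e-6)
  }
  # idempotence: z-scoring standardized data changes nothing material
  res2 <- zscoreSegments(res$segments)
  expect_equal(segmentTensor(res2$segments), x, tolerance = 1e-6)
})

test_that("a constant channel aborts z-scoring and is named", {
  segs <- makeToySegments(n = 6, channels = 3)
  t2 <- segmentTensor(segs)
  t2[, 2, ] <- 5
  segs <- deepeeg:::.segmentSet(t2, segmentLabels(segs),
                                samplingRate(segs), segmentLength(segs))
  expect_error(zscoreSegments(segs), "channel 2")
})

test_that("min-max scaling spans [0,1] on fitted data and clips held-out data", {
  set.seed(6)
  segs <- makeToySegments(n = 8, channels = 2, samples = 16, fs = 16)
  zs <- zscoreSegments(segs)
  mm <- minmaxScale(zs$segments)
  x <- segmentTensor(mm$segments)
  expect_equal(min(x), 0)
  expect_equal(max(x), 1)
  # held-out data outside the fitted range is clipped to the boundaries
  wild <- deepeeg:::.segmentSet(segmentTensor(segs) * 100,
                                segmentLabels(segs), samplingRate(segs),
                                segmentLength(segs))
  held <- applyNormalization(wild, mm$params)
  hx <- segmentTensor(held)
  expect_gte(min(hx), 0)
  expect_lte(max(hx), 1)
  expect_true(any(hx == 0) || any(hx == 1))
})

test_that("min-max scaling inverts exactly from its parameters", {
  set.seed(7)
  segs <- makeToySegments(n = 5, channels = 2, samples = 16, fs = 16)
  zs <- zscoreSegments(segs)
  mm <- minmaxScale(zs$segments)
  p <- mm$params
  inverted <- segmentTensor(mm$segments) * (p@globalMax - p@globalMin) +
    p@globalMin
  expect_lt(max(abs(inverted - segmentTensor(zs$segments))), 1e-12)
})

test_that("class balancing undersamples the majority without duplication", {
  set.seed(8)
  tensor <- array(0, c(400, 1, 8))
  tensor[, 1, 1] <- seq_len(400)        # unique fingerprint per segment
  segs <- deepeeg:::.segmentSet(tensor, c(rep(1L, 100), rep(0L, 300)), 8, 1)
  bal <- balanceClasses(segs, seed = 5)
  expect_equal(sum(segmentLabels(bal) == 1L), 100)
  expect_equal(sum(segmentLabels(bal) == 0L), 100)
  ids <- segmentTensor(bal)[, 1, 1]
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(ids[segmentLabels(bal) == 1L] %in% 1:100))
  # determinism and minority preservation
  bal2 <- balanceClasses(segs, seed = 5)
  expect_identical(segmentTensor(bal), segmentTensor(bal2))
  expect_setequal(ids[segmentLabels(bal) == 1L], 1:100)
})

test_that("already balanced input keeps the same multiset of segments", {
  segs <- makeToySegments(n = 10, nIctal = 5)
  bal <- balanceClasses(segs, seed = 3)
  expect_equal(nSegments(bal), 10)
  expect_setequal(segmentTensor(bal)[, 1, 1], segmentTensor(segs)[, 1, 1])
  expect_error(balanceClasses(makeToySegments(n = 4, nIctal = 0), 1),
               "both classes")
})

test_that("model reshaping exposes channel-by-sample planes with batch leading", {
  segs <- makeToySegments(n = 50, channels = 23, samples = 64, fs = 16)
  x <- reshapeForModel(segs)
  expect_equal(dim(x), c(50, 23, 64))
  # 4-s / 1-s windows at 256 Hz give the canonical 23x1024 / 23x256 planes
  s4 <- deepeeg:::.segmentSet(array(0, c(2, 23, 1024)), c(0L, 1L), 256, 4)
  expect_equal(dim(reshapeForModel(s4))[2:3], c(23, 1024))
  s1 <- deepeeg:::.segmentSet(array(0, c(2, 23, 256)), c(0L, 1L), 256, 1)
  expect_equal(dim(reshapeForModel(s1))[2:3], c(23, 256))
})
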