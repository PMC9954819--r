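# Confusion matrices, metric formulas, fold partitions, reports.

test_that("confusion counts partition the samples", {
  cm <- confusionMatrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(counts(cm), c(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  cm2 <- confusionMatrix(rep(c(0, 1), 5), rep(c(0, 1), 5))
  expect_equal(counts(cm2)[["fp"]], 0L)
  expect_equal(counts(cm2)[["fn"]], 0L)
  expect_equal(sum(counts(cm2)), 10)
  expect_error(confusionMatrix(c(0, 1), c(1)), "equal length")
})

test_that("confusion counts match a brute-force tally on random cases", {
  set.seed(50)
  for (rep in 1:20) {
    l <- sample(0:1, 200, replace = TRUE)
    p <- sample(0:1, 200, replace = TRUE)
    cm <- counts(confusionMatrix(l, p))
    brute <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (i in 1:200) {
      if (l[i] == 1 && p[i] == 1) brute["tp"] <- brute["tp"] + 1L
      else if (l[i] == 0 && p[i] == 0) brute["tn"] <- brute["tn"] + 1L
      else if (l[i] == 0 && p[i] == 1) brute["fp"] <- brute["fp"] + 1L
      else brute["fn"] <- brute["fn"] + 1L
    }
    expect_identical(cm, brute)
  }
})

test_that("metric formulas agree with per-sample brute force on 1000 cases", {
  set.seed(51)
  for (rep in 1:1000) {
    n <- sample(10:40, 1)
    l <- sample(0:1, n, replace = TRUE)
    p <- sample(0:1, n, replace = TRUE)
    if (length(unique(l)) < 2 || length(unique(p)) < 2) next
    m <- metricValues(metricsFromConfusion(confusionMatrix(l, p)))
    expect_equal(m[["accuracy"]], 100 * mean(l == p))
    expect_equal(m[["sensitivity"]], 100 * mean(p[l == 1] == 1))
    expect_equal(m[["specificity"]], 100 * mean(p[l == 0] == 0))
    expect_equal(m[["precision"]], 100 * mean(l[p == 1] == 1))
    prec <- mean(l[p == 1] == 1); rec <- mean(p[l == 1] == 1)
    if (prec + rec > 0)
      expect_equal(m[["f1"]], 100 * 2 * prec * rec / (prec + rec),
                   tolerance = 1e-12)
  }
})

test_that("perfect classification gives 100 on all five metrics", {
  m <- metricValues(metricsFromConfusion(confusionFromCounts(5, 5, 0, 0)))
  expect_true(all(m == 100))
})

test_that("zero denominators give NA metrics with a warning, never 0", {
  w <- capture_warnings(m <- metricsFromConfusion(confusionFromCounts(0, 8,
                                                                      0, 0)))
  expect_true(any(grepl("sensitivity", w)))
  expect_true(any(grepl("precision", w)))
  v <- metricValues(m)
  expect_true(is.na(v[["sensitivity"]]))
  expect_true(is.na(v[["precision"]]))
  expect_true(is.na(v[["f1"]]))
  expect_equal(v[["accuracy"]], 100)
  expect_equal(v[["specificity"]], 100)
})

test_that("formatted metrics round half up to one decimal", {
  expect_equal(roundHalfUp(99.85), 99.9)
  expect_equal(roundHalfUp(99.84), 99.8)
  expect_equal(roundHalfUp(2.25), 2.3)      # base round() would give 2.2
  expect_equal(roundHalfUp(c(1.04, NA)), c(1.0, NA))
  m <- metricsFromConfusion(confusionFromCounts(1772, 723, 1, 4))
  expect_equal(formatMetricSet(m)[["specificity"]], "99.9")
})

test_that("stratified folds are balanced, disjoint and deterministic", {
  labels <- rep(c(0L, 1L), each = 50)
  fold <- kfoldSplit(labels, k = 10, seed = 3)
  expect_equal(length(fold), 100)
  expect_equal(sort(unique(fold)), 1:10)
  for (f in 1:10) {
    expect_equal(sum(fold == f), 10)
    expect_equal(sum(fold == f & labels == 1L), 5)
  }
  expect_identical(fold, kfoldSplit(labels, 10, seed = 3))
  expect_false(identical(fold, kfoldSplit(labels, 10, seed = 4)))
  expect_error(kfoldSplit(c(rep(0L, 40), rep(1L, 5)), k = 10, seed = 1),
               "smaller k")
})

test_that("uneven classes split with fold sizes differing by at most one", {
  labels <- c(rep(0L, 23), rep(1L, 17))
  fold <- kfoldSplit(labels, k = 5, seed = 9)
  for (cls in 0:1) {
    sizes <- table(fold[labels == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("cross-validation produces per-fold and mean metrics", {
  segs <- makeSmallSeparableSet(n = 64, channels = 8, window = 1, seed = 6)
  tc <- trainConfig(learningRate = 1e-3, batchSize = 16, epochs = 2,
                    seed = 2)
  # barely-trained folds may predict one class only (undefined precision)
  cv <- suppressWarnings(
    crossValidate(modelConfig(head = "bilstm", seed = 2), segs, tc, k = 2))
  expect_s4_class(cv, "CVResult")
  expect_length(foldResults(cv), 2)
  accs <- vapply(foldResults(cv),
                 function(f) metricValues(f$metrics)[["accuracy"]],
                 numeric(1))
  meanAcc <- metricValues(meanMetrics(cv))[["accuracy"]]
  expect_gte(meanAcc, min(accs))
  expect_lte(meanAcc, max(accs))
  # pooled confusion covers every segment exactly once
  expect_equal(sum(counts(pooledConfusion(cv))), nSegments(segs))
})

test_that("reports carry one row per fold plus machine-readable companions", {
  segs <- makeSmallSeparableSet(n = 100, channels = 4, window = 1, seed = 3)
  tc <- trainConfig(learningRate = 1e-3, batchSize = 25, epochs = 1,
                    seed = 8)
  cv <- suppressWarnings(
    crossValidate(modelConfig(head = "mlp", baseline = TRUE, seed = 2),
                  segs, tc, k = 10))
  dir <- withr::local_tempdir()
  text <- renderReport(cv, dir = dir, prefix = "cv")
  foldRows <- grep("^[0-9]+ ", text)
  expect_length(foldRows, 10)
  js <- jsonlite::fromJSON(file.path(dir, "cv.json"))
  expect_equal(js$k, 10)
  expect_equal(js$meanMetrics$accuracy,
               metricValues(meanMetrics(cv))[["accuracy"]])
  csv <- utils::read.csv(file.path(dir, "cv-folds.csv"))
  expect_equal(nrow(csv), 10)
  expect_equal(sum(csv$tp + csv$tn + csv$fp + csv$fn), nSegments(segs))
})

test_that("metric-set reports round-trip through JSON at full precision", {
  m <- metricsFromConfusion(confusionFromCounts(37, 21, 3, 2))
  dir <- withr::local_tempdir()
  renderReport(m, dir = dir, prefix = "metrics")
  js <- jsonlite::fromJSON(file.path(dir, "metrics.json"))
  expect_equal(js$metrics$accuracy, metricValues(m)[["accuracy"]])
  expect_equal(js$metrics$f1, metricValues(m)[["f1"]])
})
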