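# Confusion-matrix metrics, stratified k-fold cross-validation and
# report rendering. The positive class is ictal (label 1) throughout.
# Headline figures are the unweighted means of the per-fold metrics; the
# pooled confusion matrix over all test folds is reported alongside.

#' Confusion matrix from labels and predictions
#'
#' @param labels,predictions equal-length binary (0/1) vectors; 1 = ictal
#'   is the positive class.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(c(labels, predictions) %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1")
  new("ConfusionMatrix",
      tp = sum(labels == 1L & predictions == 1L),
      tn = sum(labels == 0L & predictions == 0L),
      fp = sum(labels == 0L & predictions == 1L),
      fn = sum(labels == 1L & predictions == 0L))
}

#' Build a ConfusionMatrix from counts
#'
#' @param tp,tn,fp,fn nonnegative counts.
#' @return A [ConfusionMatrix-class].
#' @export
confusionFromCounts <- function(tp, tn, fp, fn) {
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

#' The five classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, sensitivity (recall) `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`, as
#' percentages at full precision. A metric whose denominator is zero is
#' undefined and returned as `NA` (with a warning), never as 0. Use
#' [formatMetricSet()] or [renderReport()] for the one-decimal
#' round-half-up presentation.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return A [MetricSet-class].
#' @export
metricsFromConfusion <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("metric '", what, "' undefined: zero denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  new("MetricSet",
      accuracy = ratio(tp + tn, tp + tn + fp + fn, "accuracy"),
      sensitivity = ratio(tp, tp + fn, "sensitivity"),
      precision = ratio(tp, tp + fp, "precision"),
      specificity = ratio(tn, tn + fp, "specificity"),
      f1 = ratio(2 * tp, 2 * tp + fp + fn, "f1"))
}

#' One-decimal presentation of a MetricSet
#'
#' @param metrics a [MetricSet-class].
#' @return Named character vector, metrics rounded half-up to one decimal
#'   (`"NA"` for undefined metrics).
#' @export
formatMetricSet <- function(metrics) {
  v <- metricValues(metrics)
  out <- formatMetric(v)
  names(out) <- names(v)
  out
}

#' Stratified k-fold assignment
#'
#' Each class is shuffled and dealt round-robin, so per-class fold sizes
#' differ by at most one and every index lands in exactly one fold.
#'
#' @param labels binary 0/1 label vector.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k), one per segment.
#' @export
kfoldSplit <- function(labels, k = 10, seed = 1) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < k) stop("need at least k segments")
  fold <- integer(n)
  withSeed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop(sprintf(
          "class %d has only %d segment(s), fewer than k = %d; use a smaller k",
          cls, length(idx), k))
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validate a model configuration
#'
#' Stratified k-fold evaluation: for each fold the model is rebuilt,
#' normalisation (z-score then min-max) is fitted on the training split
#' only and applied to the held-out split with clipping, the model is
#' trained, and the test-fold confusion matrix and metrics are recorded.
#' Set `normalization = "pooled"` to reproduce the literal batch
#' convention of fitting on all segments at once (leaks test statistics;
#' kept for comparability).
#'
#' @param config a [ModelConfig-class].
#' @param segments an unnormalised, labeled (ideally balanced)
#'   [SegmentSet-class].
#' @param trainCfg a [TrainConfig-class].
#' @param k number of folds (default 10).
#' @param normalization `"fold"` (default) or `"pooled"`.
#' @param verbose print per-fold progress.
#' @return A [CVResult-class].
#' @export
crossValidate <- function(config, segments, trainCfg = trainConfig(),
                          k = 10, normalization = c("fold", "pooled"),
                          verbose = FALSE) {
  normalization <- match.arg(normalization)
  labels <- segmentLabels(segments)
  if (length(unique(labels)) < 2)
    stop("cross-validation requires both classes")
  fold <- kfoldSplit(labels, k, trainCfg@seed)
  if (normalization == "pooled") {
    pooled <- minmaxScale(zscoreSegments(segments)$segments)$segments
  }
  folds <- vector("list", k)
  failures <- character(0)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    res <- tryCatch({
      if (normalization == "fold") {
        zs <- zscoreSegments(segments[trainIdx])
        mm <- minmaxScale(zs$segments)
        trainSet <- mm$segments
        testSet <- applyNormalization(segments[testIdx], mm$params)
      } else {
        trainSet <- pooled[trainIdx]
        testSet <- pooled[testIdx]
      }
      cfgF <- config
      cfgF@seed <- deriveSeed(config@seed, f)
      tcF <- trainCfg
      tcF@seed <- deriveSeed(trainCfg@seed, f)
      model <- buildModel(cfgF, dim(segmentTensor(segments))[2:3])
      fit <- trainModel(model, trainSet, config = tcF)
      preds <- predictLabels(fit$model, testSet)
      cmF <- confusionMatrix(labels[testIdx], preds)
      list(fold = f, confusion = cmF, metrics = metricsFromConfusion(cmF),
           history = fit$history)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("fold %d: %s", f, conditionMessage(res)))
      folds[[f]] <- list(fold = f, confusion = NULL, metrics = NULL,
                         history = NULL, error = conditionMessage(res))
    } else {
      folds[[f]] <- res
      if (verbose)
        message(sprintf("fold %d/%d: accuracy %s", f, k,
                        formatMetricSet(res$metrics)[["accuracy"]]))
    }
  }
  ok <- !vapply(folds, function(x) is.null(x$confusion), logical(1))
  if (!any(ok)) stop("all folds failed:\n", paste(failures, collapse = "\n"))
  cms <- lapply(folds[ok], `[[`, "confusion")
  pooledCm <- confusionFromCounts(
    sum(vapply(cms, slot, integer(1), "tp")),
    sum(vapply(cms, slot, integer(1), "tn")),
    sum(vapply(cms, slot, integer(1), "fp")),
    sum(vapply(cms, slot, integer(1), "fn")))
  mv <- do.call(rbind, lapply(folds[ok], function(x) metricValues(x$metrics)))
  mm <- colMeans(mv)
  meanMs <- new("MetricSet", accuracy = mm[["accuracy"]],
                sensitivity = mm[["sensitivity"]],
                precision = mm[["precision"]],
                specificity = mm[["specificity"]], f1 = mm[["f1"]])
  out <- new("CVResult", folds = folds, pooled = pooledCm,
             meanMetrics = meanMs, k = as.integer(k),
             seed = trainCfg@seed,
             fingerprint = .configFingerprint(config, trainCfg))
  if (length(failures))
    warning("partial cross-validation result; ",
            paste(failures, collapse = "; "))
  out
}

#' Render a metrics report
#'
#' Produces a human-readable text table (one-decimal, round-half-up) and,
#' when `dir` is given, machine-readable companions at full precision:
#' `<prefix>.json` (summary with config fingerprint and seed) and, for
#' cross-validation results, `<prefix>-folds.csv` with one row per fold.
#'
#' @param x a [CVResult-class] or [MetricSet-class].
#' @param dir optional output directory.
#' @param prefix file name stem for written outputs.
#' @return The text table lines, invisibly when files are written.
#' @export
renderReport <- function(x, dir = NULL, prefix = "report") {
  if (is(x, "MetricSet")) {
    fm <- formatMetricSet(x)
    text <- c("Metric          Value(%)",
              sprintf("%-15s %s", names(fm), fm))
    payload <- list(metrics = as.list(metricValues(x)))
  } else if (is(x, "CVResult")) {
    fm <- formatMetricSet(meanMetrics(x))
    header <- sprintf("%-6s %8s %8s %8s %8s %8s", "fold", "acc", "sens",
                      "prec", "spec", "f1")
    rows <- vapply(foldResults(x), function(fr) {
      if (is.null(fr$metrics)) return(sprintf("%-6d   failed", fr$fold))
      v <- formatMetric(metricValues(fr$metrics))
      sprintf("%-6d %8s %8s %8s %8s %8s", fr$fold, v[1], v[2], v[3], v[4],
              v[5])
    }, character(1))
    text <- c(sprintf("%d-fold cross-validation (seed %d, config %s)",
                      x@k, x@seed, x@fingerprint),
              header, rows,
              sprintf("%-6s %8s %8s %8s %8s %8s", "mean", fm[["accuracy"]],
                      fm[["sensitivity"]], fm[["precision"]],
                      fm[["specificity"]], fm[["f1"]]))
    payload <- list(
      k = x@k, seed = x@seed, fingerprint = x@fingerprint,
      meanMetrics = as.list(metricValues(meanMetrics(x))),
      pooledConfusion = as.list(counts(pooledConfusion(x))),
      folds = lapply(foldResults(x), function(fr) {
        if (is.null(fr$metrics)) return(list(fold = fr$fold,
                                             error = fr$error))
        list(fold = fr$fold, confusion = as.list(counts(fr$confusion)),
             metrics = as.list(metricValues(fr$metrics)))
      }))
  } else stop("renderReport expects a MetricSet or CVResult")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(payload, file.path(dir, paste0(prefix, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (is(x, "CVResult")) {
      ok <- Filter(function(fr) !is.null(fr$metrics), foldResults(x))
      df <- do.call(rbind, lapply(ok, function(fr)
        data.frame(fold = fr$fold, t(counts(fr$confusion)),
                   t(metricValues(fr$metrics)))))
      utils::write.csv(df, file.path(dir, paste0(prefix, "-folds.csv")),
                       row.names = FALSE)
    }
    writeLines(text, file.path(dir, paste0(prefix, ".txt")))
    return(invisible(text))
  }
  text
}
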