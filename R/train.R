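# Joint optimisation of reconstruction and classification.
#
# The objective is cross-entropy on the softmax output plus lambda times
# the mean squared reconstruction error, both batch-averaged, optimised
# in a single phase ("simultaneously"); an optional reconstruction-only
# pretraining phase is available for ablation. Gradients for the softmax
# + cross-entropy pair are fused (probs - onehot) / batch.

#' Training configuration
#'
#' @slot optimizer one of `"adam"`, `"sgd"`, `"rmsprop"`, `"adadelta"`.
#' @slot learningRate step size (default 1e-4).
#' @slot lrDecay multiplicative decay applied to the learning rate every
#'   `lrDecayEvery` joint epochs (1 = constant rate).
#' @slot lrDecayEvery epochs between decay steps.
#' @slot batchSize minibatch size (default 50).
#' @slot epochs number of passes over the training set (default 40).
#' @slot lambda weight of the reconstruction term (default 1).
#' @slot seed RNG seed for shuffling and dropout.
#' @slot earlyStop patience in epochs on the validation loss (`NA`
#'   disables early stopping).
#' @slot pretrainEpochs reconstruction-only epochs run before joint
#'   training (0 = single-phase joint training).
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 batchSize = "integer", epochs = "integer",
                 lambda = "numeric", seed = "integer",
                 earlyStop = "numeric", pretrainEpochs = "integer",
                 lrDecay = "numeric", lrDecayEvery = "integer"))

setValidity("TrainConfig", function(object) {
  msgs <- character(0)
  if (!(object@optimizer %in% c("adam", "sgd", "rmsprop", "adadelta")))
    msgs <- c(msgs, "unknown optimizer")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msgs <- c(msgs, "lrDecay must lie in (0, 1]")
  if (object@batchSize < 1) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@lambda < 0) msgs <- c(msgs, "lambda must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a training configuration
#'
#' @param optimizer,learningRate,batchSize,epochs,lambda,seed,earlyStop,pretrainEpochs,lrDecay,lrDecayEvery
#'   see [TrainConfig-class]. Defaults: Adam, learning rate 1e-4, batch
#'   size 50, 40 epochs, lambda 1, constant learning rate.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(optimizer = "adam", learningRate = 1e-4,
                        batchSize = 50, epochs = 40, lambda = 1, seed = 1,
                        earlyStop = NA_real_, pretrainEpochs = 0,
                        lrDecay = 1, lrDecayEvery = 3) {
  new("TrainConfig", optimizer = optimizer, learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      lambda = lambda, seed = as.integer(seed),
      earlyStop = as.numeric(earlyStop),
      pretrainEpochs = as.integer(pretrainEpochs), lrDecay = lrDecay,
      lrDecayEvery = as.integer(lrDecayEvery))
}

#' Joint classification + reconstruction loss
#'
#' `cross_entropy(labels, probs) + lambda * mse(original, reconstruction)`,
#' both terms batch-averaged. Probabilities are clamped at 1e-7 so a
#' zero-probability true class yields a large finite loss, never infinity.
#'
#' @param classProbs `[n x nClasses]` matrix of predicted probabilities
#'   (rows summing to 1).
#' @param labels integer 0/1 vector of true labels.
#' @param reconstruction,original equal-shaped arrays for the
#'   reconstruction term (both `NULL` to skip it).
#' @param lambda weight of the reconstruction term.
#' @return List with `total`, `classLoss`, `reconLoss`.
#' @export
jointLoss <- function(classProbs, labels, reconstruction = NULL,
                      original = NULL, lambda = 1) {
  if (nrow(classProbs) != length(labels))
    stop("classProbs and labels disagree in length")
  pTrue <- classProbs[cbind(seq_along(labels), as.integer(labels) + 1L)]
  ce <- -mean(log(pmax(pTrue, 1e-7)))
  rec <- 0
  if (!is.null(reconstruction) && !is.null(original) && lambda > 0) {
    if (!identical(dim(reconstruction), dim(original)) &&
        length(reconstruction) != length(original))
      stop("reconstruction and original shapes disagree")
    rec <- mean((original - reconstruction)^2)
  }
  list(total = ce + lambda * rec, classLoss = ce, reconLoss = rec)
}

# One optimizer step over the named gradient list, updating state in
# place (environments st$m, st$v, st$t).
.optimStep <- function(params, grads, cfg, st, lr = cfg@learningRate) {
  st$t <- st$t + 1
  for (k in names(grads)) {
    g <- grads[[k]]
    if (cfg@optimizer == "sgd") {
      params[[k]] <- params[[k]] - lr * g
    } else if (cfg@optimizer == "rmsprop") {
      v <- if (is.null(st$v[[k]])) g * 0 else st$v[[k]]
      v <- 0.9 * v + 0.1 * g^2
      st$v[[k]] <- v
      params[[k]] <- params[[k]] - lr * g / (sqrt(v) + 1e-8)
    } else if (cfg@optimizer == "adadelta") {
      rho <- 0.95; eps <- 1e-6
      v <- if (is.null(st$v[[k]])) g * 0 else st$v[[k]]
      d <- if (is.null(st$m[[k]])) g * 0 else st$m[[k]]
      v <- rho * v + (1 - rho) * g^2
      up <- sqrt((d + eps) / (v + eps)) * g
      d <- rho * d + (1 - rho) * up^2
      st$v[[k]] <- v; st$m[[k]] <- d
      params[[k]] <- params[[k]] - lr * up
    } else {                            # adam
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      m <- if (is.null(st$m[[k]])) g * 0 else st$m[[k]]
      v <- if (is.null(st$v[[k]])) g * 0 else st$v[[k]]
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      st$m[[k]] <- m; st$v[[k]] <- v
      mhat <- m / (1 - b1^st$t)
      vhat <- v / (1 - b2^st$t)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  params
}

#' Train a model on labeled segments
#'
#' Minibatch training of the joint objective with the configured
#' optimizer. Deterministic given the training seed (shuffling and
#' dropout use one private RNG stream). Aborts with the offending epoch
#' and batch if the loss turns non-finite.
#'
#' @param model a [SeizureModel-class] from [buildModel()].
#' @param train a normalised, labeled [SegmentSet-class].
#' @param val optional validation [SegmentSet-class] (evaluated once per
#'   epoch; enables early stopping).
#' @param config a [TrainConfig-class].
#' @param verbose print one line per epoch.
#' @return List with `model` (trained parameters) and `history` (one row
#'   per completed epoch: losses and accuracies).
#' @export
trainModel <- function(model, train, val = NULL, config = trainConfig(),
                       verbose = FALSE) {
  validObject(config)
  labels <- segmentLabels(train)
  if (length(unique(labels)) < 2 && config@lambda == 0)
    stop("training data must contain both classes")
  xa <- .toModelTensor(segmentTensor(train))
  n <- dim(xa)[4]
  if (!all(dim(xa)[1:2] == model@inputShape))
    stop("model input shape and segment shape disagree")
  nClasses <- model@config@nClasses
  onehot <- matrix(0, n, nClasses)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  params <- model@params
  st <- new.env(parent = emptyenv()); st$m <- list(); st$v <- list(); st$t <- 0
  lambda <- config@lambda
  useRecon <- !model@config@baseline && lambda > 0
  phases <- c(rep("pretrain", config@pretrainEpochs),
              rep("joint", config@epochs))
  history <- list()
  bestVal <- Inf; wait <- 0
  withSeed(config@seed, {
    for (ei in seq_along(phases)) {
      phase <- phases[ei]
      lrEpoch <- config@learningRate *
        config@lrDecay^((ei - 1) %/% config@lrDecayEvery)
      ord <- sample.int(n)
      starts <- seq(1, n, by = config@batchSize)
      epochLoss <- 0; epochCE <- 0; epochRec <- 0; hits <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config@batchSize - 1, n)]
        xb <- xa[, , , idx, drop = FALSE]
        yb <- onehot[idx, , drop = FALSE]
        model@params <- params
        fwd <- .forwardModel(model, xb, training = TRUE)
        loss <- jointLoss(fwd$probs, labels[idx], fwd$recon, xb,
                          if (useRecon) lambda else 0)
        if (!is.finite(loss$total))
          stop(sprintf("non-finite loss at epoch %d, batch %d; aborting",
                       ei, bi))
        nb <- length(idx)
        dLogits <- (fwd$probs - yb) / nb
        if (phase == "pretrain") dLogits <- dLogits * 0
        dRecon <- NULL
        if (useRecon)
          dRecon <- (lambda * 2 / length(xb)) * (fwd$recon - xb)
        grads <- .backwardModel(model, fwd, dLogits, dRecon)
        params <- .optimStep(params, grads, config, st, lrEpoch)
        epochLoss <- epochLoss + loss$total * nb
        epochCE <- epochCE + loss$classLoss * nb
        epochRec <- epochRec + loss$reconLoss * nb
        hits <- hits + sum(max.col(fwd$probs, ties.method = "first") - 1L ==
                             labels[idx])
      }
      model@params <- params
      row <- data.frame(epoch = ei, phase = phase, loss = epochLoss / n,
                        classLoss = epochCE / n, reconLoss = epochRec / n,
                        accuracy = hits / n, valLoss = NA_real_,
                        valAccuracy = NA_real_)
      if (!is.null(val)) {
        vlabels <- segmentLabels(val)
        probs <- predictProbs(model, val)
        recon <- if (useRecon) reconstruct(model, val) else NULL
        vloss <- jointLoss(probs, vlabels, recon,
                           if (useRecon) segmentTensor(val) else NULL,
                           lambda)
        row$valLoss <- vloss$total
        row$valAccuracy <-
          mean(max.col(probs, ties.method = "first") - 1L == vlabels)
      }
      history[[length(history) + 1]] <- row
      if (verbose)
        message(sprintf("epoch %d [%s]: loss %.4f (ce %.4f, mse %.4f), acc %.3f",
                        ei, phase, row$loss, row$classLoss, row$reconLoss,
                        row$accuracy))
      if (!is.null(val) && is.finite(config@earlyStop) &&
          phase == "joint") {
        if (row$valLoss < bestVal - 1e-9) {
          bestVal <- row$valLoss; wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= config@earlyStop) break
        }
      }
    }
  })
  model@params <- params
  list(model = model, history = do.call(rbind, history))
}
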