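# Forward and backward passes over layer descriptor lists.
#
# Activations flow as (H, W, C, N) arrays through the convolutional
# stages, (N, F, T) arrays through the recurrent stages and (N, F)
# matrices through the dense stages. The softmax layer's backward pass is
# fused with the cross-entropy loss: the training loop supplies the
# gradient with respect to the logits, so softmax backward is the
# identity.

.actCode <- function(act) {
  switch(act, linear = 0L, relu = 1L, sigmoid = 2L,
         stop("unknown activation ", act))
}

.actDeriv <- function(y, act) {
  switch(act,
         linear = 1,
         relu = (y > 0) * 1,
         sigmoid = y * (1 - y))
}

.fwdLayers <- function(layers, params, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      y <- .conv2dFwd(x, dim(x), params[[paste0(ly$id, ".W")]],
                      params[[paste0(ly$id, ".b")]], .actCode(ly$act))
      caches[[li]] <- list(x = x, y = y)
      x <- y
    } else if (ly$type == "pool") {
      r <- .maxpoolFwd(x, dim(x))
      caches[[li]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else if (ly$type == "resize") {
      caches[[li]] <- list(xdim = dim(x))
      x <- .resizeNearestFwd(x, dim(x), ly$target[1], ly$target[2])
    } else if (ly$type == "flatten") {
      d <- dim(x)
      caches[[li]] <- list(xdim = d)
      x <- t(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
    } else if (ly$type == "seq") {
      d <- dim(x)                       # (h, w, c, N)
      caches[[li]] <- list(xdim = d)
      a <- aperm(x, c(4, 1, 3, 2))      # (N, h, c, w)
      dim(a) <- c(d[4], d[1] * d[3], d[2])
      x <- a                            # (N, F = h*c, T = w)
    } else if (ly$type == "lstm") {
      pf <- function(n) params[[paste0(ly$id, ".fwd.", n)]]
      rf <- .lstmFwd(x, dim(x), pf("Wx"), pf("Wh"), pf("b"))
      if (ly$bidir) {
        Tn <- dim(x)[3]; U <- ly$units
        pb <- function(n) params[[paste0(ly$id, ".bwd.", n)]]
        xr <- x[, , Tn:1, drop = FALSE]
        rb <- .lstmFwd(xr, dim(x), pb("Wx"), pb("Wh"), pb("b"))
        out <- array(0, c(dim(x)[1], 2 * U, Tn))
        out[, 1:U, ] <- rf$h
        out[, U + 1:U, ] <- rb$h[, , Tn:1, drop = FALSE]
        caches[[li]] <- list(x = x, xr = xr, rf = rf, rb = rb)
      } else {
        out <- rf$h
        caches[[li]] <- list(x = x, rf = rf)
      }
      x <- out
    } else if (ly$type == "meantime") {
      caches[[li]] <- list(xdim = dim(x))
      x <- rowMeans(x, dims = 2)
    } else if (ly$type == "dense") {
      z <- x %*% params[[paste0(ly$id, ".W")]]
      z <- sweep(z, 2, params[[paste0(ly$id, ".b")]], "+")
      y <- if (ly$act == "relu") pmax(z, 0) else z
      caches[[li]] <- list(x = x, y = y)
      x <- y
    } else if (ly$type == "densetime") {
      d <- dim(x)                       # (N, F, T)
      m <- matrix(aperm(x, c(1, 3, 2)), ncol = d[2])
      z <- m %*% params[[paste0(ly$id, ".W")]]
      z <- sweep(z, 2, params[[paste0(ly$id, ".b")]], "+")
      y <- if (ly$act == "relu") pmax(z, 0) else z
      out <- aperm(array(y, c(d[1], d[3], ly$dout)), c(1, 3, 2))
      caches[[li]] <- list(m = m, y = y, xdim = d)
      x <- out
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- (runif(length(x)) >= ly$p) / (1 - ly$p)
        dim(mask) <- dim(x)
        caches[[li]] <- list(mask = mask)
        x <- x * mask
      } else caches[[li]] <- list(mask = NULL)
    } else if (ly$type == "softmax") {
      m <- x - apply(x, 1, max)
      e <- exp(m)
      x <- e / rowSums(e)
      caches[[li]] <- list()
    } else stop("unknown layer type ", ly$type)
  }
  list(out = x, caches = caches)
}

# Backward walk; `grads` is an environment keyed like params; returns the
# gradient with respect to the block input.
.bwdLayers <- function(layers, params, caches, dout, grads) {
  addGrad <- function(key, g) {
    if (is.null(grads[[key]])) grads[[key]] <- g
    else grads[[key]] <- grads[[key]] + g
  }
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    cache <- caches[[li]]
    if (ly$type == "conv") {
      r <- .conv2dBwd(cache$x, dim(cache$x), params[[paste0(ly$id, ".W")]],
                      cache$y, dout, .actCode(ly$act))
      addGrad(paste0(ly$id, ".W"), r$dW)
      addGrad(paste0(ly$id, ".b"), r$db)
      dout <- r$dx
    } else if (ly$type == "pool") {
      dout <- .maxpoolBwd(cache$idx, dout, cache$xdim)
    } else if (ly$type == "resize") {
      dout <- .resizeNearestBwd(dout, dim(dout), cache$xdim[1],
                                cache$xdim[2])
    } else if (ly$type == "flatten") {
      d <- cache$xdim
      dout <- array(t(dout), d)
    } else if (ly$type == "seq") {
      d <- cache$xdim
      dim(dout) <- c(d[4], d[1], d[3], d[2])
      dout <- aperm(dout, c(2, 4, 3, 1))
    } else if (ly$type == "lstm") {
      pf <- function(n) params[[paste0(ly$id, ".fwd.", n)]]
      U <- ly$units
      if (ly$bidir) {
        Tn <- dim(cache$x)[3]
        pb <- function(n) params[[paste0(ly$id, ".bwd.", n)]]
        dhf <- dout[, 1:U, , drop = FALSE]
        dhb <- dout[, U + 1:U, Tn:1, drop = FALSE]
        r1 <- .lstmBwd(cache$x, dim(cache$x), pf("Wx"), pf("Wh"),
                       cache$rf$g, cache$rf$c, cache$rf$h, dhf)
        r2 <- .lstmBwd(cache$xr, dim(cache$xr), pb("Wx"), pb("Wh"),
                       cache$rb$g, cache$rb$c, cache$rb$h, dhb)
        addGrad(paste0(ly$id, ".fwd.Wx"), r1$dWx)
        addGrad(paste0(ly$id, ".fwd.Wh"), r1$dWh)
        addGrad(paste0(ly$id, ".fwd.b"), r1$db)
        addGrad(paste0(ly$id, ".bwd.Wx"), r2$dWx)
        addGrad(paste0(ly$id, ".bwd.Wh"), r2$dWh)
        addGrad(paste0(ly$id, ".bwd.b"), r2$db)
        dout <- r1$dx + r2$dx[, , Tn:1, drop = FALSE]
      } else {
        r1 <- .lstmBwd(cache$x, dim(cache$x), pf("Wx"), pf("Wh"),
                       cache$rf$g, cache$rf$c, cache$rf$h, dout)
        addGrad(paste0(ly$id, ".fwd.Wx"), r1$dWx)
        addGrad(paste0(ly$id, ".fwd.Wh"), r1$dWh)
        addGrad(paste0(ly$id, ".fwd.b"), r1$db)
        dout <- r1$dx
      }
    } else if (ly$type == "meantime") {
      d <- cache$xdim
      dout <- array(dout / d[3], d)
    } else if (ly$type == "dense") {
      dpre <- dout * .actDeriv(cache$y, ly$act)
      addGrad(paste0(ly$id, ".W"), crossprod(cache$x, dpre))
      addGrad(paste0(ly$id, ".b"), colSums(dpre))
      dout <- tcrossprod(dpre, params[[paste0(ly$id, ".W")]])
    } else if (ly$type == "densetime") {
      d <- cache$xdim
      dy2 <- matrix(aperm(dout, c(1, 3, 2)), ncol = ly$dout)
      dpre <- dy2 * .actDeriv(cache$y, ly$act)
      addGrad(paste0(ly$id, ".W"), crossprod(cache$m, dpre))
      addGrad(paste0(ly$id, ".b"), colSums(dpre))
      dm <- tcrossprod(dpre, params[[paste0(ly$id, ".W")]])
      dout <- aperm(array(dm, c(d[1], d[3], d[2])), c(1, 3, 2))
    } else if (ly$type == "dropout") {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
    } else if (ly$type == "softmax") {
      # fused with cross-entropy: incoming gradient is already w.r.t. logits
    }
  }
  dout
}

# Full forward pass: returns class probabilities, reconstruction (NULL
# for the baseline) and all caches needed for the backward pass.
.forwardModel <- function(model, x, training = FALSE) {
  enc <- .fwdLayers(model@encoder$layers, model@params, x, training)
  dec <- NULL
  if (!model@config@baseline)
    dec <- .fwdLayers(model@decoder$layers, model@params, enc$out, training)
  head <- .fwdLayers(model@head$layers, model@params, enc$out, training)
  list(probs = head$out, recon = if (is.null(dec)) NULL else dec$out,
       enc = enc, dec = dec, head = head)
}

# Full backward pass; dLogits is the loss gradient w.r.t. the softmax
# logits, dRecon w.r.t. the reconstruction (NULL to skip the decoder).
.backwardModel <- function(model, fwd, dLogits, dRecon = NULL) {
  grads <- new.env(parent = emptyenv())
  dBottle <- .bwdLayers(model@head$layers, model@params, fwd$head$caches,
                        dLogits, grads)
  if (!is.null(dRecon) && !is.null(fwd$dec))
    dBottle <- dBottle + .bwdLayers(model@decoder$layers, model@params,
                                    fwd$dec$caches, dRecon, grads)
  .bwdLayers(model@encoder$layers, model@params, fwd$enc$caches, dBottle,
             grads)
  as.list(grads)
}

#' Class probabilities for a batch of segments
#'
#' Runs the encoder and classification head in evaluation mode (dropout
#' off, no reconstruction).
#'
#' @param model a trained [SeizureModel-class].
#' @param segments a normalised [SegmentSet-class] (or a plain
#'   `[n x channels x samples]` array).
#' @return Matrix `[n x nClasses]` of softmax probabilities.
#' @export
predictProbs <- function(model, segments) {
  x <- if (is(segments, "SegmentSet")) segmentTensor(segments) else segments
  xa <- .toModelTensor(x)
  enc <- .fwdLayers(model@encoder$layers, model@params, xa, FALSE)
  head <- .fwdLayers(model@head$layers, model@params, enc$out, FALSE)
  head$out
}

#' Predicted labels for a batch of segments
#'
#' @inheritParams predictProbs
#' @return Integer vector of 0/1 labels (1 = ictal).
#' @export
predictLabels <- function(model, segments) {
  probs <- predictProbs(model, segments)
  as.integer(max.col(probs, ties.method = "first") - 1L)
}

#' Reconstruct segments through the autoencoder
#'
#' @inheritParams predictProbs
#' @return Array `[n x channels x samples]` of reconstructions.
#' @export
reconstruct <- function(model, segments) {
  if (model@config@baseline) stop("the DCNN baseline has no decoder")
  x <- if (is(segments, "SegmentSet")) segmentTensor(segments) else segments
  xa <- .toModelTensor(x)
  enc <- .fwdLayers(model@encoder$layers, model@params, xa, FALSE)
  dec <- .fwdLayers(model@decoder$layers, model@params, enc$out, FALSE)
  d <- dim(dec$out)                     # (H, W, 1, N)
  aperm(array(dec$out, c(d[1], d[2], d[4])), c(3, 1, 2))
}
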