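# Shared fixtures built in code.

# small labeled SegmentSet with recognisable per-segment values
makeToySegments <- function(n = 10, channels = 2, samples = 32, fs = 32,
                            nIctal = n %/% 2) {
  tensor <- array(0, c(n, channels, samples))
  for (i in seq_len(n)) tensor[i, , ] <- i + matrix(rnorm(channels * samples,
                                                          sd = 0.1),
                                                    channels, samples)
  labels <- c(rep(1L, nIctal), rep(0L, n - nIctal))
  deepeeg:::.segmentSet(tensor, labels, fs, samples / fs)
}

# small separable segment set straight from the synthetic pipeline
makeSmallSeparableSet <- function(n = 64, channels = 8, window = 1,
                                  seed = 7) {
  segs <- makeBenchmarkSegments(nSegments = n, nChannels = channels,
                                segmentLength = window, gain = 5,
                                seed = seed)
  segs
}

# direct (non-im2col) 2D convolution used as the kernel oracle
naiveConv2d <- function(x, W, b, relu = TRUE) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]; Cout <- ncol(W)
  K <- sqrt(nrow(W) / C)
  P <- (K - 1) / 2
  y <- array(0, c(H, Wd, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    acc <- b[co]
    for (c in seq_len(C)) for (dj in seq_len(K) - P - 1)
      for (di in seq_len(K) - P - 1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
          q <- (c - 1) * K * K + (dj + P) * K + (di + P) + 1
          acc <- acc + x[ii, jj, c] * W[q, co]
        }
      }
    y[i, j, co] <- if (relu) max(acc, 0) else acc
  }
  y
}

# step-by-step LSTM forward used as the kernel oracle
naiveLstm <- function(x, Wx, Wh, b) {
  sig <- function(z) 1 / (1 + exp(-z))
  N <- dim(x)[1]; Tn <- dim(x)[3]; U <- nrow(Wh)
  h <- matrix(0, N, U); cc <- matrix(0, N, U)
  out <- array(0, c(N, U, Tn))
  for (t in seq_len(Tn)) {
    Z <- x[, , t, drop = FALSE]
    dim(Z) <- dim(x)[1:2]
    Z <- Z %*% Wx + h %*% Wh + matrix(b, N, 4 * U, byrow = TRUE)
    gi <- sig(Z[, 1:U, drop = FALSE])
    gf <- sig(Z[, U + 1:U, drop = FALSE])
    gg <- tanh(Z[, 2 * U + 1:U, drop = FALSE])
    go <- sig(Z[, 3 * U + 1:U, drop = FALSE])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    out[, , t] <- h
  }
  out
}
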