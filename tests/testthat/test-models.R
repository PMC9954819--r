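# Architecture shape contracts and kernel correctness.

test_that("encoder shape arithmetic follows stage-by-stage floor division", {
  s <- encoderShapes(c(23, 1024))
  expect_equal(vapply(s$prePool, `[`, integer(1), 1), c(23L, 11L, 5L, 2L))
  expect_equal(vapply(s$prePool, `[`, integer(1), 2),
               c(1024L, 512L, 256L, 128L))
  expect_equal(s$bottleneck, c(1L, 64L))
  expect_equal(encoderShapes(c(23, 256))$bottleneck, c(1L, 16L))
  # the electrode axis clamps at one row; the time axis keeps halving
  expect_equal(encoderShapes(c(8, 1024))$bottleneck, c(1L, 64L))
})

test_that("planes whose time axis collapses are rejected at build time", {
  expect_error(encoderShapes(c(8, 8)), "collapses")
  expect_error(buildEncoder(modelConfig(), c(8, 8)), "collapses")
})

test_that("encoder descriptor alternates conv and pool with 32/32/64/64 filters", {
  enc <- buildEncoder(modelConfig(), c(23, 1024))
  types <- vapply(enc$layers, `[[`, character(1), "type")
  expect_equal(types, rep(c("conv", "pool"), 4))
  convs <- Filter(function(l) l$type == "conv", enc$layers)
  expect_equal(vapply(convs, `[[`, numeric(1), "cout"), c(32, 32, 64, 64))
  expect_true(all(vapply(convs, `[[`, character(1), "act") == "relu"))
  expect_equal(enc$bottleneck, c(1, 64, 64))
})

test_that("decoder mirrors the encoder and restores the input shape", {
  cfg <- modelConfig()
  for (width in c(256L, 512L, 1024L)) {
    enc <- buildEncoder(cfg, c(23L, width))
    dec <- buildDecoder(cfg, enc)
    expect_equal(dec$outputShape, c(23L, width))
    convs <- Filter(function(l) l$type == "conv", dec$layers)
    expect_equal(vapply(convs, `[[`, numeric(1), "cout"), c(64, 32, 32, 1))
    expect_equal(convs[[4]]$act, "sigmoid")
  }
  expect_error(buildDecoder(modelConfig(baseline = TRUE),
                            buildEncoder(cfg, c(23, 256))),
               "baseline")
})

test_that("reconstruction output shape equals the input shape in a real pass", {
  set.seed(20)
  for (width in c(256L, 512L, 1024L)) {
    m <- buildModel(modelConfig(head = "mlp", seed = 2), c(23L, width))
    x <- array(runif(23 * width), c(23, width, 1, 1))
    fwd <- deepeeg:::.forwardModel(m, x)
    expect_equal(dim(fwd$recon), c(23L, width, 1L, 1L))
    expect_true(all(is.finite(fwd$recon)))
  }
})

test_that("bilstm head reads the bottleneck as a 64-step sequence", {
  head <- buildHead(modelConfig(head = "bilstm"), c(1, 64, 64))
  expect_equal(head$seqLen, 64)
  expect_equal(head$stepFeatures, 64)
  expect_equal(head$recurrentWidth, 160)       # two directions x 80 units
  lstm <- Filter(function(l) l$type == "lstm", head$layers)[[1]]
  expect_true(lstm$bidir)
  expect_equal(lstm$units, 80)
  expect_error(modelConfig(head = "gru"), "head must be")
})

test_that("mlp head parameter count matches the closed form", {
  cfg <- modelConfig(head = "mlp", baseline = TRUE, seed = 1)
  m <- buildModel(cfg, c(23, 256))
  flat <- prod(m@encoder$bottleneck)           # 1 x 16 x 64
  headParams <- flat * 50 + 50 + 50 * 2 + 2
  convParams <- sum((c(1, 32, 32, 64) * 9 + 1) * c(32, 32, 64, 64))
  expect_equal(parameterCount(m), headParams + convParams)
})

test_that("all roster models build and run finitely on all window lengths", {
  set.seed(30)
  roster <- list(list(head = "mlp", baseline = FALSE),
                 list(head = "lstm", baseline = FALSE),
                 list(head = "bilstm", baseline = FALSE),
                 list(head = "mlp", baseline = TRUE))
  for (r in roster) {
    for (width in c(256L, 512L, 1024L)) {
      cfg <- modelConfig(head = r$head, baseline = r$baseline, seed = 7)
      m <- buildModel(cfg, c(23L, width))
      expect_equal(m@nOutputs, if (r$baseline) 1L else 2L)
      # strict dimension reduction into the bottleneck
      expect_lt(prod(m@encoder$bottleneck), 23 * width)
    }
    # forward finiteness (checked at one window for runtime)
    m <- buildModel(modelConfig(head = r$head, baseline = r$baseline,
                                seed = 7), c(23L, 256L))
    x <- array(runif(23 * 256 * 3), c(23, 256, 1, 3))
    fwd <- deepeeg:::.forwardModel(m, x)
    expect_true(all(is.finite(fwd$probs)))
    expect_equal(rowSums(fwd$probs), rep(1, 3), tolerance = 1e-6)
    if (!r$baseline) expect_true(all(is.finite(fwd$recon)))
  }
})

test_that("per-sample outputs are invariant to batch order", {
  set.seed(31)
  m <- buildModel(modelConfig(head = "bilstm", seed = 3), c(8L, 64L))
  x <- array(runif(8 * 64 * 6), c(6, 8, 64))
  p1 <- predictProbs(m, x)
  perm <- c(4, 1, 6, 2, 5, 3)
  p2 <- predictProbs(m, x[perm, , , drop = FALSE])
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
})

test_that("conv kernel agrees with direct convolution", {
  set.seed(40)
  x <- array(rnorm(5 * 7 * 2 * 3), c(5, 7, 2, 3))
  W <- matrix(rnorm(2 * 9 * 4), 18, 4)
  b <- rnorm(4)
  y <- deepeeg:::.conv2dFwd(x, dim(x), W, b, 1L)
  for (n in 1:3)
    expect_equal(y[, , , n], naiveConv2d(x[, , , n], W, b, TRUE),
                 tolerance = 1e-12)
  # height-1 planes only use the central kernel row
  x1 <- array(rnorm(1 * 8 * 2 * 2), c(1, 8, 2, 2))
  y1 <- deepeeg:::.conv2dFwd(x1, dim(x1), W, b, 0L)
  for (n in 1:2) {
    ref <- naiveConv2d(array(x1[, , , n], c(1, 8, 2)), W, b, FALSE)
    expect_equal(as.vector(y1[, , , n]), as.vector(ref), tolerance = 1e-12)
  }
})

test_that("maxpool kernel floors, clamps height 1 and tracks argmax", {
  set.seed(41)
  x <- array(rnorm(5 * 7 * 2 * 2), c(5, 7, 2, 2))
  r <- deepeeg:::.maxpoolFwd(x, dim(x))
  expect_equal(dim(r$y), c(2, 3, 2, 2))        # floor(5/2), floor(7/2)
  for (n in 1:2) for (c in 1:2) for (i in 1:2) for (j in 1:3)
    expect_equal(r$y[i, j, c, n],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n]))
  x1 <- array(rnorm(1 * 6 * 1 * 1), c(1, 6, 1, 1))
  r1 <- deepeeg:::.maxpoolFwd(x1, dim(x1))
  expect_equal(dim(r1$y), c(1, 3, 1, 1))
  expect_equal(r1$y[1, , 1, 1],
               vapply(1:3, function(j) max(x1[1, (2 * j - 1):(2 * j), 1, 1]),
                      numeric(1)))
  # backward routes gradient to the argmax only
  dy <- r$y * 0 + 1
  dx <- deepeeg:::.maxpoolBwd(r$idx, dy, dim(x))
  expect_equal(sum(dx), length(dy))
  expect_true(all(dx %in% c(0, 1)))
})

test_that("nearest-neighbour resize matches index mapping both ways", {
  set.seed(42)
  x <- array(rnorm(2 * 5 * 3 * 2), c(2, 5, 3, 2))
  y <- deepeeg:::.resizeNearestFwd(x, dim(x), 4L, 10L)
  for (n in 1:2) for (c in 1:3) for (i in 1:4) for (j in 1:10)
    expect_equal(y[i, j, c, n],
                 x[floor((i - 1) * 2 / 4) + 1, floor((j - 1) * 5 / 10) + 1,
                   c, n])
  # backward is the exact adjoint: <y, A x> = <A' y, x>
  dy <- array(rnorm(length(y)), dim(y))
  dx <- deepeeg:::.resizeNearestBwd(dy, dim(dy), 2L, 5L)
  expect_equal(sum(dy * y), sum(dx * x), tolerance = 1e-10)
})

test_that("lstm kernel agrees with a step-by-step reference", {
  set.seed(43)
  N <- 3; Fdim <- 4; Tn <- 6; U <- 5
  x <- array(rnorm(N * Fdim * Tn), c(N, Fdim, Tn))
  Wx <- matrix(rnorm(Fdim * 4 * U), Fdim, 4 * U)
  Wh <- matrix(rnorm(U * 4 * U) * 0.3, U, 4 * U)
  b <- rnorm(4 * U)
  r <- deepeeg:::.lstmFwd(x, dim(x), Wx, Wh, b)
  expect_equal(r$h, naiveLstm(x, Wx, Wh, b), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the whole model", {
  set.seed(44)
  m <- buildModel(modelConfig(head = "bilstm", seed = 3), c(8L, 64L))
  x <- array(runif(8 * 64 * 4), c(8, 64, 1, 4))
  labs <- c(0L, 1L, 1L, 0L)
  Y <- matrix(0, 4, 2); Y[cbind(1:4, labs + 1L)] <- 1
  lossAt <- function(params) {
    m@params <- params
    f <- deepeeg:::.forwardModel(m, x)
    jointLoss(f$probs, labs, f$recon, x, 1)$total
  }
  fwd <- deepeeg:::.forwardModel(m, x)
  gr <- deepeeg:::.backwardModel(m, fwd, (fwd$probs - Y) / 4,
                                 (2 / length(x)) * (fwd$recon - x))
  p0 <- m@params
  set.seed(45)
  for (k in names(gr)) {
    i <- sample(length(p0[[k]]), 1)
    eps <- 1e-5
    pp <- p0; pp[[k]][i] <- pp[[k]][i] + eps
    pm <- p0; pm[[k]][i] <- pm[[k]][i] - eps
    num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
    # absolute-or-relative: finite differences are noisy at ReLU kinks
    expect_lt(abs(num - gr[[k]][i]), 1e-4 + 1e-2 * abs(num))
  }
})

test_that("model manifest serializes the architecture", {
  m <- buildModel(modelConfig(head = "bilstm", seed = 1), c(8, 256))
  path <- withr::local_tempfile(fileext = ".json")
  writeModelManifest(m, path)
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expect_equal(man$model, "dcae")
  expect_equal(man$head, "bilstm")
  expect_equal(man$config$decoderFilters, c(64, 32, 32, 1))
  expect_equal(man$parameterCount, parameterCount(m))
})
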