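# Architecture descriptors for the DCAE and its classification heads.
#
# The encoder alternates four 3x3 same-padded ReLU convolutions
# (32, 32, 64, 64 filters) with four 2x2 max-pooling stages; the decoder
# mirrors it with four nearest-neighbour up-sampling stages and
# convolutions of 64, 32, 32 and 1 filters (final sigmoid, since inputs
# are min-max scaled to [0, 1]), resizing each stage to the encoder's
# pre-pool shape so the reconstruction exactly matches the input shape.
# The bottleneck feeds an MLP, LSTM or Bi-LSTM head; the recurrent heads
# read the reduced time axis as the sequence dimension. The DCNN baseline
# is the encoder plus MLP head without a decoder.
#
# Pooling uses floor division along both axes, except that the electrode
# (height) axis clamps at 1: once collapsed to a single row it passes
# through later pooling stages unchanged, so recordings with fewer than
# 16 channels remain usable. The time axis must survive four halvings,
# i.e. segments need at least 16 samples.

#' Model configuration
#'
#' @slot encoderFilters filters of the four encoder convolutions.
#' @slot decoderFilters filters of the four decoder convolutions (the
#'   last must be 1, the single reconstructed plane).
#' @slot kernel odd convolution kernel size (default 3).
#' @slot pool pooling factor per stage (2).
#' @slot head one of `"mlp"`, `"lstm"`, `"bilstm"`.
#' @slot bilstmUnits recurrent units per direction.
#' @slot denseUnits width of the fully connected layer before softmax.
#' @slot dropoutRate probability of dropping a unit at the dense-layer
#'   input during training.
#' @slot nClasses number of output classes.
#' @slot baseline `TRUE` for the DCNN baseline (encoder + head only, no
#'   decoder and no reconstruction output).
#' @slot avgPoolPosition `"before_dense"` (temporal average pooling before
#'   the fully connected layer, the functional reading) or
#'   `"after_dense"` (dense layer applied per time step, then averaged).
#' @slot seed weight-initialisation seed.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(encoderFilters = "numeric", decoderFilters = "numeric",
                 kernel = "integer", pool = "integer", head = "character",
                 bilstmUnits = "integer", denseUnits = "integer",
                 dropoutRate = "numeric", nClasses = "integer",
                 baseline = "logical", avgPoolPosition = "character",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  if (length(object@encoderFilters) != 4)
    msgs <- c(msgs, "encoder must have exactly 4 convolution stages")
  if (length(object@decoderFilters) != 4)
    msgs <- c(msgs, "decoder must have exactly 4 convolution stages")
  else if (object@decoderFilters[4] != 1)
    msgs <- c(msgs, "final decoder stage must have exactly 1 filter")
  if (!(object@head %in% c("mlp", "lstm", "bilstm")))
    msgs <- c(msgs, "head must be one of mlp, lstm, bilstm")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msgs <- c(msgs, "dropoutRate must lie in [0, 1)")
  if (object@kernel %% 2 != 1 || object@kernel < 1)
    msgs <- c(msgs, "kernel must be a positive odd size")
  if (object@pool != 2)
    msgs <- c(msgs, "only pool = 2 is supported")
  if (!(object@avgPoolPosition %in% c("before_dense", "after_dense")))
    msgs <- c(msgs, "avgPoolPosition must be before_dense or after_dense")
  if (length(msgs)) msgs else TRUE
})

#' Construct a model configuration
#'
#' Defaults follow the reference architecture: encoder filters
#' 32/32/64/64, decoder filters 64/32/32/1, 3x3 kernels, 2x2 pooling,
#' Bi-LSTM head with 80 units per direction, a 50-unit dense layer,
#' dropout 0.75 and a 2-class softmax output.
#'
#' @param head classification head: `"mlp"`, `"lstm"` or `"bilstm"`.
#' @param baseline `TRUE` builds the DCNN baseline (no decoder).
#' @param encoderFilters,decoderFilters,kernel,pool,bilstmUnits,denseUnits,dropoutRate,nClasses,avgPoolPosition,seed
#'   see the corresponding [ModelConfig-class] slots.
#' @return A [ModelConfig-class].
#' @examples
#' cfg <- modelConfig(head = "bilstm")
#' model <- buildModel(cfg, inputShape = c(23, 1024))
#' model
#' @export
modelConfig <- function(head = "bilstm", baseline = FALSE,
                        encoderFilters = c(32, 32, 64, 64),
                        decoderFilters = c(64, 32, 32, 1), kernel = 3,
                        pool = 2, bilstmUnits = 80, denseUnits = 50,
                        dropoutRate = 0.75, nClasses = 2,
                        avgPoolPosition = "before_dense", seed = 1) {
  new("ModelConfig", encoderFilters = encoderFilters,
      decoderFilters = decoderFilters, kernel = as.integer(kernel),
      pool = as.integer(pool), head = head,
      bilstmUnits = as.integer(bilstmUnits),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate,
      nClasses = as.integer(nClasses), baseline = baseline,
      avgPoolPosition = avgPoolPosition, seed = as.integer(seed))
}

# One pooling stage: floor division on both axes, height clamped at 1.
.poolShape <- function(shape) {
  c(if (shape[1] >= 2L) shape[1] %/% 2L else 1L, shape[2] %/% 2L)
}

#' Encoder shape arithmetic
#'
#' Stage-by-stage spatial shapes of the encoder for a given input plane:
#' heights and widths are integer-halved at each of the four pooling
#' stages (height clamps at one row; the time axis must stay positive).
#'
#' @param inputShape `c(n_channels, segment_samples)`.
#' @return List with `prePool` (shapes entering each pooling stage) and
#'   `bottleneck` (`c(height, width)` of the latent representation).
#' @export
encoderShapes <- function(inputShape) {
  shape <- as.integer(inputShape)
  prePool <- vector("list", 4)
  for (stage in 1:4) {
    prePool[[stage]] <- shape
    shape <- .poolShape(shape)
    if (shape[2] < 1)
      stop(sprintf(
        "input plane %dx%d collapses at pooling stage %d: segments need >= 16 samples",
        inputShape[1], inputShape[2], stage))
  }
  list(prePool = prePool, bottleneck = shape)
}

#' Build the encoder descriptor
#'
#' Eight alternating stages: four same-padded ReLU convolutions with the
#' configured filter counts, each followed by 2x2 max pooling.
#'
#' @param config a [ModelConfig-class].
#' @param inputShape `c(n_channels, segment_samples)`.
#' @return List with `layers`, `prePool` shapes, `bottleneck`
#'   `c(height, width, featureMaps)`.
#' @export
buildEncoder <- function(config, inputShape) {
  validObject(config)
  shapes <- encoderShapes(inputShape)
  filters <- as.integer(config@encoderFilters)
  cin <- 1L
  layers <- list()
  for (stage in 1:4) {
    layers[[length(layers) + 1]] <- list(
      type = "conv", id = sprintf("enc_conv%d", stage), cin = cin,
      cout = filters[stage], act = "relu", kernel = config@kernel)
    layers[[length(layers) + 1]] <- list(
      type = "pool", id = sprintf("enc_pool%d", stage))
    cin <- filters[stage]
  }
  list(layers = layers, prePool = shapes$prePool,
       bottleneck = c(shapes$bottleneck, filters[4]))
}

#' Build the decoder descriptor
#'
#' Four up-sampling stages, each resizing (nearest neighbour) to the
#' matching encoder pre-pool shape — undoing the floor losses of pooling —
#' followed by a convolution; filters 64/32/32/1, final activation
#' sigmoid. Reconstruction shape equals the encoder input shape exactly.
#'
#' @param config a [ModelConfig-class] (non-baseline).
#' @param encoder descriptor from [buildEncoder()].
#' @return List with `layers` and `outputShape`.
#' @export
buildDecoder <- function(config, encoder) {
  validObject(config)
  if (config@baseline)
    stop("configuration error: the DCNN baseline has no decoder")
  filters <- as.integer(config@decoderFilters)
  cin <- encoder$bottleneck[3]
  layers <- list()
  for (stage in 1:4) {
    target <- encoder$prePool[[5 - stage]]
    layers[[length(layers) + 1]] <- list(
      type = "resize", id = sprintf("dec_up%d", stage),
      target = as.integer(target))
    layers[[length(layers) + 1]] <- list(
      type = "conv", id = sprintf("dec_conv%d", stage), cin = cin,
      cout = filters[stage], act = if (stage == 4) "sigmoid" else "relu",
      kernel = config@kernel)
    cin <- filters[stage]
  }
  list(layers = layers, outputShape = encoder$prePool[[1]])
}

#' Build the classification head descriptor
#'
#' `mlp`: flatten, dense(ReLU), dropout, softmax. `lstm`/`bilstm`: the
#' bottleneck is read as a sequence along its reduced time axis (features
#' = reduced height x feature maps per step), passed through the
#' recurrent layer returning per-step outputs, temporally average-pooled,
#' then dense(ReLU), dropout, softmax. With
#' `avgPoolPosition = "after_dense"` the dense layer is applied per time
#' step and the average taken afterwards (the literal layer order).
#'
#' @param config a [ModelConfig-class].
#' @param bottleneck `c(height, width, featureMaps)` from [buildEncoder()].
#' @return List with `layers` and head metadata (`seqLen`, `stepFeatures`,
#'   `recurrentWidth` for recurrent heads).
#' @export
buildHead <- function(config, bottleneck) {
  validObject(config)
  h <- bottleneck[1]; w <- bottleneck[2]; cmaps <- bottleneck[3]
  du <- config@denseUnits; nc <- config@nClasses
  layers <- list()
  meta <- list()
  if (config@head == "mlp") {
    flat <- h * w * cmaps
    layers <- list(
      list(type = "flatten", id = "head_flatten"),
      list(type = "dense", id = "head_dense1", din = flat, dout = du,
           act = "relu"),
      list(type = "dropout", id = "head_dropout", p = config@dropoutRate),
      list(type = "dense", id = "head_dense2", din = du, dout = nc,
           act = "linear"),
      list(type = "softmax", id = "head_softmax"))
  } else {
    bidir <- config@head == "bilstm"
    stepF <- h * cmaps
    recW <- config@bilstmUnits * (if (bidir) 2L else 1L)
    meta <- list(seqLen = w, stepFeatures = stepF, recurrentWidth = recW)
    layers <- list(
      list(type = "seq", id = "head_seq"),
      list(type = "lstm", id = "head_lstm", fin = stepF,
           units = config@bilstmUnits, bidir = bidir))
    if (config@avgPoolPosition == "before_dense") {
      layers <- c(layers, list(
        list(type = "meantime", id = "head_avgpool"),
        list(type = "dense", id = "head_dense1", din = recW, dout = du,
             act = "relu"),
        list(type = "dropout", id = "head_dropout", p = config@dropoutRate),
        list(type = "dense", id = "head_dense2", din = du, dout = nc,
             act = "linear")))
    } else {
      layers <- c(layers, list(
        list(type = "densetime", id = "head_dense1", din = recW, dout = du,
             act = "relu"),
        list(type = "meantime", id = "head_avgpool"),
        list(type = "dropout", id = "head_dropout", p = config@dropoutRate),
        list(type = "dense", id = "head_dense2", din = du, dout = nc,
             act = "linear")))
    }
    layers <- c(layers, list(list(type = "softmax", id = "head_softmax")))
  }
  c(list(layers = layers), meta)
}

#' Full seizure-detection model
#'
#' @slot config the [ModelConfig-class].
#' @slot inputShape `c(n_channels, segment_samples)`.
#' @slot encoder,decoder,head layer descriptor lists (decoder empty for
#'   the DCNN baseline).
#' @slot params named list of weight arrays.
#' @slot nOutputs 2 for DCAE variants (class probabilities +
#'   reconstruction), 1 for the baseline.
#' @exportClass SeizureModel
setClass("SeizureModel",
  representation(config = "ModelConfig", inputShape = "integer",
                 encoder = "list", decoder = "list", head = "list",
                 params = "list", nOutputs = "integer"))

setMethod("show", "SeizureModel", function(object) {
  cfg <- object@config
  bn <- object@encoder$bottleneck
  cat(sprintf("SeizureModel: %s (%s), input %dx%d -> bottleneck %dx%dx%d\n",
              if (cfg@baseline) "DCNN" else "DCAE",
              toupper(cfg@head), object@inputShape[1], object@inputShape[2],
              bn[1], bn[2], bn[3]))
  cat(sprintf("  %d outputs, %d trainable parameters\n", object@nOutputs,
              parameterCount(object)))
})

# seeded uniform fan-in initialisation: U(-lim, lim) with
# lim = sqrt(6/fanin) for ReLU layers (He scaling, which keeps activation
# variance roughly constant through the deep ReLU stack) and
# lim = sqrt(1/fanin) elsewhere.
.initMatrix <- function(nrow, ncol, fanin, relu = FALSE) {
  lim <- if (relu) sqrt(6 / fanin) else sqrt(1 / fanin)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

.initLayerParams <- function(layers, kernel) {
  params <- list()
  for (ly in layers) {
    if (ly$type == "conv") {
      kk <- ly$kernel^2
      params[[paste0(ly$id, ".W")]] <-
        .initMatrix(ly$cin * kk, ly$cout, ly$cin * kk,
                    relu = identical(ly$act, "relu"))
      params[[paste0(ly$id, ".b")]] <- numeric(ly$cout)
    } else if (ly$type %in% c("dense", "densetime")) {
      params[[paste0(ly$id, ".W")]] <-
        .initMatrix(ly$din, ly$dout, ly$din,
                    relu = identical(ly$act, "relu"))
      params[[paste0(ly$id, ".b")]] <- numeric(ly$dout)
    } else if (ly$type == "lstm") {
      dirs <- if (ly$bidir) c("fwd", "bwd") else "fwd"
      for (d in dirs) {
        U <- ly$units
        b <- numeric(4 * U)
        b[(U + 1):(2 * U)] <- 1          # forget-gate bias
        params[[paste0(ly$id, ".", d, ".Wx")]] <-
          .initMatrix(ly$fin, 4 * U, ly$fin)
        params[[paste0(ly$id, ".", d, ".Wh")]] <- .initMatrix(U, 4 * U, U)
        params[[paste0(ly$id, ".", d, ".b")]] <- b
      }
    }
  }
  params
}

#' Build a full model
#'
#' Assembles encoder, (for DCAE variants) decoder, and classification
#' head, and initialises all weights with a seeded uniform fan-in scheme.
#'
#' @param config a [ModelConfig-class].
#' @param inputShape `c(n_channels, segment_samples)`.
#' @return A [SeizureModel-class]. DCAE variants expose two outputs
#'   (class probabilities and reconstruction); the DCNN baseline one.
#' @export
buildModel <- function(config, inputShape) {
  validObject(config)
  inputShape <- as.integer(inputShape)
  enc <- buildEncoder(config, inputShape)
  dec <- if (config@baseline) list(layers = list())
         else buildDecoder(config, enc)
  head <- buildHead(config, enc$bottleneck)
  params <- withSeed(config@seed, {
    c(.initLayerParams(enc$layers, config@kernel),
      .initLayerParams(dec$layers, config@kernel),
      .initLayerParams(head$layers, config@kernel))
  })
  new("SeizureModel", config = config, inputShape = inputShape,
      encoder = enc, decoder = dec, head = head, params = params,
      nOutputs = if (config@baseline) 1L else 2L)
}

#' Number of trainable parameters
#'
#' @param model a [SeizureModel-class].
#' @return Integer count over all weight arrays.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

#' Serialize the architecture to a JSON manifest
#'
#' Writes the configuration and the layer list (types, ids, shapes) —
#' not the weights — to a JSON file.
#'
#' @param model a [SeizureModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModelManifest <- function(model, path) {
  cfg <- model@config
  manifest <- list(
    model = if (cfg@baseline) "dcnn" else "dcae",
    head = cfg@head,
    inputShape = model@inputShape,
    bottleneck = model@encoder$bottleneck,
    nOutputs = model@nOutputs,
    parameterCount = parameterCount(model),
    config = list(encoderFilters = cfg@encoderFilters,
                  decoderFilters = cfg@decoderFilters,
                  kernel = cfg@kernel, pool = cfg@pool,
                  bilstmUnits = cfg@bilstmUnits,
                  denseUnits = cfg@denseUnits,
                  dropoutRate = cfg@dropoutRate, nClasses = cfg@nClasses,
                  avgPoolPosition = cfg@avgPoolPosition, seed = cfg@seed),
    layers = lapply(c(model@encoder$layers, model@decoder$layers,
                      model@head$layers),
                    function(ly) ly[setdiff(names(ly), character(0))]))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.configFingerprint <- function(config, trainCfg = NULL) {
  s <- paste(c(config@encoderFilters, config@decoderFilters, config@kernel,
               config@pool, config@head, config@bilstmUnits,
               config@denseUnits, config@dropoutRate, config@nClasses,
               config@baseline, config@avgPoolPosition),
             collapse = "|")
  if (!is.null(trainCfg))
    s <- paste(s, trainCfg@optimizer, trainCfg@learningRate,
               trainCfg@batchSize, trainCfg@epochs, trainCfg@lambda,
               sep = "|")
  fnv1a(s)
}
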