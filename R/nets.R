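# Network construction and training.
#
# Two families are provided. The AlexNet family (classifier with a softmax
# head, regressor with a single scalar output and Euclidean loss) follows
# the original five-convolution design with 2 filter groups in conv2/4/5
# and LRN after conv1/conv2. The FCN family is a VGG-16 backbone (stacked
# 3x3 convolution blocks of 2/2/3/3/3) whose fully connected layers become
# convolutions (fc6 as a 7x7 convolution to 4096 channels, fc7 1x1), with a
# 1x1 scoring layer, a 2x upsampling deconvolution, a pool4 skip fusion
# (score_pool4 -> centre crop -> element-wise sum) and a final 16x
# upsampling deconvolution back to input resolution. Deconvolutions are
# full (not per-class grouped) and bias-free.
#
# widthScale scales every channel count as ceiling(widthScale * c), rounded
# up to a multiple of the layer's group count; widthScale = 1 reproduces
# the reference shapes exactly.

convOutDim <- function(n, k, s = 1L, p = 0L) (n + 2L * p - k) %/% s + 1L
poolOutDim <- function(n, k, s) {
  out <- as.integer(ceiling((n - k) / s)) + 1L
  if ((out - 1L) * s >= n) out <- out - 1L
  out
}

scaleChannels <- function(c, ws, groups = 1L) {
  v <- ceiling(c * ws)
  as.integer(ceiling(v / groups) * groups)
}

# layer-descriptor helper
.ly <- function(name, type, bottom, ...) {
  c(list(name = name, type = type, bottom = bottom), list(...))
}

alexnetLayers <- function(spec) {
  ws <- spec@widthScale
  s <- function(c, g = 1L) scaleChannels(c, ws, g)
  fc8out <- if (spec@family == "alexnet_regressor") 1L else spec@numClasses
  list(
    .ly("conv1", "conv", "data", kernel = 11L, stride = 4L, pad = 0L,
        groups = 1L, out_channels = s(96)),
    .ly("relu1", "relu", "conv1"),
    .ly("norm1", "lrn", "relu1", lrn_size = 5L, lrn_alpha = 1e-4,
        lrn_beta = 0.75),
    .ly("pool1", "pool", "norm1", kernel = 3L, stride = 2L),
    .ly("conv2", "conv", "pool1", kernel = 5L, stride = 1L, pad = 2L,
        groups = 2L, out_channels = s(256, 2L)),
    .ly("relu2", "relu", "conv2"),
    .ly("norm2", "lrn", "relu2", lrn_size = 5L, lrn_alpha = 1e-4,
        lrn_beta = 0.75),
    .ly("pool2", "pool", "norm2", kernel = 3L, stride = 2L),
    .ly("conv3", "conv", "pool2", kernel = 3L, stride = 1L, pad = 1L,
        groups = 1L, out_channels = s(384)),
    .ly("relu3", "relu", "conv3"),
    .ly("conv4", "conv", "relu3", kernel = 3L, stride = 1L, pad = 1L,
        groups = 2L, out_channels = s(384, 2L)),
    .ly("relu4", "relu", "conv4"),
    .ly("conv5", "conv", "relu4", kernel = 3L, stride = 1L, pad = 1L,
        groups = 2L, out_channels = s(256, 2L)),
    .ly("relu5", "relu", "conv5"),
    .ly("pool5", "pool", "relu5", kernel = 3L, stride = 2L),
    .ly("fc6", "fc", "pool5", out_features = s(4096)),
    .ly("relu6", "relu", "fc6"),
    .ly("drop6", "dropout", "relu6", rate = 0.5),
    .ly("fc7", "fc", "drop6", out_features = s(4096)),
    .ly("relu7", "relu", "fc7"),
    .ly("drop7", "dropout", "relu7", rate = 0.5),
    .ly("fc8", "fc", "drop7", out_features = fc8out))
}

fcnLayers <- function(spec) {
  ws <- spec@widthScale
  s <- function(c) scaleChannels(c, ws)
  nc <- spec@numClasses
  blocks <- list(c(2L, 64L), c(2L, 128L), c(3L, 256L), c(3L, 512L),
                 c(3L, 512L))
  layers <- list()
  bottom <- "data"
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[[b]][1])) {
      nm <- sprintf("conv%d_%d", b, i)
      layers[[length(layers) + 1]] <-
        .ly(nm, "conv", bottom, kernel = 3L, stride = 1L, pad = 1L,
            groups = 1L, out_channels = s(blocks[[b]][2]))
      layers[[length(layers) + 1]] <-
        .ly(sprintf("relu%d_%d", b, i), "relu", nm)
      bottom <- sprintf("relu%d_%d", b, i)
    }
    layers[[length(layers) + 1]] <-
      .ly(sprintf("pool%d", b), "pool", bottom, kernel = 2L, stride = 2L)
    bottom <- sprintf("pool%d", b)
  }
  c(layers, list(
    .ly("fc6", "conv", "pool5", kernel = 7L, stride = 1L, pad = 0L,
        groups = 1L, out_channels = s(4096)),
    .ly("relu6", "relu", "fc6"),
    .ly("drop6", "dropout", "relu6", rate = 0.5),
    .ly("fc7", "conv", "drop6", kernel = 1L, stride = 1L, pad = 0L,
        groups = 1L, out_channels = s(4096)),
    .ly("relu7", "relu", "fc7"),
    .ly("drop7", "dropout", "relu7", rate = 0.5),
    .ly("score", "conv", "drop7", kernel = 1L, stride = 1L, pad = 0L,
        groups = 1L, out_channels = nc),
    .ly("score2", "deconv", "score", kernel = 4L, stride = 2L,
        out_channels = nc, bias = FALSE),
    .ly("score_pool4", "conv", "pool4", kernel = 1L, stride = 1L, pad = 0L,
        groups = 1L, out_channels = nc),
    .ly("score_pool4c", "crop", "score_pool4", bottom2 = "score2"),
    .ly("score_fuse", "eltwise", "score2", bottom2 = "score_pool4c"),
    .ly("bigscore", "deconv", "score_fuse", kernel = 32L, stride = 16L,
        out_channels = nc, bias = FALSE),
    .ly("upscore", "fit", "bigscore", target_h = spec@inputSize,
        target_w = spec@inputSize)))
}

# walk the layer graph and infer every output shape and parameter count
inferShapes <- function(layers, spec) {
  dims <- list(data = c(spec@inputSize, spec@inputSize,
                        spec@inputChannels))
  rows <- data.frame(name = "data", type = "data",
                     outC = spec@inputChannels, outH = spec@inputSize,
                     outW = spec@inputSize, params = 0,
                     stringsAsFactors = FALSE)
  for (L in layers) {
    din <- dims[[L$bottom]]
    if (is.null(din)) stop("layer '", L$name, "': unknown bottom")
    p <- 0
    if (L$type == "conv") {
      h <- convOutDim(din[1], L$kernel, L$stride, L$pad)
      w <- convOutDim(din[2], L$kernel, L$stride, L$pad)
      d <- c(h, w, L$out_channels)
      bias <- is.null(L$bias) || isTRUE(L$bias)
      p <- L$kernel^2 * (din[3] / L$groups) * L$out_channels +
        if (bias) L$out_channels else 0
    } else if (L$type == "deconv") {
      d <- c((din[1] - 1) * L$stride + L$kernel,
             (din[2] - 1) * L$stride + L$kernel, L$out_channels)
      p <- L$kernel^2 * L$out_channels * din[3]   # bias-free
    } else if (L$type == "pool") {
      d <- c(poolOutDim(din[1], L$kernel, L$stride),
             poolOutDim(din[2], L$kernel, L$stride), din[3])
    } else if (L$type == "fc") {
      p <- prod(din) * L$out_features + L$out_features
      d <- c(1, 1, L$out_features)
    } else if (L$type == "crop") {
      ref <- dims[[L$bottom2]]
      d <- c(ref[1], ref[2], din[3])
    } else if (L$type == "fit") {
      d <- c(L$target_h, L$target_w, din[3])
    } else if (L$type %in% c("relu", "lrn", "dropout", "eltwise")) {
      d <- din
    } else stop("unknown layer type '", L$type, "'")
    dims[[L$name]] <- d
    rows <- rbind(rows, data.frame(name = L$name, type = L$type,
                                   outC = d[3], outH = d[1], outW = d[2],
                                   params = p, stringsAsFactors = FALSE))
  }
  rows
}

#' Build a network from its specification
#'
#' Constructs the layer graph and the per-layer shape/parameter table for a
#' \linkS4class{NetSpec}. Weights are not materialised (see
#' \code{\link{initializeWeights}}), so even the full-scale architectures
#' can be built and verified instantly.
#'
#' @param spec a \linkS4class{NetSpec}.
#' @return A \linkS4class{PadNetwork}.
#' @examples
#' net <- buildNetwork(NetSpec("fcn"))
#' subset(layerShapes(net), name %in% c("conv1_2", "score_fuse", "upscore"))
#' countParameters(net) / 1e6
#' @export
buildNetwork <- function(spec) {
  validObject(spec)
  layers <- if (spec@family == "fcn") fcnLayers(spec) else
    alexnetLayers(spec)
  shapes <- inferShapes(layers, spec)
  if (any(shapes$outC <= 0) || any(shapes$outH <= 0) || any(shapes$outW <= 0))
    stop("degenerate layer shape: input ", spec@inputSize,
         " is too small for this architecture (or widthScale yields zero ",
         "channels)")
  new("PadNetwork", spec = spec, layers = layers, shapes = shapes,
      weights = list())
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "PadNetwork",
          function(object) sum(object@shapes$params))
#' @rdname countParameters
#' @export
setMethod("countParameters", "TrainedModel",
          function(object) sum(object@network@shapes$params))

# FCN-style bilinear interpolation kernel, k x k
bilinearKernel <- function(k) {
  f <- ceiling(k / 2)
  c0 <- (2 * f - 1 - f %% 2) / (2 * f)
  w <- 1 - abs((seq_len(k) - 1) / f - c0)
  outer(w, w)
}

#' Initialise network weights
#'
#' Convolution and inner-product weights are drawn from fan-in-scaled
#' Gaussians (no pretrained weights are used anywhere); scoring layers
#' (\code{score}, \code{score_pool4}) start at zero and deconvolutions start
#' as fixed bilinear interpolation kernels, the usual initialisation for
#' upsampling heads; all biases start at zero.
#'
#' When \code{calibrationInputs} are supplied, each Gaussian layer is
#' additionally rescaled so that its output activations have unit standard
#' deviation on that sample (layer-sequential unit-variance calibration).
#' At the very narrow widths used for desk-scale training the random
#' per-layer gain otherwise varies so much that deep activations can
#' collapse to zero before training starts.
#'
#' @param network a \linkS4class{PadNetwork}.
#' @param seed integer seed.
#' @param calibrationInputs optional small list of input arrays used to
#'   calibrate per-layer activation scales.
#' @return the network with weights materialised.
#' @export
initializeWeights <- function(network, seed = 1L,
                              calibrationInputs = NULL) {
  shp <- network@shapes
  dims <- setNames(lapply(seq_len(nrow(shp)), function(i)
    c(shp$outH[i], shp$outW[i], shp$outC[i])), shp$name)
  withSeed(seed, {
    w <- list()
    for (L in network@layers) {
      din <- dims[[L$bottom]]
      if (L$type == "conv") {
        k <- L$kernel; cpg <- din[3] / L$groups; out <- L$out_channels
        if (L$name %in% c("score", "score_pool4")) {
          W <- array(0, c(k, k, cpg, out))
        } else {
          W <- array(rnorm(k * k * cpg * out, 0, sqrt(2 / (k * k * cpg))),
                     c(k, k, cpg, out))
        }
        w[[L$name]] <- list(W = W, b = numeric(out))
      } else if (L$type == "deconv") {
        k <- L$kernel; out <- L$out_channels; cin <- din[3]
        W <- array(0, c(k, k, out, cin))
        bk <- bilinearKernel(k)
        for (ci in seq_len(min(out, cin))) W[, , ci, ci] <- bk
        w[[L$name]] <- list(W = W)
      } else if (L$type == "fc") {
        nin <- prod(din); out <- L$out_features
        sd <- if (L$name == "fc8") 0.01 else sqrt(2 / nin)
        w[[L$name]] <- list(W = array(rnorm(nin * out, 0, sd),
                                      c(nin, out)),
                            b = numeric(out))
      }
    }
    network@weights <- w
  })
  if (!is.null(calibrationInputs))
    network <- calibrateInitScales(network, calibrationInputs)
  network
}

# layer-sequential unit-variance rescaling of Gaussian-initialised layers;
# output heads (the last parameterised layer, zero-init score layers) keep
# their small Gaussian init -- a scalar head's sample sd is near zero and
# rescaling it would blow up its gain
calibrateInitScales <- function(network, inputs, target = 1, passes = 2) {
  weighted <- vapply(network@layers, function(L)
    L$type %in% c("conv", "deconv", "fc"), logical(1))
  lastWeighted <- network@layers[[max(which(weighted))]]$name
  skip <- c("score", "score_pool4", lastWeighted)
  for (pass in seq_len(passes)) {
    for (L in network@layers) {
      if (!(L$type %in% c("conv", "fc")) || L$name %in% skip) next
      acts <- .cnn_forward(network@layers, network@weights, inputs,
                          L$name, length(inputs))
      s <- stats::sd(unlist(acts))
      if (is.finite(s) && s > 1e-8)
        network@weights[[L$name]]$W <- network@weights[[L$name]]$W *
          (target / s)
    }
  }
  network
}

.lossName <- c(softmax_cross_entropy = "softmax", euclidean = "euclidean",
               pixel_softmax = "pixel_softmax")

checkLabels <- function(loss, y, numClasses) {
  if (loss == "softmax_cross_entropy") {
    if (!is.numeric(y) || any(y != round(y)) || any(y < 0) ||
        any(y >= numClasses))
      stop("softmax loss needs integer class labels in [0, numClasses)")
  } else if (loss == "euclidean") {
    if (!is.numeric(y)) stop("euclidean loss needs numeric targets")
  } else {
    if (!is.list(y) || !all(vapply(y, is.matrix, logical(1))))
      stop("pixelwise loss needs a list of label matrices")
  }
}

#' Train a network
#'
#' Momentum SGD with a step-down learning-rate schedule. Training is
#' deterministic under the configuration seed (which controls weight
#' initialisation, shuffling and dropout) on single-threaded execution.
#'
#' @param network a \linkS4class{PadNetwork} (initialised or not).
#' @param x list of input arrays (\code{H x W x C}), all the same size.
#' @param y labels matching the configured loss: 0-based integer classes for
#'   \code{softmax_cross_entropy}, numeric targets for \code{euclidean}, or
#'   a list of \code{H x W} integer class matrices for \code{pixel_softmax}.
#' @param config a \linkS4class{TrainConfig}.
#' @param xTest,yTest optional held-out data evaluated after every epoch.
#' @param holdout \code{"none"} or \code{"fraction"}: with
#'   \code{"fraction"} a \code{testFraction} share of \code{x} is split off
#'   (seeded) and used as the held-out set.
#' @param selectBest when \code{TRUE} (and held-out data are present) the
#'   returned model carries the weights of the epoch with the lowest
#'   held-out loss instead of the final epoch (early stopping by model
#'   selection).
#' @param evalEvery evaluate the held-out set every this many epochs (the
#'   final epoch is always evaluated; ignored when \code{selectBest}).
#' @return A \linkS4class{TrainedModel}.
#' @export
trainNetwork <- function(network, x, y, config, xTest = NULL, yTest = NULL,
                         holdout = c("none", "fraction"),
                         selectBest = FALSE, evalEvery = 1L) {
  holdout <- match.arg(holdout)
  validObject(config)
  if (length(x) == 0) stop("empty dataset")
  checkLabels(config@loss, y, network@spec@numClasses)
  if (config@loss == "euclidean" &&
      network@spec@family != "alexnet_regressor")
    stop("label/loss mismatch: euclidean loss needs a regressor network")
  if (config@loss == "softmax_cross_entropy" &&
      network@spec@family == "alexnet_regressor")
    stop("label/loss mismatch: the regressor has a scalar output")
  if (holdout == "fraction") {
    idx <- withSeed(config@seed,
                    sample(length(x), round(config@testFraction * length(x))))
    xTest <- x[idx]
    yTest <- if (is.list(y)) y[idx] else y[idx]
    x <- x[-idx]
    y <- if (is.list(y)) y[-idx] else y[-idx]
  }
  if (length(network@weights) == 0)
    network <- initializeWeights(network, config@seed,
                                 calibrationInputs = x[seq_len(min(4,
                                                                   length(x)))])
  cfg <- list(epochs = config@epochs, lr = config@learningRate,
              momentum = config@momentum, gamma = config@gamma,
              step_size = config@stepSize, batch_size = config@batchSize,
              weight_decay = config@weightDecay,
              loss = unname(.lossName[config@loss]),
              select_best = isTRUE(selectBest),
              eval_every = as.integer(evalEvery),
              class_weights = if (length(config@classWeights))
                config@classWeights else NULL)
  yEng <- if (config@loss == "softmax_cross_entropy") as.integer(y) else y
  yTestEng <- if (is.null(yTest)) integer(0) else
    if (config@loss == "softmax_cross_entropy") as.integer(yTest) else yTest
  res <- withSeed(config@seed + 1L,
                  .cnn_train(network@layers, network@weights, x, yEng,
                             if (is.null(xTest)) list() else xTest,
                             yTestEng, cfg))
  network@weights <- res$weights
  new("TrainedModel", network = network, config = config,
      curves = res$curves, seed = config@seed)
}

# ---- inference ------------------------------------------------------------

.counters <- new.env(parent = emptyenv())

#' Forward-pass instrumentation
#'
#' Every call to \code{\link{forwardNetwork}} increments a per-family
#' counter by the number of network inferences performed (one per input
#' image). Used to verify the single-inference contract of the regression
#' pipeline.
#'
#' @return named numeric vector of inference counts per network family.
#' @export
inferenceCounts <- function() {
  v <- as.list(.counters)
  if (!length(v)) return(setNames(numeric(0), character(0)))
  unlist(v)
}

#' @rdname inferenceCounts
#' @export
resetInferenceCounts <- function() {
  rm(list = ls(.counters), envir = .counters)
  invisible(NULL)
}

bumpCounter <- function(family, n) {
  cur <- if (exists(family, envir = .counters)) get(family, .counters) else 0
  assign(family, cur + n, envir = .counters)
}

#' Run a network forward
#'
#' @param model a \linkS4class{TrainedModel} (or initialised
#'   \linkS4class{PadNetwork}).
#' @param x one input array or a list of input arrays.
#' @param upto name of the layer whose activation to return (default: the
#'   network's top layer).
#' @param batchSize internal batch size.
#' @return for a single input, the activation array (\code{H x W x C});
#'   for a list, a list of such arrays.
#' @export
forwardNetwork <- function(model, x, upto = "", batchSize = 16L) {
  net <- if (is(model, "TrainedModel")) model@network else model
  if (length(net@weights) == 0) stop("network has no weights")
  single <- !is.list(x)
  xs <- if (single) list(x) else x
  out <- .cnn_forward(net@layers, net@weights, xs, upto, batchSize)
  bumpCounter(net@spec@family, length(xs))
  if (single) out[[1]] else out
}

# softmax over the last dimension of a 1x1xC activation
softmaxVec <- function(z) {
  z <- as.numeric(z); e <- exp(z - max(z)); e / sum(e)
}

#' Classify image patches
#'
#' Resizes patches to the classifier's input size and returns class
#' probabilities (softmax of the final layer).
#'
#' @param model trained patch classifier.
#' @param patchList list of \code{H x W x 3} arrays.
#' @param batchSize internal batch size.
#' @return numeric matrix \code{n x numClasses}; column 2 is the mosquito
#'   probability under the package's 0 = non-mosquito, 1 = mosquito coding.
#' @export
classifyPatches <- function(model, patchList, batchSize = 64L) {
  if (!length(patchList))
    return(matrix(numeric(0), 0, model@network@spec@numClasses))
  sz <- model@network@spec@inputSize
  xs <- lapply(patchList, function(p)
    if (dim(p)[1] == sz && dim(p)[2] == sz) p else resizeArray(p, sz, sz))
  logits <- forwardNetwork(model, xs, batchSize = batchSize)
  t(vapply(logits, softmaxVec, numeric(model@network@spec@numClasses)))
}
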