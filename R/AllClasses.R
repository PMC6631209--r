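# S4 classes for scenes, detections, networks and evaluation results.

#' Synthetic scene specification
#'
#' Describes one synthetic observation-pad scene: pad size, number of
#' mosquito sprites and non-mosquito distractors, illumination and noise
#' parameters, sprite size range and the seed that makes generation
#' bit-reproducible.
#'
#' @slot width,height image size in pixels.
#' @slot nMosquitoes,nDistractors number of mosquito sprites and of dark
#'   non-mosquito distractors (round specks, blotches, elongated smudges).
#' @slot backgroundLevel nominal pad gray value on the 0--255 scale
#'   (pads are near-white; allowed range 200--255).
#' @slot illuminationGradient fractional amplitude in [0, 0.15] of a linear
#'   illumination ramp across the pad.
#' @slot noiseSigma per-channel Gaussian sensor noise, gray-value std.
#' @slot spriteSizeRange numeric length 2; admissible range in pixels of a
#'   sprite's longest bounding-box axis.
#' @slot minContrast minimum gray-value difference between the local
#'   (noise-free) background and every mask-positive sprite pixel.
#' @slot placementMargin extra margin in pixels kept between a sprite's
#'   bounding box and the image border.
#' @slot seed integer seed; identical specs regenerate identical scenes.
#' @name SceneSpec-class
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  width = "integer", height = "integer",
  nMosquitoes = "integer", nDistractors = "integer",
  backgroundLevel = "numeric", illuminationGradient = "numeric",
  noiseSigma = "numeric", spriteSizeRange = "numeric",
  minContrast = "numeric", placementMargin = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- NULL
  if (object@width < 32 || object@height < 32)
    msg <- c(msg, "width/height must be at least 32 pixels")
  if (object@nMosquitoes < 0 || object@nDistractors < 0)
    msg <- c(msg, "sprite counts must be non-negative")
  if (object@backgroundLevel < 200 || object@backgroundLevel > 255)
    msg <- c(msg, "backgroundLevel must lie in [200, 255]")
  if (object@illuminationGradient < 0 || object@illuminationGradient > 0.15)
    msg <- c(msg, "illuminationGradient must lie in [0, 0.15]")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(object@spriteSizeRange) != 2 ||
      object@spriteSizeRange[1] > object@spriteSizeRange[2] ||
      object@spriteSizeRange[1] < 5)
    msg <- c(msg, "spriteSizeRange must be [min, max] with min >= 5")
  if (object@minContrast <= 0) msg <- c(msg, "minContrast must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Create a scene specification
#'
#' @param width,height image size in pixels.
#' @param nMosquitoes,nDistractors sprite counts.
#' @param backgroundLevel pad gray value (0--255 scale, in [200, 255]).
#' @param illuminationGradient fractional ramp amplitude in [0, 0.15].
#' @param noiseSigma Gaussian noise std in gray values.
#' @param spriteSizeRange range in pixels of a sprite's longest axis.
#' @param minContrast minimum background-minus-sprite gray difference.
#' @param placementMargin border margin in pixels.
#' @param seed integer seed.
#' @return A \linkS4class{SceneSpec}.
#' @examples
#' SceneSpec(nMosquitoes = 3, seed = 7)
#' @export
SceneSpec <- function(width = 500L, height = 500L, nMosquitoes = 0L,
                      nDistractors = 0L, backgroundLevel = 235,
                      illuminationGradient = 0.06, noiseSigma = 6,
                      spriteSizeRange = c(28, 42), minContrast = 70,
                      placementMargin = 66, seed = 1L) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      nMosquitoes = as.integer(nMosquitoes),
      nDistractors = as.integer(nDistractors),
      backgroundLevel = backgroundLevel,
      illuminationGradient = illuminationGradient, noiseSigma = noiseSigma,
      spriteSizeRange = spriteSizeRange, minContrast = minContrast,
      placementMargin = placementMargin, seed = as.integer(seed))
}

#' Synthetic observation-pad scene with ground truth
#'
#' @slot image numeric array \code{c(height, width, 3)}, values in [0, 1].
#' @slot count true number of mosquitoes.
#' @slot boxes integer matrix \code{count x 4} of half-open 0-based boxes,
#'   columns \code{x0, y0, x1, y1} (x = column axis).
#' @slot mask integer matrix \code{height x width}, 1 on mosquito pixels.
#'   Distractors are never mask-positive.
#' @slot spec the \linkS4class{SceneSpec} the scene was generated from.
#' @name PadScene-class
#' @exportClass PadScene
setClass("PadScene", representation(
  image = "array", count = "integer", boxes = "matrix", mask = "matrix",
  spec = "SceneSpec"))

setValidity("PadScene", function(object) {
  msg <- NULL
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) msg <- c(msg, "image must be H x W x 3")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask must match image size")
  if (nrow(object@boxes) != object@count)
    msg <- c(msg, "count must equal the number of boxes")
  if (!all(object@mask %in% c(0L, 1L))) msg <- c(msg, "mask must be 0/1")
  if (is.null(msg)) TRUE else msg
})

#' Candidate detection parameters
#'
#' Parameters of the classical dark-object detector: threshold choice, the
#' admissible contour area window, and an optional morphological opening.
#'
#' @slot thresholdMode \code{"otsu"} (automatic) or \code{"fixed"}.
#' @slot fixedThreshold gray value in [0, 255] used when mode is
#'   \code{"fixed"}.
#' @slot areaMin,areaMax admissible connected-component area in pixels^2.
#' @slot morphOpenRadius radius in pixels of the opening brush; 0 disables.
#' @name DetectParams-class
#' @exportClass DetectParams
setClass("DetectParams", representation(
  thresholdMode = "character", fixedThreshold = "numeric",
  areaMin = "numeric", areaMax = "numeric", morphOpenRadius = "numeric"))

setValidity("DetectParams", function(object) {
  msg <- NULL
  if (!object@thresholdMode %in% c("otsu", "fixed"))
    msg <- c(msg, "thresholdMode must be 'otsu' or 'fixed'")
  if (object@thresholdMode == "fixed" &&
      (object@fixedThreshold < 0 || object@fixedThreshold > 255))
    msg <- c(msg, "fixedThreshold must lie in [0, 255]")
  if (object@areaMin >= object@areaMax)
    msg <- c(msg, "areaMin must be smaller than areaMax")
  if (object@morphOpenRadius < 0)
    msg <- c(msg, "morphOpenRadius must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Create detection parameters
#'
#' @param thresholdMode \code{"otsu"} or \code{"fixed"}.
#' @param fixedThreshold gray value in [0, 255] (used in fixed mode).
#' @param areaMin,areaMax admissible component area in pixels^2.
#' @param morphOpenRadius opening brush radius in pixels (0 disables).
#' @return A \linkS4class{DetectParams}.
#' @seealso \code{\link{defaultDetectParams}} to derive the area window from
#'   a scene specification's sprite size range.
#' @export
DetectParams <- function(thresholdMode = "otsu", fixedThreshold = 128,
                         areaMin = 40, areaMax = 2000,
                         morphOpenRadius = 0) {
  new("DetectParams", thresholdMode = thresholdMode,
      fixedThreshold = fixedThreshold, areaMin = areaMin, areaMax = areaMax,
      morphOpenRadius = morphOpenRadius)
}

#' Set of candidate detections in one image
#'
#' One row per size-filtered connected foreground component, sorted by
#' centroid (row, then column) for determinism.
#'
#' @slot boxes integer matrix \code{n x 4}, half-open 0-based \code{x0, y0,
#'   x1, y1}.
#' @slot centroids numeric matrix \code{n x 2} (row, col), 0-based.
#' @slot areas numeric vector of component areas in pixels^2.
#' @slot patches list of \code{60 x 60 x 3} arrays (possibly empty when only
#'   boxes were requested).
#' @slot params the \linkS4class{DetectParams} used.
#' @name DetectionSet-class
#' @exportClass DetectionSet
setClass("DetectionSet", representation(
  boxes = "matrix", centroids = "matrix", areas = "numeric",
  patches = "list", params = "DetectParams"))

#' Network architecture specification
#'
#' @slot family \code{"alexnet_classifier"}, \code{"alexnet_regressor"} or
#'   \code{"fcn"}.
#' @slot widthScale channel-width multiplier in (0, 1]; 1 reproduces the
#'   reference layer shapes exactly. Scaled channel counts are
#'   \code{ceiling(widthScale * c)}, rounded up to a multiple of the layer's
#'   filter-group count.
#' @slot numClasses classifier class count (2 for mosquito/non-mosquito,
#'   1000 for the original reference head), FCN score channels (21 in the
#'   reference head), or ignored for the regressor (scalar output).
#' @slot inputSize input raster side in pixels (227 reference for the
#'   AlexNet families, 500 for the FCN).
#' @slot inputChannels input channel count (3 for RGB; the channel-stack
#'   regression mode feeds all score channels instead).
#' @name NetSpec-class
#' @exportClass NetSpec
setClass("NetSpec", representation(
  family = "character", widthScale = "numeric", numClasses = "integer",
  inputSize = "integer", inputChannels = "integer"))

setValidity("NetSpec", function(object) {
  msg <- NULL
  if (!object@family %in% c("alexnet_classifier", "alexnet_regressor", "fcn"))
    msg <- c(msg, "unknown family")
  if (object@widthScale <= 0 || object@widthScale > 1)
    msg <- c(msg, "widthScale must lie in (0, 1]")
  if (object@numClasses < 1) msg <- c(msg, "numClasses must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Create a network specification
#'
#' @param family one of \code{"alexnet_classifier"},
#'   \code{"alexnet_regressor"}, \code{"fcn"}.
#' @param widthScale channel-width multiplier in (0, 1].
#' @param numClasses number of classes (see \linkS4class{NetSpec}).
#' @param inputSize input side length in pixels.
#' @param inputChannels input channels (default 3).
#' @return A \linkS4class{NetSpec}.
#' @examples
#' NetSpec("fcn")                       # full-scale reference FCN
#' NetSpec("alexnet_classifier", widthScale = 0.125, numClasses = 2,
#'         inputSize = 75)              # desk-scale patch classifier
#' @export
NetSpec <- function(family = c("alexnet_classifier", "alexnet_regressor",
                               "fcn"),
                    widthScale = 1,
                    numClasses = if (family == "fcn") 21L else 1000L,
                    inputSize = if (family == "fcn") 500L else 227L,
                    inputChannels = 3L) {
  family <- match.arg(family)
  new("NetSpec", family = family, widthScale = widthScale,
      numClasses = as.integer(numClasses), inputSize = as.integer(inputSize),
      inputChannels = as.integer(inputChannels))
}

#' A network: layer graph, shape table and (optionally) weights
#'
#' Built by \code{\link{buildNetwork}}. Weights are materialised lazily by
#' \code{\link{initializeWeights}} (or by training); the shape table alone
#' suffices for layer-shape assertions and parameter counting.
#'
#' @slot spec the \linkS4class{NetSpec}.
#' @slot layers list of layer descriptors consumed by the compiled engine.
#' @slot shapes data.frame with one row per layer: \code{name, type, outC,
#'   outH, outW, params}.
#' @slot weights named list (\code{list(W = array, b = vector)} per
#'   parameterised layer); empty until initialised.
#' @name PadNetwork-class
#' @exportClass PadNetwork
setClass("PadNetwork", representation(
  spec = "NetSpec", layers = "list", shapes = "data.frame",
  weights = "list"))

#' Training configuration
#'
#' Momentum SGD with a step-down learning-rate schedule (the rate is
#' multiplied by \code{gamma} every \code{stepSize} epochs).
#'
#' @slot learningRate initial learning rate (default 0.001).
#' @slot epochs training epochs (default 20).
#' @slot batchSize minibatch size.
#' @slot testFraction held-out fraction in (0, 1) when the caller asks for an
#'   internal split (default 0.25).
#' @slot stepSize epochs between learning-rate drops; \code{NA} means
#'   \code{ceiling(epochs / 2)}.
#' @slot gamma learning-rate decay factor (default 0.1).
#' @slot momentum SGD momentum (default 0.9).
#' @slot weightDecay L2 penalty on weights (not biases; default 5e-4).
#' @slot loss \code{"softmax_cross_entropy"}, \code{"euclidean"} or
#'   \code{"pixel_softmax"}.
#' @slot classWeights optional per-class loss weights for the pixelwise loss
#'   (length 0 = uniform).
#' @slot seed integer seed controlling initialisation, shuffling and dropout.
#' @name TrainConfig-class
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  learningRate = "numeric", epochs = "integer", batchSize = "integer",
  testFraction = "numeric", stepSize = "integer", gamma = "numeric",
  momentum = "numeric", weightDecay = "numeric", loss = "character",
  classWeights = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- NULL
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must lie strictly between 0 and 1")
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (!object@loss %in% c("softmax_cross_entropy", "euclidean",
                          "pixel_softmax"))
    msg <- c(msg, "unknown loss")
  if (is.null(msg)) TRUE else msg
})

#' Create a training configuration
#'
#' @param learningRate initial learning rate.
#' @param epochs number of epochs.
#' @param batchSize minibatch size.
#' @param testFraction held-out fraction for internal splits.
#' @param stepSize epochs between rate drops (\code{NA}: half the epochs).
#' @param gamma decay factor.
#' @param momentum SGD momentum.
#' @param weightDecay L2 penalty.
#' @param loss loss name (see \linkS4class{TrainConfig}).
#' @param classWeights per-class weights for the pixelwise loss.
#' @param seed integer seed.
#' @return A \linkS4class{TrainConfig}.
#' @export
TrainConfig <- function(learningRate = 0.001, epochs = 20L, batchSize = 32L,
                        testFraction = 0.25, stepSize = NA_integer_,
                        gamma = 0.1, momentum = 0.9, weightDecay = 5e-4,
                        loss = "softmax_cross_entropy",
                        classWeights = numeric(0), seed = 1L) {
  if (is.na(stepSize)) stepSize <- ceiling(epochs / 2)
  new("TrainConfig", learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), testFraction = testFraction,
      stepSize = as.integer(stepSize), gamma = gamma, momentum = momentum,
      weightDecay = weightDecay, loss = loss, classWeights = classWeights,
      seed = as.integer(seed))
}

#' A trained network with its learning curves
#'
#' @slot network the \linkS4class{PadNetwork} holding the final weights.
#' @slot config the \linkS4class{TrainConfig} used.
#' @slot curves data.frame with one row per epoch: \code{epoch, lr,
#'   train_loss, test_loss, test_metric} (accuracy for classification, pixel
#'   accuracy for the FCN, RMSE for regression).
#' @slot seed the seed training ran under.
#' @name TrainedModel-class
#' @exportClass TrainedModel
setClass("TrainedModel", representation(
  network = "PadNetwork", config = "TrainConfig", curves = "data.frame",
  seed = "integer"))

#' Pixel-label mask bootstrapped from the patch classifier
#'
#' Black background with accepted detection components painted purple
#' (255, 0, 255), plus the matching integer class-index raster
#' (background = 0, mosquito = 1).
#'
#' @slot raster numeric array \code{H x W x 3} containing exactly the two
#'   palette colors (0,0,0) and (1,0,1) on the [0, 1] scale.
#' @slot classIndex integer matrix \code{H x W} of class ids.
#' @name LabelMask-class
#' @exportClass LabelMask
setClass("LabelMask", representation(
  raster = "array", classIndex = "matrix"))

setValidity("LabelMask", function(object) {
  d <- dim(object@raster)
  if (length(d) != 3 || d[3] != 3) return("raster must be H x W x 3")
  if (!identical(dim(object@classIndex), d[1:2]))
    return("classIndex must match raster size")
  ok <- (object@raster[, , 1] == object@raster[, , 3]) &
    (object@raster[, , 2] == 0) & (object@raster[, , 1] %in% c(0, 1))
  if (!all(ok)) return("raster must contain only black and purple pixels")
  TRUE
})

#' Score map extracted before the final deconvolution
#'
#' @slot tensor numeric array \code{H' x W' x C} holding the activation of
#'   the skip-fused scoring layer (\code{score_fuse}), i.e. the input of the
#'   final upsampling.
#' @slot sourceLayer layer name the tensor was taken from.
#' @slot sceneRef free-form provenance string (e.g. a file path).
#' @name ScoreMap-class
#' @exportClass ScoreMap
setClass("ScoreMap", representation(
  tensor = "array", sourceLayer = "character", sceneRef = "character"))

#' A count estimate under the clamped 0--5 label scheme
#'
#' @slot raw real-valued regression output.
#' @slot count integer in [0, 5]: \code{min(5, max(0, round(raw)))} with
#'   round-half-away-from-zero.
#' @slot exceededTopBin \code{TRUE} when \code{raw > 5} before clamping
#'   (scored as correct on top-bin images).
#' @name CountEstimate-class
#' @exportClass CountEstimate
setClass("CountEstimate", representation(
  raw = "numeric", count = "integer", exceededTopBin = "logical"))

#' Evaluation report for a counting method
#'
#' @slot nImages number of evaluated images.
#' @slot accuracy clamped-count accuracy in [0, 1] (an output exceeding 5 on
#'   a top-bin image counts as correct).
#' @slot rmse root-mean-square error of the method's outputs against the
#'   labels (regression outputs are capped at 5 on top-bin images; the
#'   per-contour baseline uses its unclamped integer counts).
#' @slot perImage data.frame \code{true_label, predicted_count, raw}.
#' @slot method \code{"fcn_regression"} or \code{"contour_classifier"}.
#' @name EvalReport-class
#' @exportClass EvalReport
setClass("EvalReport", representation(
  nImages = "integer", accuracy = "numeric", rmse = "numeric",
  perImage = "data.frame", method = "character"))

setValidity("EvalReport", function(object) {
  msg <- NULL
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must lie in [0, 1]")
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (nrow(object@perImage) != object@nImages)
    msg <- c(msg, "perImage must have nImages rows")
  if (is.null(msg)) TRUE else msg
})

#' Time series of pad counts for the release trigger
#'
#' @slot timestamps strictly increasing numeric timestamps.
#' @slot counts non-negative integer counts, one per timestamp.
#' @slot window trailing window length (>= 2) the trigger rule inspects.
#' @name CountSeries-class
#' @exportClass CountSeries
setClass("CountSeries", representation(
  timestamps = "numeric", counts = "integer", window = "integer"))

setValidity("CountSeries", function(object) {
  msg <- NULL
  if (length(object@timestamps) != length(object@counts))
    msg <- c(msg, "timestamps and counts must have equal length")
  if (any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (object@window < 2) msg <- c(msg, "window must be >= 2")
  if (is.null(msg)) TRUE else msg
})

#' Create a count time series
#'
#' @param counts non-negative integer counts.
#' @param timestamps strictly increasing timestamps (default \code{1:n}).
#' @param window trailing window length inspected by the trigger rule.
#' @return A \linkS4class{CountSeries}.
#' @examples
#' CountSeries(c(3, 3, 4, 4))
#' @export
CountSeries <- function(counts, timestamps = seq_along(counts),
                        window = 4L) {
  new("CountSeries", timestamps = as.numeric(timestamps),
      counts = as.integer(counts), window = as.integer(window))
}

#' Trained counting pipeline (classifier, FCN and count regressor)
#'
#' Returned by \code{\link{trainCountingPipeline}}; consumed by
#' \code{\link{countByRegression}}, \code{\link{countByClassifier}} and
#' \code{\link{evaluatePipeline}}.
#'
#' @slot classifier patch classifier \linkS4class{TrainedModel}.
#' @slot fcn score-map network \linkS4class{TrainedModel}.
#' @slot regressor count regressor \linkS4class{TrainedModel}.
#' @slot detectParams \linkS4class{DetectParams} shared by labelling and the
#'   baseline.
#' @slot scoremapMode \code{"probability_image"} or \code{"channel_stack"}.
#' @slot seed pipeline-level seed.
#' @name CountingPipeline-class
#' @exportClass CountingPipeline
setClass("CountingPipeline", representation(
  classifier = "TrainedModel", fcn = "TrainedModel",
  regressor = "TrainedModel", detectParams = "DetectParams",
  scoremapMode = "character", seed = "integer"))
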