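# Generics and accessors.

#' @rdname PadScene-class
#' @param object,x a \linkS4class{PadScene} (or other object, see methods).
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))
#' @rdname PadScene-class
#' @export
setGeneric("sceneCount", function(object) standardGeneric("sceneCount"))
#' @rdname PadScene-class
#' @export
setGeneric("sceneBoxes", function(object) standardGeneric("sceneBoxes"))
#' @rdname PadScene-class
#' @export
setGeneric("sceneMask", function(object) standardGeneric("sceneMask"))
#' @rdname PadScene-class
#' @export
setGeneric("sceneSpec", function(object) standardGeneric("sceneSpec"))

#' @rdname PadScene-class
#' @export
setMethod("sceneImage", "PadScene", function(object) object@image)
#' @rdname PadScene-class
#' @export
setMethod("sceneCount", "PadScene", function(object) object@count)
#' @rdname PadScene-class
#' @export
setMethod("sceneBoxes", "PadScene", function(object) object@boxes)
#' @rdname PadScene-class
#' @export
setMethod("sceneMask", "PadScene", function(object) object@mask)
#' @rdname PadScene-class
#' @export
setMethod("sceneSpec", "PadScene", function(object) object@spec)

#' @rdname DetectionSet-class
#' @param object,x a \linkS4class{DetectionSet}.
#' @export
setGeneric("boxes", function(object) standardGeneric("boxes"))
#' @rdname DetectionSet-class
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname DetectionSet-class
#' @export
setGeneric("areas", function(object) standardGeneric("areas"))
#' @rdname DetectionSet-class
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))

#' @rdname DetectionSet-class
#' @export
setMethod("boxes", "DetectionSet", function(object) object@boxes)
#' @rdname DetectionSet-class
#' @export
setMethod("centroids", "DetectionSet", function(object) object@centroids)
#' @rdname DetectionSet-class
#' @export
setMethod("areas", "DetectionSet", function(object) object@areas)
#' @rdname DetectionSet-class
#' @export
setMethod("patches", "DetectionSet", function(object) object@patches)
#' @rdname DetectionSet-class
#' @export
setMethod("length", "DetectionSet", function(x) nrow(x@boxes))

#' Count trainable parameters
#'
#' Total number of trainable weights and biases of a network, computed from
#' the architecture's layer shapes (so it is available without materialising
#' any weight array).
#'
#' @param object a \linkS4class{PadNetwork} or \linkS4class{TrainedModel}.
#' @return numeric scalar.
#' @examples
#' countParameters(buildNetwork(NetSpec("fcn"))) / 1e6
#' @export
setGeneric("countParameters",
           function(object) standardGeneric("countParameters"))

#' @rdname PadNetwork-class
#' @param object,x a \linkS4class{PadNetwork}.
#' @export
setGeneric("networkSpec", function(object) standardGeneric("networkSpec"))
#' @rdname PadNetwork-class
#' @export
setGeneric("layerShapes", function(object) standardGeneric("layerShapes"))
#' @rdname TrainedModel-class
#' @param object a \linkS4class{TrainedModel}.
#' @export
setGeneric("trainingCurves",
           function(object) standardGeneric("trainingCurves"))

#' @rdname PadNetwork-class
#' @export
setMethod("networkSpec", "PadNetwork", function(object) object@spec)
#' @rdname PadNetwork-class
#' @export
setMethod("layerShapes", "PadNetwork", function(object) object@shapes)
#' @rdname TrainedModel-class
#' @export
setMethod("networkSpec", "TrainedModel",
          function(object) object@network@spec)
#' @rdname TrainedModel-class
#' @export
setMethod("layerShapes", "TrainedModel",
          function(object) object@network@shapes)
#' @rdname TrainedModel-class
#' @export
setMethod("trainingCurves", "TrainedModel", function(object) object@curves)

#' @rdname ScoreMap-class
#' @param object a \linkS4class{ScoreMap}.
#' @export
setGeneric("scoreTensor", function(object) standardGeneric("scoreTensor"))
#' @rdname ScoreMap-class
#' @export
setMethod("scoreTensor", "ScoreMap", function(object) object@tensor)

# ---- show methods ---------------------------------------------------------

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec %dx%d | %d mosquito(es), %d distractor(s) | bg %g, grad %g, noise %g | sprite %g-%g px | seed %d\n",
    object@width, object@height, object@nMosquitoes, object@nDistractors,
    object@backgroundLevel, object@illuminationGradient, object@noiseSigma,
    object@spriteSizeRange[1], object@spriteSizeRange[2], object@seed))
})

setMethod("show", "PadScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("PadScene %dx%d | true count %d | %d mosquito component(s) in mask\n",
              d[2], d[1], object@count, nrow(object@boxes)))
})

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet with %d candidate(s)", nrow(object@boxes)))
  if (nrow(object@boxes) > 0)
    cat(sprintf(" | areas %g-%g px^2", min(object@areas), max(object@areas)))
  cat(sprintf(" | %s patches\n",
              if (length(object@patches)) "with" else "without"))
})

setMethod("show", "NetSpec", function(object) {
  cat(sprintf("NetSpec %s | widthScale %g | %d class(es) | input %dx%dx%d\n",
              object@family, object@widthScale, object@numClasses,
              object@inputChannels, object@inputSize, object@inputSize))
})

setMethod("show", "PadNetwork", function(object) {
  cat(sprintf("PadNetwork %s (widthScale %g): %d layers, %.4g M parameters, %s\n",
              object@spec@family, object@spec@widthScale,
              nrow(object@shapes), countParameters(object) / 1e6,
              if (length(object@weights)) "initialised" else "uninitialised"))
})

setMethod("show", "TrainedModel", function(object) {
  n <- nrow(object@curves)
  cat(sprintf("TrainedModel %s | %d epoch(s) | final train loss %.4g",
              object@network@spec@family, n, object@curves$train_loss[n]))
  if (!is.na(object@curves$test_metric[n]))
    cat(sprintf(" | final test metric %.4g", object@curves$test_metric[n]))
  cat("\n")
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask %dx%d | %d mosquito pixel(s)\n",
              dim(object@raster)[2], dim(object@raster)[1],
              sum(object@classIndex == 1L)))
})

setMethod("show", "ScoreMap", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("ScoreMap %d x %d x %d from layer '%s'\n",
              d[3], d[1], d[2], object@sourceLayer))
})

setMethod("show", "CountEstimate", function(object) {
  cat(sprintf("CountEstimate: raw %.3f -> count %d%s\n", object@raw,
              object@count,
              if (object@exceededTopBin) " (exceeded top bin)" else ""))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: %d images | accuracy %.1f%% | RMSE %.3f\n",
              object@method, object@nImages, 100 * object@accuracy,
              object@rmse))
})

setMethod("show", "CountSeries", function(object) {
  cat(sprintf("CountSeries of length %d (window %d): %s\n",
              length(object@counts), object@window,
              paste(object@counts, collapse = " ")))
})

setMethod("show", "CountingPipeline", function(object) {
  cat(sprintf("CountingPipeline (seed %d): classifier %s, fcn %s, regressor %s | scoremap mode %s\n",
              object@seed, object@classifier@network@spec@family,
              object@fcn@network@spec@family,
              object@regressor@network@spec@family, object@scoremapMode))
})
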