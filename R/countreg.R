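# Count regression from the FCN score map taken before the final
# deconvolution (the skip-fused scoring layer): map extraction, conversion
# to regressor input, training with Euclidean loss on clamped 0-5 labels,
# and prediction with the clamp/flag semantics used for evaluation.

#' Clamp a raw regression output to the 0--5 label scheme
#'
#' @param raw real-valued network output.
#' @return A \linkS4class{CountEstimate}: \code{count = min(5, max(0,
#'   round(raw)))} (round half away from zero) and a flag recording whether
#'   \code{raw > 5} (scored as correct on top-bin images).
#' @examples
#' countEstimate(2.4)   # count 2
#' countEstimate(7.1)   # count 5, exceeded top bin
#' countEstimate(-0.3)  # count 0
#' @export
countEstimate <- function(raw) {
  new("CountEstimate", raw = as.numeric(raw),
      count = as.integer(min(5, max(0, roundHalfAway(raw)))),
      exceededTopBin = raw > 5)
}

#' Extract the score map before the final deconvolution
#'
#' Runs the FCN forward and returns the activation of the skip-fused
#' scoring layer (\code{score_fuse}), i.e. the input of the final 16x
#' upsampling. For the full-scale reference network on a 500x500 input this
#' is 21 x 22 x 22; for other input sizes and widths it follows the
#' architecture's arithmetic. The extraction is bit-stable for fixed
#' weights and input.
#'
#' @param fcn trained FCN (\linkS4class{TrainedModel}).
#' @param image input array matching the FCN input size.
#' @param sceneRef optional provenance string stored in the result.
#' @return A \linkS4class{ScoreMap}.
#' @export
extractScoreMap <- function(fcn, image, sceneRef = "") {
  sz <- fcn@network@spec@inputSize
  if (dim(image)[1] != sz || dim(image)[2] != sz)
    stop("image size does not match the FCN input size ", sz)
  a <- forwardNetwork(fcn, image, upto = "score_fuse")
  new("ScoreMap", tensor = a, sourceLayer = "score_fuse",
      sceneRef = sceneRef)
}

#' Convert a score map to regression-network input
#'
#' \code{"probability_image"} (default): per-pixel softmax across score
#' channels, the mosquito-class probability plane is resized bilinearly to
#' \code{size x size} and replicated to 3 channels -- the rendered
#' probability-map image. \code{"channel_stack"}: all score channels are
#' resized and
#' stacked, each mapped affinely into the unit input range (z/40 + 0.5,
#' clipped; trained score logits stay within about +/-20), for a regressor built with a matching
#' \code{inputChannels}. The stack preserves the score margin that the
#' softmax saturates away, which is what makes blob confidence usable by
#' the count regressor.
#'
#' @param map a \linkS4class{ScoreMap}.
#' @param mode \code{"probability_image"} or \code{"channel_stack"}.
#' @param size output side in pixels (default 227, the reference regressor
#'   input).
#' @param mosquitoClass 0-based class index of the mosquito channel
#'   (default 1; background is class 0).
#' @return numeric array \code{size x size x 3} (probability image) or
#'   \code{size x size x C} (channel stack).
#' @export
scoremapToInput <- function(map, mode = c("probability_image",
                                          "channel_stack"),
                            size = 227L, mosquitoClass = 1L) {
  mode <- match.arg(mode)
  z <- map@tensor
  if (mode == "probability_image") {
    zmax <- apply(z, c(1, 2), max)
    e <- exp(sweep(z, c(1, 2), zmax))
    p <- e[, , mosquitoClass + 1L] / apply(e, c(1, 2), sum)
    plane <- resizeArray(p, size, size)
    array(rep(plane, 3), c(size, size, 3))
  } else {
    out <- array(0, c(size, size, dim(z)[3]))
    for (ch in seq_len(dim(z)[3])) {
      plane <- resizeArray(z[, , ch], size, size) / 40 + 0.5
      out[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    out
  }
}

#' Train the count regressor on score maps
#'
#' Trains an AlexNet-family regressor with Euclidean distance loss on
#' score-map-derived inputs. Labels must already be clamped to the 0--5
#' scheme; unclamped labels are an error (the caller decides how to pool
#' counts above the top bin).
#'
#' @param scoreMaps list of \linkS4class{ScoreMap}.
#' @param counts integer labels in [0, 5], one per map.
#' @param config a \linkS4class{TrainConfig} with \code{loss =
#'   "euclidean"}.
#' @param regressorSpec \linkS4class{NetSpec} of the regressor; default is
#'   a desk-scale reduced-width regressor.
#' @param mode score-map conversion mode (see
#'   \code{\link{scoremapToInput}}).
#' @param augment add the three axis/point flips of every training map
#'   (counting is invariant under them), quadrupling the training set
#'   (default TRUE).
#' @param valFraction fraction of the maps held out for epoch selection;
#'   the returned model carries the weights of the epoch with the lowest
#'   validation loss. 0 disables selection.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainCountRegressor <- function(scoreMaps, counts, config,
                                regressorSpec = NetSpec(
                                  "alexnet_regressor", widthScale = 0.125,
                                  inputSize = 75L),
                                mode = "probability_image",
                                augment = TRUE, valFraction = 0.15) {
  if (any(counts < 0 | counts > 5))
    stop("labels must be clamped to [0, 5] before training")
  if (config@loss != "euclidean")
    stop("the count regressor uses the euclidean loss")
  sz <- regressorSpec@inputSize
  x <- lapply(scoreMaps, scoremapToInput, mode = mode, size = sz)
  y <- as.numeric(counts)
  xv <- NULL; yv <- NULL
  if (valFraction > 0 && length(x) >= 10) {
    idx <- withSeed(config@seed + 7L,
                    sample(length(x), max(2, round(valFraction * length(x)))))
    xv <- x[idx]; yv <- y[idx]
    x <- x[-idx]; y <- y[-idx]
  }
  if (augment) {
    n <- length(x)
    flipH <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
    flipV <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
    for (i in seq_len(n)) {
      a <- x[[i]]
      for (b in list(flipH(a), flipV(a), flipH(flipV(a)))) {
        x[[length(x) + 1]] <- b
        y <- c(y, y[i])
      }
    }
  }
  net <- buildNetwork(regressorSpec)
  trainNetwork(net, x, y, config, xTest = xv, yTest = yv,
               selectBest = !is.null(xv))
}

#' Predict a mosquito count from a score map
#'
#' @param regressor trained count regressor.
#' @param map a \linkS4class{ScoreMap}.
#' @param mode conversion mode (must match training).
#' @return A \linkS4class{CountEstimate}.
#' @export
predictCount <- function(regressor, map, mode = "probability_image") {
  x <- scoremapToInput(map, mode = mode,
                       size = regressor@network@spec@inputSize)
  raw <- as.numeric(forwardNetwork(regressor, x))
  countEstimate(raw)
}
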