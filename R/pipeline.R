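# End-to-end orchestration: desk-scale configuration, pipeline training,
# the per-contour classification baseline, evaluation metrics and the
# larvicide-release trigger.

#' Desk-scale study configuration
#'
#' Default sizes and hyper-parameters for training and evaluating the full
#' pipeline on a CPU. Scenes are 320x320 with 20--28 px sprites (the FCN
#' score grid then resolves 10x10 cells of 32 px, the same stride-32 cell
#' geometry as the full-scale 500x500 design, with sprites spanning one to
#' two cells); the FCN runs at 1/32 width with a 2-channel head
#' (background/mosquito -- the reference 21-channel head keeps 19 channels
#' unused); the classifier runs at 1/8 width on 67x67 inputs with the
#' reference protocol (lr 0.001, step-down decay, 20 epochs); the count
#' regressor runs at 1/8 width on 115x115 channel-stack inputs with flip
#' augmentation and best-validation-epoch selection. The FCN trains with
#' inverse-frequency class weighting because mosquito pixels are <1\% of
#' each label mask.
#'
#' @param sceneSize scene side in pixels.
#' @param nDistractors base number of distractors per scene.
#' @return named list with \code{sceneSpec}, \code{detectParams},
#'   \code{classifierSpec}, \code{classifierConfig}, \code{fcnSpec},
#'   \code{fcnConfig}, \code{regressorSpec}, \code{regressorConfig} and
#'   \code{scoremapMode}.
#' @export
deskConfig <- function(sceneSize = 320L, nDistractors = 2L) {
  # sprites land on the pad's active central area: the score grid's field
  # of view spans the central (sceneSize - 144) px (the final 16x
  # upsampling covers 16*(grid-1)+32 px), so placement keeps that margin.
  # Sprite sizes keep the full-scale mosquito-to-score-cell ratio (about
  # one to two 32 px cells); distractors are occasional pad artifacts.
  sceneSpec <- SceneSpec(width = sceneSize, height = sceneSize,
                         nDistractors = nDistractors,
                         spriteSizeRange = c(20, 28),
                         placementMargin = 72)
  list(
    sceneSpec = sceneSpec,
    detectParams = defaultDetectParams(sceneSpec),
    classifierSpec = NetSpec("alexnet_classifier", widthScale = 0.125,
                             numClasses = 2L, inputSize = 67L),
    classifierConfig = TrainConfig(epochs = 20L, batchSize = 32L,
                                   loss = "softmax_cross_entropy"),
    fcnSpec = NetSpec("fcn", widthScale = 1 / 32, numClasses = 2L,
                      inputSize = sceneSize),
    fcnConfig = TrainConfig(learningRate = 0.05, epochs = 14L,
                            batchSize = 2L, stepSize = 11L,
                            loss = "pixel_softmax"),
    regressorSpec = NetSpec("alexnet_regressor", widthScale = 0.125,
                            inputSize = 115L, inputChannels = 2L),
    regressorConfig = TrainConfig(learningRate = 0.003, epochs = 25L,
                                  batchSize = 32L, stepSize = 19L,
                                  loss = "euclidean"),
    scoremapMode = "channel_stack")
}

#' Extract score maps for many images at once
#'
#' @param fcn trained FCN.
#' @param images list of input arrays.
#' @param batchSize internal batch size.
#' @return list of \linkS4class{ScoreMap}.
#' @export
extractScoreMaps <- function(fcn, images, batchSize = 4L) {
  acts <- forwardNetwork(fcn, images, upto = "score_fuse",
                         batchSize = batchSize)
  lapply(acts, function(a) new("ScoreMap", tensor = a,
                               sourceLayer = "score_fuse", sceneRef = ""))
}

#' Train the complete counting pipeline
#'
#' Runs the whole bootstrapping chain on synthetic data: (1) trains the
#' mosquito/non-mosquito patch classifier on a generated patch set; (2)
#' generates a count-labelled scene set; (3) auto-labels a subset of scenes
#' with the classifier (purple-on-black masks) and trains the FCN on the
#' pairs; (4) extracts the pre-deconvolution score maps of all training
#' scenes and trains the count regressor on them with Euclidean loss.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param config configuration list from \code{\link{deskConfig}}.
#' @param perLabel training scenes per label 0--5 (default 60).
#' @param nFcnImages scenes auto-labelled for FCN training (default 100).
#' @param nPatches length-2 integer: mosquito / non-mosquito patches for
#'   classifier training.
#' @param verbose print stage progress.
#' @return A \linkS4class{CountingPipeline}.
#' @export
trainCountingPipeline <- function(seed = 1L, config = deskConfig(),
                                  perLabel = 60L, nFcnImages = 100L,
                                  nPatches = c(600L, 600L),
                                  verbose = FALSE) {
  seeds <- subSeeds(seed, 6L)
  say <- function(...) if (verbose) message(...)

  say("training patch classifier ...")
  pd <- generatePatchDataset(nPatches[1], nPatches[2], seed = seeds[1],
                             baseSpec = config$sceneSpec)
  sz <- config$classifierSpec@inputSize
  px <- lapply(pd$patches, resizeArray, h = sz, w = sz)
  ccfg <- config$classifierConfig
  ccfg@seed <- as.integer(seeds[2] %% .Machine$integer.max)
  classifier <- trainNetwork(buildNetwork(config$classifierSpec), px,
                             pd$labels, ccfg)
  rm(pd, px)

  say("generating training scenes ...")
  trainScenes <- generateCountDataset(perLabel, config$sceneSpec,
                                      seed = seeds[3])
  ord <- withSeed(seeds[4], sample(length(trainScenes)))
  trainScenes <- trainScenes[ord]

  say("auto-labelling and training FCN ...")
  fset <- buildFcnTrainingSet(trainScenes, classifier,
                              nImages = min(nFcnImages, length(trainScenes)),
                              detectParams = config$detectParams)
  ymask <- lapply(fset$masks, function(m) m@classIndex)
  fcfg <- config$fcnConfig
  fcfg@seed <- as.integer(seeds[5] %% .Machine$integer.max)
  if (!length(fcfg@classWeights)) {
    fg <- mean(vapply(ymask, function(m) mean(m == 1L), numeric(1)))
    fcfg@classWeights <- c(1, min(50, (1 - fg) / max(fg, 1e-6)))
  }
  fcn <- trainNetwork(buildNetwork(config$fcnSpec), fset$images, ymask,
                      fcfg)

  say("extracting score maps and training count regressor ...")
  maps <- extractScoreMaps(fcn, lapply(trainScenes, sceneImage))
  rcfg <- config$regressorConfig
  rcfg@seed <- as.integer(seeds[6] %% .Machine$integer.max)
  regressor <- trainCountRegressor(maps, sceneLabels(trainScenes), rcfg,
                                   regressorSpec = config$regressorSpec,
                                   mode = config$scoremapMode)

  new("CountingPipeline", classifier = classifier, fcn = fcn,
      regressor = regressor, detectParams = config$detectParams,
      scoremapMode = config$scoremapMode, seed = as.integer(seed))
}

#' Count mosquitoes by classifying every contour (baseline)
#'
#' The comparison method: every size-filtered dark contour is cropped and
#' classified individually; the count is the number of contours the patch
#' classifier accepts as mosquito. One network inference per contour. The
#' count is not clamped.
#'
#' @param image scene array.
#' @param detectParams a \linkS4class{DetectParams}.
#' @param classifier trained 2-class patch model, or \code{NULL} to accept
#'   every contour (oracle substitution for diagnostics).
#' @param acceptThreshold minimum mosquito probability.
#' @return integer count.
#' @export
countByClassifier <- function(image, detectParams, classifier,
                              acceptThreshold = 0.5) {
  det <- detectCandidates(image, detectParams)
  if (length(det) == 0) return(0L)
  if (is.null(classifier)) return(length(det))
  probs <- classifyPatches(classifier, det@patches)
  as.integer(sum(probs[, 2] >= acceptThreshold))
}

#' Count mosquitoes by score-map regression
#'
#' The pipeline method: one FCN forward pass to the pre-deconvolution
#' score map, one regressor forward pass on the rendered probability image
#' -- exactly two network inferences per image, independent of how many
#' objects it contains.
#'
#' @param image scene array (FCN input size).
#' @param fcn trained FCN.
#' @param regressor trained count regressor.
#' @param mode score-map conversion mode.
#' @return A \linkS4class{CountEstimate}.
#' @export
countByRegression <- function(image, fcn, regressor,
                              mode = "probability_image") {
  predictCount(regressor, extractScoreMap(fcn, image), mode = mode)
}

#' Evaluate counts against clamped labels
#'
#' Accuracy uses the clamped rule: a prediction is correct when its integer
#' count equals the label, or when the label is the top bin (5) and the raw
#' output exceeds 5. The RMSE for the regression method caps raw outputs at
#' 5 on top-bin images (mirroring the accuracy rule); the baseline's RMSE
#' uses its unclamped integer counts, which is what makes its
#' overcounting visible.
#'
#' @param predictions list of \linkS4class{CountEstimate} (regression) or
#'   integer vector of counts (baseline).
#' @param trueLabels integer labels in [0, 5].
#' @param method \code{"fcn_regression"} or \code{"contour_classifier"}.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateCounts <- function(predictions, trueLabels,
                           method = c("fcn_regression",
                                      "contour_classifier")) {
  method <- match.arg(method)
  n <- length(trueLabels)
  if (length(predictions) != n)
    stop("predictions and trueLabels must have equal length")
  if (any(trueLabels < 0 | trueLabels > 5))
    stop("labels must lie in [0, 5]")
  if (method == "fcn_regression") {
    raw <- vapply(predictions, function(p) p@raw, numeric(1))
    cnt <- vapply(predictions, function(p) p@count, integer(1))
    resid <- ifelse(trueLabels == 5, pmin(raw, 5), raw) - trueLabels
  } else {
    cnt <- as.integer(predictions)
    raw <- as.numeric(cnt)
    resid <- raw - trueLabels
  }
  correct <- cnt == trueLabels | (trueLabels == 5 & raw > 5)
  new("EvalReport", nImages = as.integer(n),
      accuracy = mean(correct), rmse = sqrt(mean(resid^2)),
      perImage = data.frame(true_label = as.integer(trueLabels),
                            predicted_count = as.integer(cnt), raw = raw),
      method = method)
}

#' Evaluate both counting methods on a scene set
#'
#' @param pipeline a \linkS4class{CountingPipeline}.
#' @param scenes list of \linkS4class{PadScene} (test set).
#' @param batchSize internal batch size for the regression path.
#' @return list with elements \code{fcn_regression} and
#'   \code{contour_classifier}, both \linkS4class{EvalReport}.
#' @export
evaluatePipeline <- function(pipeline, scenes, batchSize = 4L) {
  labels <- sceneLabels(scenes)
  images <- lapply(scenes, sceneImage)
  maps <- extractScoreMaps(pipeline@fcn, images, batchSize = batchSize)
  sz <- pipeline@regressor@network@spec@inputSize
  xs <- lapply(maps, scoremapToInput, mode = pipeline@scoremapMode,
               size = sz)
  raw <- vapply(forwardNetwork(pipeline@regressor, xs,
                               batchSize = 2L * batchSize),
                as.numeric, numeric(1))
  est <- lapply(raw, countEstimate)
  base <- vapply(images, countByClassifier, integer(1),
                 detectParams = pipeline@detectParams,
                 classifier = pipeline@classifier)
  list(fcn_regression = evaluateCounts(est, labels, "fcn_regression"),
       contour_classifier = evaluateCounts(base, labels,
                                           "contour_classifier"))
}

#' Larvicide-release trigger rule
#'
#' Fires when, over the trailing \code{window} observations, the counts are
#' all at least \code{minCount} and non-decreasing within \code{slack}
#' (each successive count may drop by at most \code{slack}) -- i.e. a
#' constant or increasing number of mosquitoes is being observed, the
#' signature of an active nearby breeding site.
#'
#' @param series a \linkS4class{CountSeries}.
#' @param minCount minimum count required throughout the window.
#' @param window trailing window length (default: the series' window).
#' @param slack tolerated decrease between successive observations.
#' @return logical: release the larvicide package?
#' @examples
#' releaseDecision(CountSeries(c(3, 3, 3, 3)))   # TRUE (constant)
#' releaseDecision(CountSeries(c(1, 2, 3, 4)))   # TRUE (increasing)
#' releaseDecision(CountSeries(c(0, 0, 0, 0)))   # FALSE (nothing observed)
#' releaseDecision(CountSeries(c(4, 3, 2, 1)))   # FALSE (declining)
#' @export
releaseDecision <- function(series, minCount = 1L, window = series@window,
                            slack = 0L) {
  validObject(series)
  n <- length(series@counts)
  if (n < window)
    stop("series shorter than the trigger window (", window, ")")
  tailc <- series@counts[(n - window + 1L):n]
  all(tailc >= minCount) && all(diff(tailc) >= -slack)
}

#' Plot ground truth against both counting methods
#'
#' Per-image comparison in the style of a method head-to-head: ground-truth
#' labels as points, the regression and baseline counts as lines.
#'
#' @param regReport,baseReport \linkS4class{EvalReport}s over the same
#'   images.
#' @param ... passed to \code{plot}.
#' @return invisibly \code{NULL}.
#' @importFrom graphics legend lines points
#' @export
plotEvalReports <- function(regReport, baseReport, ...) {
  gt <- regReport@perImage$true_label
  o <- order(gt)
  plot(seq_along(gt), gt[o], col = "red", pch = 1,
       xlab = "test image (sorted by true count)", ylab = "count",
       ylim = range(c(gt, regReport@perImage$predicted_count,
                      baseReport@perImage$predicted_count)), ...)
  lines(seq_along(gt), regReport@perImage$predicted_count[o],
        col = "darkgreen")
  lines(seq_along(gt), baseReport@perImage$predicted_count[o], col = "blue",
        lty = 2)
  legend("topleft", bty = "n",
         legend = c("ground truth", "score-map regression",
                    "per-contour baseline"),
         col = c("red", "darkgreen", "blue"), pch = c(1, NA, NA),
         lty = c(NA, 1, 2))
  invisible(NULL)
}
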