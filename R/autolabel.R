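# Bootstrapped FCN labels: detections accepted by the patch classifier are
# painted purple (255,0,255) on a black canvas. Only the thresholded
# foreground component of a detection is painted, not its square patch, so
# the mosquito class area stays close to the true silhouette.

PURPLE <- c(1, 0, 1)

#' Build a pixel-label mask from classifier-accepted detections
#'
#' Re-runs the dark-object binarisation with the detection parameters,
#' labels its connected components, classifies every detection's patch and
#' paints the foreground component of each detection whose mosquito-class
#' probability reaches \code{acceptThreshold} purple on a black canvas.
#'
#' @param image numeric array \code{H x W x 3} (the scene the detections
#'   came from).
#' @param detections a \linkS4class{DetectionSet} with patches (from
#'   \code{\link{detectCandidates}}).
#' @param classifier trained 2-class patch classifier, or \code{NULL} to
#'   accept every detection (oracle-free labelling for diagnostics).
#' @param acceptThreshold minimum mosquito-class probability (default 0.5,
#'   i.e. argmax).
#' @return A \linkS4class{LabelMask}.
#' @export
makeLabelMask <- function(image, detections, classifier,
                          acceptThreshold = 0.5) {
  H <- dim(image)[1]; W <- dim(image)[2]
  n <- length(detections)
  accept <- rep(TRUE, n)
  if (!is.null(classifier) && n > 0) {
    if (classifier@network@spec@numClasses != 2L)
      stop("classifier must be a 2-class patch model")
    if (length(detections@patches) != n)
      stop("detections must carry patches (use detectCandidates)")
    probs <- classifyPatches(classifier, detections@patches)
    accept <- probs[, 2] >= acceptThreshold
  }
  cls <- matrix(0L, H, W)
  if (any(accept)) {
    lab <- labelComponents(binarizeImage(image, detections@params))
    for (i in which(accept)) {
      ctr <- round(detections@centroids[i, ]) + 1L
      ctr <- pmin(pmax(ctr, 1L), c(H, W))
      id <- lab[ctr[1], ctr[2]]
      if (id == 0) {
        # centroid fell off a concave component: majority id inside the box
        b <- detections@boxes[i, ]
        sub <- lab[(b[2] + 1):b[4], (b[1] + 1):b[3]]
        ids <- sub[sub > 0]
        if (!length(ids)) next
        id <- as.integer(names(which.max(table(ids))))
      }
      cls[lab == id] <- 1L
    }
  }
  raster <- array(0, c(H, W, 3))
  for (ch in 1:3) raster[, , ch][cls == 1L] <- PURPLE[ch]
  new("LabelMask", raster = raster, classIndex = cls)
}

#' Build an image/label-mask training set for the FCN
#'
#' Applies \code{\link{detectCandidates}} and \code{\link{makeLabelMask}} to
#' the first \code{nImages} scenes (deterministic order) and returns the
#' paired set with a manifest.
#'
#' @param scenes list of \linkS4class{PadScene}.
#' @param classifier trained patch classifier (or \code{NULL}, see
#'   \code{\link{makeLabelMask}}).
#' @param nImages number of pairs to build (must not exceed the number of
#'   scenes).
#' @param detectParams a \linkS4class{DetectParams}; default derived from
#'   the first scene's spec.
#' @param acceptThreshold forwarded to \code{\link{makeLabelMask}}.
#' @return list with \code{images} (list of arrays), \code{masks} (list of
#'   \linkS4class{LabelMask}) and \code{manifest} (data.frame with scene
#'   index, true count and painted-component count).
#' @export
buildFcnTrainingSet <- function(scenes, classifier, nImages = length(scenes),
                                detectParams = NULL,
                                acceptThreshold = 0.5) {
  if (nImages > length(scenes))
    stop("nImages exceeds the number of available scenes")
  if (is.null(detectParams))
    detectParams <- defaultDetectParams(sceneSpec(scenes[[1]]))
  idx <- seq_len(nImages)
  images <- lapply(scenes[idx], sceneImage)
  masks <- lapply(idx, function(i) {
    det <- detectCandidates(images[[i]], detectParams)
    makeLabelMask(images[[i]], det, classifier, acceptThreshold)
  })
  manifest <- data.frame(
    scene = idx,
    true_count = vapply(scenes[idx], sceneCount, integer(1)),
    painted_components = vapply(masks, function(m)
      max(labelComponents(m@classIndex)), numeric(1)))
  list(images = images, masks = masks, manifest = manifest)
}
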