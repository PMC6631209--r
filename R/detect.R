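# Classical dark-object candidate detection: grayscale conversion,
# thresholding, size-filtered connected components, 60x60 patch crops.

#' Derive detection parameters from a scene specification
#'
#' The area window is derived from the sprite size range: the nominal body
#' area of a sprite with longest axis L is about 0.1 L^2 (an ellipse with
#' semi-axes 0.30 L and 0.105 L), and the window spans 0.25x the nominal
#' area at the smallest sprite to 4x at the largest.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param ... passed to \code{\link{DetectParams}} (e.g. thresholdMode).
#' @return A \linkS4class{DetectParams}.
#' @export
defaultDetectParams <- function(spec, ...) {
  nominal <- function(L) 0.1 * L^2
  DetectParams(areaMin = 0.25 * nominal(spec@spriteSizeRange[1]),
               areaMax = 4 * nominal(spec@spriteSizeRange[2]), ...)
}

#' Binarize a pad image into a dark-object mask
#'
#' Converts to grayscale with ITU-R BT.601 luma weights and thresholds with
#' the black-object convention: foreground pixels are those darker than the
#' threshold. In \code{"otsu"} mode the threshold is computed automatically;
#' because the pad is nearly uniform, an automatic threshold is only
#' accepted when it marks less than 15\% of the image as foreground --
#' otherwise the image is treated as containing no dark objects (an Otsu
#' split of a plain noisy background would otherwise label about half of
#' the pad as foreground). An optional morphological opening with a disc
#' brush removes speckle.
#'
#' @param image numeric array \code{H x W x 3} in [0, 1].
#' @param params a \linkS4class{DetectParams}.
#' @return integer matrix \code{H x W}, 1 = foreground (dark object).
#' @examples
#' sc <- generateScene(SceneSpec(nMosquitoes = 2, width = 200, height = 200,
#'                               spriteSizeRange = c(16, 30), seed = 3))
#' sum(binarizeImage(sceneImage(sc), DetectParams()))
#' @export
binarizeImage <- function(image, params = DetectParams()) {
  validObject(params)
  g <- luma(image)
  if (params@thresholdMode == "fixed") {
    thr <- params@fixedThreshold / 255
  } else {
    thr <- EBImage::otsu(EBImage::Image(t(g)), range = c(0, 1))
    if (mean(g < thr) > 0.15) thr <- -Inf   # no credible dark objects
  }
  fg <- matrix(as.integer(g < thr), nrow(g), ncol(g))
  if (params@morphOpenRadius > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(params@morphOpenRadius) + 1,
                                shape = "disc")
    fg <- t(EBImage::opening(EBImage::Image(t(fg)), brush)@.Data)
    storage.mode(fg) <- "integer"
  }
  fg
}

# connected components of a 0/1 matrix (4-connectivity), via EBImage
labelComponents <- function(binary) {
  lab <- EBImage::bwlabel(EBImage::Image(t(binary)))
  t(lab@.Data)
}

#' Find size-filtered candidate detections
#'
#' Labels connected foreground components (4-connectivity) and keeps those
#' whose pixel area lies in \code{[areaMin, areaMax]}. Components touching
#' the image border are retained. Candidates are sorted by centroid (row,
#' then column) so the output order is deterministic.
#'
#' @param binary integer matrix from \code{\link{binarizeImage}}.
#' @param params a \linkS4class{DetectParams}.
#' @return A \linkS4class{DetectionSet} (without patches).
#' @export
findCandidates <- function(binary, params = DetectParams()) {
  validObject(params)
  lab <- labelComponents(binary)
  n <- max(lab)
  bx <- matrix(0L, 0, 4, dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  ce <- matrix(0, 0, 2, dimnames = list(NULL, c("row", "col")))
  ar <- numeric(0)
  if (n > 0) {
    idx <- which(lab > 0)
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    comp <- lab[idx]
    for (k in seq_len(n)) {
      sel <- comp == k
      a <- sum(sel)
      if (a < params@areaMin || a > params@areaMax) next
      r <- rows[sel]; c <- cols[sel]
      bx <- rbind(bx, c(min(c) - 1L, min(r) - 1L, max(c), max(r)))
      ce <- rbind(ce, c(mean(r) - 1, mean(c) - 1))
      ar <- c(ar, a)
    }
    if (nrow(bx) > 1) {
      o <- order(ce[, 1], ce[, 2])
      bx <- bx[o, , drop = FALSE]; ce <- ce[o, , drop = FALSE]; ar <- ar[o]
    }
  }
  rownames(bx) <- NULL; rownames(ce) <- NULL
  new("DetectionSet", boxes = bx, centroids = ce, areas = ar,
      patches = list(), params = params)
}

#' Crop a square patch around a detection box
#'
#' The patch is centred on the box centroid; parts falling outside the image
#' are filled with the median background colour (per channel) rather than
#' zeros, so border detections do not acquire artificial dark edges.
#'
#' @param image numeric array \code{H x W x 3}.
#' @param box numeric length 4, half-open 0-based \code{x0, y0, x1, y1}.
#' @param size patch side in pixels (default 60).
#' @return numeric array \code{size x size x 3}.
#' @export
cropPatch <- function(image, box, size = 60L) {
  if (box[3] <= box[1] || box[4] <= box[2]) stop("zero-area box")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (box[1] >= W || box[2] >= H || box[3] <= 0 || box[4] <= 0)
    stop("box does not intersect the image")
  cr <- (box[2] + box[4]) / 2   # centre row (0-based continuous)
  cc <- (box[1] + box[3]) / 2
  r0 <- round(cr - size / 2); c0 <- round(cc - size / 2)
  fill <- vapply(1:3, function(ch) median(image[, , ch]), numeric(1))
  patch <- array(rep(fill, each = size * size), c(size, size, 3))
  rr <- (r0 + 1):(r0 + size); cc2 <- (c0 + 1):(c0 + size)
  rok <- rr >= 1 & rr <= H; cok <- cc2 >= 1 & cc2 <= W
  patch[rok, cok, ] <- image[rr[rok], cc2[cok], , drop = FALSE]
  patch
}

#' Detect candidates and crop their patches in one call
#'
#' Convenience wrapper: \code{\link{binarizeImage}},
#' \code{\link{findCandidates}}, then \code{\link{cropPatch}} around every
#' candidate.
#'
#' @param image numeric array \code{H x W x 3}.
#' @param params a \linkS4class{DetectParams}.
#' @param patchSize patch side (default 60).
#' @return A \linkS4class{DetectionSet} with patches.
#' @export
detectCandidates <- function(image, params = DetectParams(),
                             patchSize = 60L) {
  det <- findCandidates(binarizeImage(image, params), params)
  if (nrow(det@boxes))
    det@patches <- lapply(seq_len(nrow(det@boxes)), function(i)
      cropPatch(image, det@boxes[i, ], patchSize))
  det
}
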