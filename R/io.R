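# Disk formats: scenes as 8-bit RGB PNG, masks as 0/255 grayscale PNG,
# ground truth as sidecar JSON, dataset manifests as CSV.

arrayToImage <- function(arr) {
  # our arrays are (row, col[, channel]); EBImage stores (x, y[, channel])
  if (length(dim(arr)) == 2) EBImage::Image(t(arr))
  else EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color")
}

imageToArray <- function(img) {
  d <- img@.Data
  if (length(dim(d)) == 2) t(d) else aperm(d, c(2, 1, 3))
}

#' Write / read a scene with its ground truth
#'
#' The image goes to \code{<path>.png}, the mask to \code{<path>_mask.png}
#' (0/255 grayscale) and the ground truth to \code{<path>.json}
#' (\code{count}, \code{boxes} as half-open 0-based \code{[x0,y0,x1,y1]},
#' \code{seed}).
#'
#' @param scene a \linkS4class{PadScene}.
#' @param path file stem (no extension).
#' @return \code{writeScene}: invisibly the stem. \code{readScene}: a
#'   \linkS4class{PadScene} (with the stored spec reduced to its seed and
#'   geometry).
#' @export
writeScene <- function(scene, path) {
  EBImage::writeImage(arrayToImage(scene@image), paste0(path, ".png"))
  EBImage::writeImage(arrayToImage(scene@mask), paste0(path, "_mask.png"))
  jsonlite::write_json(
    list(count = scene@count,
         boxes = if (nrow(scene@boxes)) unname(as.matrix(scene@boxes))
                 else matrix(0L, 0, 4),
         seed = scene@spec@seed,
         width = scene@spec@width, height = scene@spec@height),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  img <- imageToArray(EBImage::readImage(paste0(path, ".png")))
  mask <- imageToArray(EBImage::readImage(paste0(path, "_mask.png")))
  mask <- matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask))
  gt <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  boxes <- matrix(as.integer(gt$boxes), ncol = 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  spec <- SceneSpec(width = gt$width, height = gt$height,
                    nMosquitoes = gt$count, seed = gt$seed)
  new("PadScene", image = img, count = as.integer(gt$count), boxes = boxes,
      mask = mask, spec = spec)
}

#' Write / read a scene dataset with a manifest
#'
#' Scenes are stored as \code{scene_0001} ... stems via
#' \code{\link{writeScene}} plus a \code{manifest.csv} with columns
#' \code{path, label, count, seed}.
#'
#' @param scenes list of \linkS4class{PadScene}.
#' @param dir output directory (created if missing).
#' @return \code{writeSceneDataset}: invisibly the manifest data.frame.
#'   \code{readSceneDataset}: list of \linkS4class{PadScene}.
#' @export
writeSceneDataset <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stems <- sprintf("scene_%04d", seq_along(scenes))
  for (i in seq_along(scenes))
    writeScene(scenes[[i]], file.path(dir, stems[i]))
  manifest <- data.frame(path = stems,
                         label = sceneLabels(scenes),
                         count = vapply(scenes, sceneCount, integer(1)),
                         seed = vapply(scenes, function(s) s@spec@seed,
                                       integer(1)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname writeSceneDataset
#' @export
readSceneDataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$path, function(p) readScene(file.path(dir, p)))
}

#' Write / read a label mask
#'
#' Stored as an RGB PNG holding exactly the black/purple palette; reading
#' reconstructs the class-index raster from the palette.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param file PNG path.
#' @return \code{readLabelMask}: a \linkS4class{LabelMask}.
#' @export
writeLabelMask <- function(mask, file) {
  EBImage::writeImage(arrayToImage(mask@raster), file)
  invisible(file)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(file) {
  r <- imageToArray(EBImage::readImage(file))
  r <- round(r)
  cls <- matrix(as.integer(r[, , 1] == 1 & r[, , 3] == 1),
                nrow(r), ncol(r))
  new("LabelMask", raster = r, classIndex = cls)
}

#' Read a count time series from CSV
#'
#' Expects columns \code{timestamp} (optional) and \code{count}.
#'
#' @param file CSV path.
#' @param window trigger window (default 4).
#' @return A \linkS4class{CountSeries}.
#' @export
readCountSeries <- function(file, window = 4L) {
  d <- read.csv(file)
  ts <- if ("timestamp" %in% names(d)) d$timestamp else seq_len(nrow(d))
  CountSeries(d$count, ts, window = window)
}
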