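# Dark-object candidate detection: thresholding, component filtering,
# patch cropping, and the clean-scene detection == ground truth property.

cleanSpec <- function(...) {
  SceneSpec(width = 220, height = 220, spriteSizeRange = c(14, 26),
            placementMargin = 20, noiseSigma = 2,
            illuminationGradient = 0.03, ...)
}

test_that("a uniform white image binarizes to all background", {
  img <- array(1, c(64, 64, 3))
  expect_true(all(binarizeImage(img, DetectParams()) == 0L))
  expect_true(all(binarizeImage(img,
                                DetectParams("fixed",
                                             fixedThreshold = 128)) == 0L))
})

test_that("fixed thresholds outside [0,255] are rejected", {
  expect_error(DetectParams("fixed", fixedThreshold = 300), "0, 255")
})

test_that("binarization separates exactly the dark sprites", {
  spec <- cleanSpec(nMosquitoes = 3, seed = 41)
  sc <- generateScene(spec)
  fg <- binarizeImage(sceneImage(sc), defaultDetectParams(spec))
  expect_equal(nComponents(fg), 3L)
  spec2 <- cleanSpec(nMosquitoes = 1, nDistractors = 1, seed = 15)
  fg2 <- binarizeImage(sceneImage(generateScene(spec2)),
                       defaultDetectParams(spec2))
  expect_equal(nComponents(fg2), 2L)  # distractors are dark objects too
})

test_that("area filtering matches a brute-force component filter", {
  # 3 in-range blobs + 1 giant + 1 speck
  bin <- matrix(0L, 120, 120)
  bin[10:17, 10:17] <- 1L      # 64 px
  bin[30:38, 60:68] <- 1L      # 81 px
  bin[80:87, 20:28] <- 1L      # 72 px
  bin[50:95, 80:119] <- 1L     # giant
  bin[3, 3] <- 1L              # single-pixel speck
  params <- DetectParams(areaMin = 20, areaMax = 200)
  det <- findCandidates(bin, params)
  lab <- bfsComponents(bin)
  sizes <- tabulate(lab[lab > 0])
  expect_equal(length(det), sum(sizes >= 20 & sizes <= 200))
  expect_equal(length(det), 3L)
  expect_equal(unname(det@areas), c(64, 81, 72)[order(c(13.5, 34, 83.5))])
})

test_that("two touching sprites merge into a single detection", {
  bin <- matrix(0L, 60, 60)
  bin[20:28, 10:20] <- 1L
  bin[28:36, 18:30] <- 1L      # overlaps the first blob -> one component
  det <- findCandidates(bin, DetectParams(areaMin = 10, areaMax = 500))
  expect_equal(length(det), 1L)
})

test_that("components touching the border are retained", {
  bin <- matrix(0L, 50, 50)
  bin[1:6, 1:6] <- 1L
  expect_equal(length(findCandidates(bin, DetectParams(areaMin = 10,
                                                       areaMax = 100))), 1L)
})

test_that("relaxing the area window never loses detections", {
  set.seed(99)
  for (i in 1:5) {
    bin <- matrix(rbinom(80 * 80, 1, 0.02), 80, 80)
    bin <- t(EBImage::dilate(EBImage::Image(t(bin)),
                             EBImage::makeBrush(3, "box"))@.Data)
    storage.mode(bin) <- "integer"
    narrow <- findCandidates(bin, DetectParams(areaMin = 12, areaMax = 60))
    wide <- findCandidates(bin, DetectParams(areaMin = 6, areaMax = 200))
    expect_gte(length(wide), length(narrow))
  }
})

test_that("on clean scenes detections equal ground truth one-to-one", {
  for (seed in c(3, 29)) {
    spec <- cleanSpec(nMosquitoes = 4, seed = seed)
    sc <- generateScene(spec)
    det <- findCandidates(binarizeImage(sceneImage(sc),
                                        defaultDetectParams(spec)),
                          defaultDetectParams(spec))
    expect_equal(length(det), sceneCount(sc))
    # IoU-based matching: each detection overlaps exactly one true box
    gt <- sceneBoxes(sc)
    iou <- function(a, b) {
      ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
      iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
      inter <- ix * iy
      inter / ((a[3] - a[1]) * (a[4] - a[2]) +
                 (b[3] - b[1]) * (b[4] - b[2]) - inter)
    }
    m <- outer(seq_len(length(det)), seq_len(nrow(gt)),
               Vectorize(function(i, j) iou(boxes(det)[i, ], gt[j, ])))
    expect_true(all(rowSums(m > 0.3) == 1))
    expect_true(all(colSums(m > 0.3) == 1))
  }
})

test_that("detection output is deterministic and sorted by centroid", {
  spec <- cleanSpec(nMosquitoes = 5, nDistractors = 2, seed = 8)
  img <- sceneImage(generateScene(spec))
  d1 <- detectCandidates(img, defaultDetectParams(spec))
  d2 <- detectCandidates(img, defaultDetectParams(spec))
  expect_identical(boxes(d1), boxes(d2))
  expect_identical(d1@patches, d2@patches)
  expect_true(!is.unsorted(centroids(d1)[, "row"]))
})

test_that("cropPatch centres, pads with background, and validates boxes", {
  img <- array(0.9, c(100, 100, 3))
  img[40:59, 45:64, ] <- 0.1
  p <- cropPatch(img, c(44, 39, 64, 59), 60)
  expect_equal(dim(p), c(60, 60, 3))
  expect_equal(p[30, 30, 1], 0.1)     # centre is inside the dark box
  # corner box: out-of-image area filled with the median background
  p2 <- cropPatch(img, c(0, 0, 8, 8), 60)
  expect_equal(dim(p2), c(60, 60, 3))
  expect_equal(p2[1, 1, 1], 0.9)
  expect_error(cropPatch(img, c(10, 10, 10, 20)), "zero-area")
  expect_error(cropPatch(img, c(150, 150, 160, 160)), "intersect")
})
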