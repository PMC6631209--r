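# Bootstrapped label masks: palette purity, component-level agreement with
# ground truth under oracle acceptance, and disk round-trips.

alSpec <- function(...) {
  SceneSpec(width = 220, height = 220, spriteSizeRange = c(14, 26),
            placementMargin = 20, noiseSigma = 3, ...)
}

test_that("zero detections give an all-black mask", {
  img <- array(0.92, c(80, 80, 3))
  det <- detectCandidates(img, DetectParams())
  m <- makeLabelMask(img, det, classifier = NULL)
  expect_true(all(m@raster == 0))
  expect_true(all(m@classIndex == 0L))
})

test_that("masks contain exactly the black/purple palette", {
  spec <- alSpec(nMosquitoes = 3, nDistractors = 2, seed = 12)
  img <- sceneImage(generateScene(spec))
  det <- detectCandidates(img, defaultDetectParams(spec))
  m <- makeLabelMask(img, det, classifier = NULL)
  expect_true(validObject(m))
  cols <- unique(matrix(m@raster, ncol = 3))
  expect_true(nrow(cols) <= 2)
  expect_true(all(apply(cols, 1, function(p)
    identical(p, c(0, 0, 0)) || identical(p, c(1, 0, 1)))))
  expect_gt(sum(m@classIndex), 0)
})

test_that("with accept-all labelling purple components equal the count on
           distractor-free scenes", {
  for (seed in c(4, 40)) {
    spec <- alSpec(nMosquitoes = 4, seed = seed)
    sc <- generateScene(spec)
    det <- detectCandidates(sceneImage(sc), defaultDetectParams(spec))
    m <- makeLabelMask(sceneImage(sc), det, classifier = NULL)
    expect_equal(nComponents(m@classIndex), sceneCount(sc))
    # painted pixels sit inside the ground-truth boxes
    pos <- which(m@classIndex == 1L, arr.ind = TRUE)
    bx <- sceneBoxes(sc)
    inAny <- vapply(seq_len(nrow(pos)), function(i) {
      any(pos[i, 2] - 1 >= bx[, "x0"] & pos[i, 2] - 1 < bx[, "x1"] &
            pos[i, 1] - 1 >= bx[, "y0"] & pos[i, 1] - 1 < bx[, "y1"])
    }, logical(1))
    expect_true(all(inAny))
  }
})

test_that("the classifier's rejections remove distractor components", {
  clf <- smallClassifier()
  spec <- alSpec(nMosquitoes = 2, nDistractors = 3, seed = 23)
  sc <- generateScene(spec)
  det <- detectCandidates(sceneImage(sc), defaultDetectParams(spec))
  all5 <- makeLabelMask(sceneImage(sc), det, classifier = NULL)
  filt <- makeLabelMask(sceneImage(sc), det, clf)
  expect_lte(nComponents(filt@classIndex), nComponents(all5@classIndex))
})

test_that("FCN training sets pair scenes with masks and round-trip disk", {
  scenes <- lapply(c(61, 62, 63), function(s)
    generateScene(alSpec(nMosquitoes = 2, seed = s)))
  fs <- buildFcnTrainingSet(scenes, classifier = NULL, nImages = 2)
  expect_length(fs$images, 2)
  expect_length(fs$masks, 2)
  expect_equal(nrow(fs$manifest), 2)
  expect_equal(fs$manifest$true_count, c(2L, 2L))
  expect_error(buildFcnTrainingSet(scenes, NULL, nImages = 7), "exceeds")
  d <- withr::local_tempdir()
  writeLabelMask(fs$masks[[1]], file.path(d, "m.png"))
  back <- readLabelMask(file.path(d, "m.png"))
  expect_identical(back@classIndex, fs$masks[[1]]@classIndex)
  expect_identical(back@raster, fs$masks[[1]]@raster)
})
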