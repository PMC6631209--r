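# Scene, patch and dataset generation: ground-truth consistency,
# determinism, sprite geometry and the contrast guarantee.

deskSpec <- function(...) {
  SceneSpec(width = 220, height = 220, spriteSizeRange = c(14, 26),
            placementMargin = 20, ...)
}

test_that("an empty noise-free scene is a uniform background", {
  sc <- generateScene(deskSpec(noiseSigma = 0, illuminationGradient = 0,
                               seed = 1))
  expect_equal(sceneCount(sc), 0L)
  expect_equal(nrow(sceneBoxes(sc)), 0L)
  expect_true(all(sceneMask(sc) == 0L))
  for (ch in 1:3)
    expect_equal(diff(range(sceneImage(sc)[, , ch])), 0)
})

test_that("ground truth is consistent: count == boxes == mask components", {
  for (seed in c(7, 19, 83)) {
    sc <- generateScene(deskSpec(nMosquitoes = 3, nDistractors = 2,
                                 seed = seed))
    expect_equal(sceneCount(sc), 3L)
    expect_equal(nrow(sceneBoxes(sc)), 3L)
    expect_equal(nComponents(sceneMask(sc)), 3L)  # independent BFS oracle
    # every mask-positive pixel lies inside exactly one (half-open) box
    pos <- which(sceneMask(sc) == 1L, arr.ind = TRUE)
    bx <- sceneBoxes(sc)
    inBox <- vapply(seq_len(nrow(pos)), function(i) {
      r <- pos[i, 1] - 1L; c <- pos[i, 2] - 1L
      sum(c >= bx[, "x0"] & c < bx[, "x1"] &
            r >= bx[, "y0"] & r < bx[, "y1"])
    }, numeric(1))
    expect_true(all(inBox == 1))
  }
})

test_that("sprite bounding boxes respect the size range", {
  sc <- generateScene(deskSpec(nMosquitoes = 6, seed = 5))
  bx <- sceneBoxes(sc)
  longest <- pmax(bx[, "x1"] - bx[, "x0"], bx[, "y1"] - bx[, "y0"])
  expect_true(all(longest >= 14 & longest <= 26))
})

test_that("scene generation is bit-reproducible and seed-sensitive", {
  spec <- deskSpec(nMosquitoes = 4, nDistractors = 3, seed = 11)
  a <- generateScene(spec)
  b <- generateScene(spec)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(sceneMask(a), sceneMask(b))
  spec@seed <- 12L
  expect_false(identical(sceneImage(a), sceneImage(generateScene(spec))))
})

test_that("mask pixels honour the minimum-contrast guarantee", {
  spec <- deskSpec(nMosquitoes = 4, noiseSigma = 0, seed = 21,
                   minContrast = 70)
  sc <- generateScene(spec)
  bg <- spec; bg@nMosquitoes <- 0L; bg@nDistractors <- 0L
  lumBg <- 0.299 * generateScene(bg)@image[, , 1] +
    0.587 * generateScene(bg)@image[, , 2] +
    0.114 * generateScene(bg)@image[, , 3]
  lumSc <- 0.299 * sceneImage(sc)[, , 1] + 0.587 * sceneImage(sc)[, , 2] +
    0.114 * sceneImage(sc)[, , 3]
  onMask <- sceneMask(sc) == 1L
  expect_true(min(lumBg[onMask] - lumSc[onMask]) >= 70 / 255 - 1e-6)
})

test_that("distractors appear in the image but never in the ground truth", {
  spec <- deskSpec(nMosquitoes = 0, nDistractors = 4, noiseSigma = 0,
                   seed = 9)
  sc <- generateScene(spec)
  expect_equal(sceneCount(sc), 0L)
  expect_true(all(sceneMask(sc) == 0L))
  bg <- spec; bg@nDistractors <- 0L
  expect_gt(sum(abs(sceneImage(sc) - sceneImage(generateScene(bg)))), 0)
})

test_that("placement failure raises an informative error", {
  expect_error(generateScene(SceneSpec(width = 60, height = 60,
                                       nMosquitoes = 30,
                                       spriteSizeRange = c(14, 26))),
               "placement failed|too crowded")
})

test_that("count datasets cover the labels and pool >5 into the top bin", {
  scenes <- generateCountDataset(2, deskSpec(nDistractors = 2), seed = 31)
  expect_length(scenes, 12)
  counts <- vapply(scenes, sceneCount, integer(1))
  expect_equal(sceneLabels(scenes), pmin(counts, 5L))
  expect_equal(sort(unique(sceneLabels(scenes))), 0:5)
  # deterministic regeneration, including the over-5 draws
  again <- generateCountDataset(2, deskSpec(nDistractors = 2), seed = 31)
  expect_identical(lapply(scenes, sceneImage), lapply(again, sceneImage))
  # the top bin admits true counts above 5
  many <- generateCountDataset(8, deskSpec(), seed = 57, labels = 5L,
                               over5Fraction = 0.5)
  expect_true(any(vapply(many, sceneCount, integer(1)) > 5))
  expect_true(all(sceneLabels(many) == 5L))
})

test_that("patch datasets have the right shapes, labels and determinism", {
  pd <- generatePatchDataset(3, 5, seed = 13, baseSpec = deskSpec())
  expect_length(pd$patches, 8)
  expect_equal(pd$labels, rep(c(1L, 0L), c(3, 5)))
  for (p in pd$patches) expect_equal(dim(p), c(60, 60, 3))
  pd0 <- generatePatchDataset(0, 5, seed = 13, baseSpec = deskSpec())
  expect_true(all(pd0$labels == 0L))
  again <- generatePatchDataset(3, 5, seed = 13, baseSpec = deskSpec())
  expect_identical(pd$patches, again$patches)
})

test_that("scenes and datasets round-trip through disk", {
  sc <- generateScene(deskSpec(nMosquitoes = 2, seed = 3))
  d <- withr::local_tempdir()
  writeScene(sc, file.path(d, "s1"))
  back <- readScene(file.path(d, "s1"))
  expect_equal(sceneCount(back), 2L)
  expect_identical(sceneMask(back), sceneMask(sc))
  expect_identical(unname(sceneBoxes(back)), unname(sceneBoxes(sc)))
  expect_lt(max(abs(sceneImage(back) - sceneImage(sc))), 1 / 255)  # 8-bit
  scenes <- generateCountDataset(1, deskSpec(), seed = 77)
  man <- writeSceneDataset(scenes, file.path(d, "ds"))
  expect_equal(nrow(man), 6)
  back2 <- readSceneDataset(file.path(d, "ds"))
  expect_equal(sceneLabels(back2), sceneLabels(scenes))
})
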