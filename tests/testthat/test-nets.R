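# Architecture construction: layer-shape arithmetic against the reference
# tables, width scaling, parameter counting against an independent
# formula, and small-scale training behaviour.

shapeOf <- function(net, layer) {
  s <- layerShapes(net)
  unlist(s[s$name == layer, c("outC", "outH", "outW")], use.names = FALSE)
}

test_that("the full-scale FCN reproduces every reference layer shape", {
  net <- buildNetwork(NetSpec("fcn"))
  expect_equal(shapeOf(net, "conv1_2"), c(64, 500, 500))
  expect_equal(shapeOf(net, "pool1"), c(64, 250, 250))
  expect_equal(shapeOf(net, "conv2_2"), c(128, 250, 250))
  expect_equal(shapeOf(net, "pool2"), c(128, 125, 125))
  expect_equal(shapeOf(net, "conv3_3"), c(256, 125, 125))
  expect_equal(shapeOf(net, "pool3"), c(256, 63, 63))
  expect_equal(shapeOf(net, "conv4_3"), c(512, 63, 63))
  expect_equal(shapeOf(net, "pool4"), c(512, 32, 32))
  expect_equal(shapeOf(net, "conv5_3"), c(512, 32, 32))
  expect_equal(shapeOf(net, "pool5"), c(512, 16, 16))
  expect_equal(shapeOf(net, "fc6"), c(4096, 10, 10))
  expect_equal(shapeOf(net, "fc7"), c(4096, 10, 10))
  expect_equal(shapeOf(net, "score"), c(21, 10, 10))
  expect_equal(shapeOf(net, "score2"), c(21, 22, 22))
  expect_equal(shapeOf(net, "score_pool4"), c(21, 32, 32))
  expect_equal(shapeOf(net, "score_pool4c"), c(21, 22, 22))
  expect_equal(shapeOf(net, "score_fuse"), c(21, 22, 22))
  expect_equal(shapeOf(net, "bigscore"), c(21, 368, 368))
  expect_equal(shapeOf(net, "upscore"), c(21, 500, 500))
})

test_that("the full-scale AlexNet reproduces every reference layer shape", {
  net <- buildNetwork(NetSpec("alexnet_classifier"))
  expect_equal(shapeOf(net, "conv1"), c(96, 55, 55))
  expect_equal(shapeOf(net, "norm1"), c(96, 55, 55))
  expect_equal(shapeOf(net, "pool1"), c(96, 27, 27))
  expect_equal(shapeOf(net, "conv2"), c(256, 27, 27))
  expect_equal(shapeOf(net, "pool2"), c(256, 13, 13))
  expect_equal(shapeOf(net, "conv3"), c(384, 13, 13))
  expect_equal(shapeOf(net, "conv4"), c(384, 13, 13))
  expect_equal(shapeOf(net, "conv5"), c(256, 13, 13))
  expect_equal(shapeOf(net, "pool5"), c(256, 6, 6))
  expect_equal(shapeOf(net, "fc6"), c(4096, 1, 1))
  expect_equal(shapeOf(net, "fc7"), c(4096, 1, 1))
  expect_equal(shapeOf(net, "fc8"), c(1000, 1, 1))
})

test_that("width scaling multiplies channels and preserves spatial sizes", {
  net <- buildNetwork(NetSpec("alexnet_classifier", widthScale = 0.125,
                              numClasses = 2))
  expect_equal(shapeOf(net, "conv1"), c(ceiling(0.125 * 96), 55, 55))
  expect_equal(shapeOf(net, "conv2"), c(ceiling(0.125 * 256), 27, 27))
  expect_equal(shapeOf(net, "conv3"), c(ceiling(0.125 * 384), 13, 13))
  expect_equal(shapeOf(net, "conv5"), c(ceiling(0.125 * 256), 13, 13))
  expect_equal(shapeOf(net, "fc6"), c(ceiling(0.125 * 4096), 1, 1))
  expect_equal(shapeOf(net, "fc8"), c(2, 1, 1))
})

test_that("the regressor swaps the head for a scalar output", {
  net <- buildNetwork(NetSpec("alexnet_regressor", widthScale = 0.25))
  expect_equal(shapeOf(net, "fc8"), c(1, 1, 1))
  # otherwise identical to the classifier
  cl <- buildNetwork(NetSpec("alexnet_classifier", widthScale = 0.25))
  expect_equal(layerShapes(net)$outC[1:21], layerShapes(cl)$outC[1:21])
})

test_that("degenerate specifications are rejected", {
  expect_error(buildNetwork(NetSpec("alexnet_classifier", inputSize = 8)),
               "too small")
  expect_error(buildNetwork(NetSpec("fcn", inputSize = 64)), "too small")
  expect_error(NetSpec("unknown_family"), "arg")
})

test_that("parameter counts match a hand formula on a toy layer list", {
  # single 3x3 conv, 3 -> 4 channels, with bias: 3*4*9 + 4 = 112
  layers <- list(padcount:::.ly("c", "conv", "data", kernel = 3L,
                                stride = 1L, pad = 1L, groups = 1L,
                                out_channels = 4L))
  spec <- NetSpec("alexnet_classifier", inputSize = 227L)
  spec@inputChannels <- 3L
  shp <- padcount:::inferShapes(layers, spec)
  expect_equal(shp$params[shp$name == "c"], 112)
})

test_that("countParameters equals the independent layer-wise formula", {
  for (ws in c(1, 0.5, 0.125)) {
    expect_equal(countParameters(buildNetwork(
      NetSpec("alexnet_classifier", widthScale = ws, numClasses = 1000))),
      alexnetParamFormula(ws, 1000))
    expect_equal(countParameters(buildNetwork(
      NetSpec("alexnet_regressor", widthScale = ws))),
      alexnetParamFormula(ws, scalarHead = TRUE))
  }
  for (ws in c(1, 1 / 16)) {
    expect_equal(countParameters(buildNetwork(
      NetSpec("fcn", widthScale = ws))), fcnParamFormula(ws, 21))
  }
  expect_equal(countParameters(buildNetwork(
    NetSpec("fcn", widthScale = 1 / 32, numClasses = 2,
            inputSize = 320))), fcnParamFormula(1 / 32, 2))
})

test_that("a tiny classifier memorises a 10-patch dataset", {
  pd <- generatePatchDataset(5, 5, seed = 71,
                             baseSpec = SceneSpec(width = 320, height = 320,
                                                  spriteSizeRange = c(14, 26)))
  px <- lapply(pd$patches, padcount:::resizeArray, h = 75, w = 75)
  net <- buildNetwork(NetSpec("alexnet_classifier", widthScale = 0.125,
                              numClasses = 2, inputSize = 75))
  cfg <- TrainConfig(epochs = 60L, batchSize = 5L,
                     loss = "softmax_cross_entropy", seed = 5L)
  m <- trainNetwork(net, px, pd$labels, cfg)
  pr <- classifyPatches(m, pd$patches)
  expect_equal(as.integer(pr[, 2] > 0.5), pd$labels)
  expect_lt(tail(trainingCurves(m)$train_loss, 1),
            trainingCurves(m)$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  pd <- generatePatchDataset(4, 4, seed = 7,
                             baseSpec = SceneSpec(width = 320, height = 320,
                                                  spriteSizeRange = c(14, 26)))
  px <- lapply(pd$patches, padcount:::resizeArray, h = 75, w = 75)
  net <- buildNetwork(NetSpec("alexnet_classifier", widthScale = 0.125,
                              numClasses = 2, inputSize = 75))
  cfg <- TrainConfig(epochs = 3L, batchSize = 4L,
                     loss = "softmax_cross_entropy", seed = 42L)
  m1 <- trainNetwork(net, px, pd$labels, cfg)
  m2 <- trainNetwork(net, px, pd$labels, cfg)
  expect_identical(trainingCurves(m1), trainingCurves(m2))
  expect_identical(m1@network@weights$conv1$W, m2@network@weights$conv1$W)
})

test_that("label/loss mismatches are rejected", {
  net <- buildNetwork(NetSpec("alexnet_classifier", widthScale = 0.125,
                              numClasses = 2, inputSize = 75))
  cfg <- TrainConfig(loss = "softmax_cross_entropy")
  x <- list(array(0.5, c(75, 75, 3)))
  expect_error(trainNetwork(net, x, 7, cfg), "class labels")
  expect_error(trainNetwork(net, list(), integer(0), cfg), "empty")
  reg <- buildNetwork(NetSpec("alexnet_regressor", widthScale = 0.125,
                              inputSize = 75))
  expect_error(trainNetwork(reg, x, 1L, cfg), "mismatch")
})

test_that("a regressor on constant inputs converges to the label mean", {
  x <- replicate(12, array(0.5, c(75, 75, 3)), simplify = FALSE)
  y <- rep(c(2, 3, 4), 4)
  net <- buildNetwork(NetSpec("alexnet_regressor", widthScale = 0.125,
                              inputSize = 75))
  cfg <- TrainConfig(epochs = 120L, batchSize = 12L, loss = "euclidean",
                     seed = 3L, learningRate = 0.01, stepSize = 90L)
  m <- trainNetwork(net, x, y, cfg)
  pred <- as.numeric(forwardNetwork(m, x[[1]]))
  expect_equal(pred, mean(y), tolerance = 0.1)
})
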