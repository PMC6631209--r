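# Count-estimate semantics, score-map extraction arithmetic and the
# score-map-to-input conversion.

test_that("the clamped count mapping is total, monotone and idempotent", {
  expect_equal(countEstimate(2.4)@count, 2L)
  expect_equal(countEstimate(2.5)@count, 3L)   # round half away from zero
  expect_equal(countEstimate(-0.3)@count, 0L)
  e <- countEstimate(7.1)
  expect_equal(e@count, 5L)
  expect_true(e@exceededTopBin)
  expect_false(countEstimate(4.9)@exceededTopBin)
  raws <- seq(-3, 9, by = 0.1)
  cnts <- vapply(raws, function(r) countEstimate(r)@count, integer(1))
  expect_true(all(cnts >= 0 & cnts <= 5))             # total
  expect_true(all(diff(cnts) >= 0))                   # monotone
  expect_equal(vapply(cnts, function(c) countEstimate(c)@count,
                      integer(1)), cnts)              # idempotent
  expect_equal(cnts, pmin(5, pmax(0, sign(raws) * floor(abs(raws) + 0.5))))
})

test_that("score-map extraction follows the architecture arithmetic", {
  # hand-computed score_fuse sizes: input -> pool5 = in/32 (ceil chain),
  # fc6 = pool5 - 6, score2 = 2*fc6 + 2
  cases <- list(c(320, 10), c(256, 6), c(352, 12))
  for (cs in cases) {
    net <- initializeWeights(buildNetwork(
      NetSpec("fcn", widthScale = 1 / 32, numClasses = 2,
              inputSize = cs[1])), seed = 1)
    model <- new("TrainedModel", network = net, config = TrainConfig(),
                 curves = data.frame(), seed = 1L)
    x <- array(runif(cs[1]^2 * 3), c(cs[1], cs[1], 3))
    sm <- extractScoreMap(model, x)
    expect_equal(dim(scoreTensor(sm)), c(cs[2], cs[2], 2))
    expect_identical(scoreTensor(sm),
                     scoreTensor(extractScoreMap(model, x)))
    expect_error(extractScoreMap(model, array(0, c(64, 64, 3))),
                 "input size")
  }
  # full-scale reference arithmetic without materialising weights
  shp <- layerShapes(buildNetwork(NetSpec("fcn")))
  expect_equal(unlist(shp[shp$name == "score_fuse",
                          c("outC", "outH", "outW")], use.names = FALSE),
               c(21, 22, 22))
})

test_that("a constant-zero score map renders a uniform 1/C plane", {
  z <- array(0, c(22, 22, 21))
  sm <- new("ScoreMap", tensor = z, sourceLayer = "score_fuse",
            sceneRef = "")
  out <- scoremapToInput(sm)
  expect_equal(dim(out), c(227, 227, 3))
  expect_true(all(abs(out - 1 / 21) < 1e-12))
})

test_that("resizing preserves the location of a delta peak within a pixel", {
  z <- array(0, c(10, 10, 2))
  z[3, 7, 2] <- 8               # strong mosquito logit at cell (3, 7)
  sm <- new("ScoreMap", tensor = z, sourceLayer = "score_fuse",
            sceneRef = "")
  out <- scoremapToInput(sm, size = 75)
  peak <- which(out[, , 1] == max(out[, , 1]), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak[1]), (3 - 0.5) * 7.5, tolerance = 0.15)
  expect_equal(unname(peak[2]), (7 - 0.5) * 7.5, tolerance = 0.15)
})

test_that("the channel-stack mode keeps all score channels", {
  z <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  sm <- new("ScoreMap", tensor = z, sourceLayer = "score_fuse",
            sceneRef = "")
  out <- scoremapToInput(sm, mode = "channel_stack", size = 40)
  expect_equal(dim(out), c(40, 40, 2))
})

test_that("unclamped labels are rejected by the regressor trainer", {
  sm <- list(new("ScoreMap", tensor = array(0, c(10, 10, 2)),
                 sourceLayer = "score_fuse", sceneRef = ""))
  expect_error(trainCountRegressor(sm, 7, TrainConfig(loss = "euclidean")),
               "clamped")
  expect_error(trainCountRegressor(sm, 3, TrainConfig()),
               "euclidean")
})
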