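# The compiled engine against naive R oracles: convolution (stride, pad,
# groups), transposed convolution, pooling arithmetic, and forward
# determinism.

test_that("conv forward matches a naive R convolution", {
  set.seed(31)
  spec <- NetSpec("alexnet_classifier", numClasses = 2, inputSize = 75)
  cases <- list(list(k = 3, s = 1, p = 1, g = 1, cin = 3, cout = 4, n = 9),
                list(k = 5, s = 2, p = 2, g = 2, cin = 4, cout = 6, n = 11),
                list(k = 11, s = 4, p = 0, g = 1, cin = 3, cout = 2, n = 23))
  for (cs in cases) {
    layers <- list(padcount:::.ly("c", "conv", "data",
                                  kernel = as.integer(cs$k),
                                  stride = as.integer(cs$s),
                                  pad = as.integer(cs$p),
                                  groups = as.integer(cs$g),
                                  out_channels = as.integer(cs$cout)))
    W <- array(rnorm(cs$k^2 * (cs$cin / cs$g) * cs$cout, sd = 0.3),
               c(cs$k, cs$k, cs$cin / cs$g, cs$cout))
    b <- rnorm(cs$cout, sd = 0.1)
    x <- array(runif(cs$n^2 * cs$cin), c(cs$n, cs$n, cs$cin))
    out <- padcount:::.cnn_forward(layers, list(c = list(W = W, b = b)),
                                   list(x), "", 4L)[[1]]
    expect_equal(out, naiveConvForward(x, W, b, cs$s, cs$p, cs$g),
                 tolerance = 1e-5)
  }
})

test_that("deconv forward matches a naive transposed convolution", {
  set.seed(17)
  for (cs in list(list(k = 4, s = 2, cin = 3, cout = 2, n = 5),
                  list(k = 32, s = 16, cin = 2, cout = 2, n = 4))) {
    layers <- list(
      padcount:::.ly("c", "conv", "data", kernel = 1L, stride = 1L,
                     pad = 0L, groups = 1L,
                     out_channels = as.integer(cs$cin)),
      padcount:::.ly("d", "deconv", "c", kernel = as.integer(cs$k),
                     stride = as.integer(cs$s),
                     out_channels = as.integer(cs$cout), bias = FALSE))
    # identity 1x1 conv so the deconv sees a known input
    Wc <- array(0, c(1, 1, cs$cin, cs$cin))
    for (i in seq_len(cs$cin)) Wc[1, 1, i, i] <- 1
    Wd <- array(rnorm(cs$k^2 * cs$cout * cs$cin, sd = 0.2),
                c(cs$k, cs$k, cs$cout, cs$cin))
    x <- array(runif(cs$n^2 * cs$cin), c(cs$n, cs$n, cs$cin))
    out <- padcount:::.cnn_forward(
      layers, list(c = list(W = Wc, b = numeric(cs$cin)),
                   d = list(W = Wd)), list(x), "", 4L)[[1]]
    expect_equal(out, naiveDeconvForward(2 * (x - 0.5), Wd, cs$s),
                 tolerance = 1e-5)
  }
})

test_that("ceil-mode pooling follows the reference arithmetic", {
  # 500 -> 250 -> 125 -> 63 -> 32 -> 16 (2x2, stride 2)
  sizes <- c(500, 250, 125, 63, 32)
  for (i in seq_along(sizes))
    expect_equal(padcount:::poolOutDim(sizes[i], 2L, 2L),
                 c(250, 125, 63, 32, 16)[i])
  # 227-input chain: 55 -> 27, 27 -> 13, 13 -> 6 (3x3, stride 2)
  expect_equal(padcount:::poolOutDim(55L, 3L, 2L), 27L)
  expect_equal(padcount:::poolOutDim(27L, 3L, 2L), 13L)
  expect_equal(padcount:::poolOutDim(13L, 3L, 2L), 6L)
})

test_that("forward passes are bit-stable for fixed weights and input", {
  net <- initializeWeights(buildNetwork(
    NetSpec("fcn", widthScale = 1 / 32, numClasses = 2, inputSize = 256)),
    seed = 2)
  x <- array(runif(256 * 256 * 3), c(256, 256, 3))
  a <- forwardNetwork(net, x, upto = "score_fuse")
  b <- forwardNetwork(net, x, upto = "score_fuse")
  expect_identical(a, b)
  expect_error(forwardNetwork(net, x, upto = "no_such_layer"), "not found")
})
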