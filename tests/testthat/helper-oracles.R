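# Independent oracles used across tests. These deliberately re-derive
# quantities with naive algorithms rather than calling the implementation.

# connected components of a 0/1 matrix by breadth-first search
bfsComponents <- function(mask, connectivity = 4) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  for (start in which(mask != 0 & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1L) %% h + 1L; c <- (q - 1L) %/% h + 1L
      for (k in seq_len(nrow(nbr))) {
        rr <- r + nbr[k, 1]; cc <- c + nbr[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] != 0 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- c(queue, (cc - 1L) * h + rr)
        }
      }
    }
  }
  lab
}

nComponents <- function(mask, connectivity = 4) {
  max(bfsComponents(mask, connectivity))
}

# naive direct convolution (valid padding handled explicitly), matching the
# engine's conventions: input (h, w, cin), W (k, k, cin/groups, cout),
# inputs centred to [-1, 1] by the engine
naiveConvForward <- function(x, W, b, stride = 1, pad = 0, groups = 1) {
  x <- 2 * (x - 0.5)
  k <- dim(W)[1]; cin <- dim(x)[3]; cout <- dim(W)[4]
  cpg <- cin / groups; opg <- cout / groups
  oh <- (dim(x)[1] + 2 * pad - k) %/% stride + 1
  ow <- (dim(x)[2] + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(dim(x)[1] + 2 * pad, dim(x)[2] + 2 * pad, cin))
  xp[pad + seq_len(dim(x)[1]), pad + seq_len(dim(x)[2]), ] <- x
  out <- array(0, c(oh, ow, cout))
  for (o in seq_len(cout)) {
    g <- ceiling(o / opg)
    chans <- ((g - 1) * cpg + 1):(g * cpg)
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- b[o]
      for (ci in seq_along(chans))
        acc <- acc + sum(xp[(i - 1) * stride + 1:k,
                            (j - 1) * stride + 1:k, chans[ci]] *
                           W[, , ci, o])
      out[i, j, o] <- acc
    }
  }
  out
}

# naive transposed convolution, W (k, k, cout, cin), bias-free
naiveDeconvForward <- function(x, W, stride) {
  k <- dim(W)[1]; cout <- dim(W)[3]; cin <- dim(x)[3]
  oh <- (dim(x)[1] - 1) * stride + k
  ow <- (dim(x)[2] - 1) * stride + k
  out <- array(0, c(oh, ow, cout))
  for (o in seq_len(cout)) {
    for (i in seq_len(dim(x)[1])) for (j in seq_len(dim(x)[2])) {
      ri <- (i - 1) * stride + 1:k
      cj <- (j - 1) * stride + 1:k
      for (ci in seq_len(cin))
        out[ri, cj, o] <- out[ri, cj, o] + x[i, j, ci] * W[, , o, ci]
    }
  }
  out
}

# brute-force parameter formula from an architecture description
alexnetParamFormula <- function(ws = 1, numClasses = 1000, scalarHead = FALSE) {
  s <- function(c, g = 1) as.integer(ceiling(ceiling(c * ws) / g) * g)
  conv <- function(k, cin, cout, g = 1) k^2 * (cin / g) * cout + cout
  fc <- function(nin, nout) nin * nout + nout
  c1 <- s(96); c2 <- s(256, 2); c3 <- s(384); c4 <- s(384, 2); c5 <- s(256, 2)
  f6 <- s(4096); f7 <- s(4096)
  head <- if (scalarHead) 1 else numClasses
  # pool5 spatial size for the 227 reference input is 6x6
  conv(11, 3, c1) + conv(5, c1, c2, 2) + conv(3, c2, c3) +
    conv(3, c3, c4, 2) + conv(3, c4, c5, 2) +
    fc(c5 * 36, f6) + fc(f6, f7) + fc(f7, head)
}

fcnParamFormula <- function(ws = 1, nc = 21) {
  s <- function(c) as.integer(ceiling(c * ws))
  conv <- function(k, cin, cout) k^2 * cin * cout + cout
  ch <- sapply(c(64, 128, 256, 512, 512), s)
  p <- conv(3, 3, ch[1]) + conv(3, ch[1], ch[1]) +
    conv(3, ch[1], ch[2]) + conv(3, ch[2], ch[2]) +
    conv(3, ch[2], ch[3]) + 2 * conv(3, ch[3], ch[3]) +
    conv(3, ch[3], ch[4]) + 2 * conv(3, ch[4], ch[4]) +
    3 * conv(3, ch[4], ch[5])
  f6 <- s(4096); f7 <- s(4096)
  p <- p + conv(7, ch[5], f6) + conv(1, f6, f7) + conv(1, f7, nc)
  # deconvs bias-free; score_pool4 1x1 with bias
  p + 4^2 * nc * nc + conv(1, ch[4], nc) + 32^2 * nc * nc
}

rmseOf <- function(a, b) sqrt(mean((a - b)^2))

# a small trained patch classifier, trained once per session and memoised
.testCache <- new.env()
smallClassifier <- function() {
  if (!is.null(.testCache$clf)) return(.testCache$clf)
  spec <- SceneSpec(width = 320, height = 320, spriteSizeRange = c(14, 26))
  pd <- generatePatchDataset(250, 250, seed = 404, baseSpec = spec)
  px <- lapply(pd$patches, padcount:::resizeArray, h = 75, w = 75)
  cfgc <- TrainConfig(epochs = 10L, batchSize = 32L,
                      loss = "softmax_cross_entropy", seed = 11L)
  net <- buildNetwork(NetSpec("alexnet_classifier", widthScale = 0.125,
                              numClasses = 2L, inputSize = 75L))
  .testCache$clf <- trainNetwork(net, px, pd$labels, cfgc,
                                 holdout = "fraction")
  .testCache$clf
}
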