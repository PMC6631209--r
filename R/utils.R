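# Internal helpers: seeded evaluation, luma conversion, rasterisation.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generation never disturbs user-level randomness.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ITU-R BT.601 luma of an H x W x 3 array, in [0, 1]
luma <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# round half away from zero
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a stream of sub-seeds from a master seed, staying inside the
# 32-bit integer range
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 4-connected rasterisation of the segment (r0,c0)-(r1,c1); returns a
# 2-column matrix of integer (row, col) cells. Consecutive cells share an
# edge, so strokes stay connected under 4-connectivity.
line4 <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- dr + dc
  out <- matrix(0L, n + 1L, 2L)
  r <- r0; c <- c0; err <- dr - dc
  out[1L, ] <- c(r, c)
  if (n > 0) for (i in seq_len(n)) {
    # step in the direction that keeps the path closest to the ideal line
    if (err > 0 || (err == 0 && dr >= dc)) { r <- r + sr; err <- err - 2 * dc }
    else { c <- c + sc; err <- err + 2 * dr }
    out[i + 1L, ] <- c(r, c)
  }
  out
}

# cells of a filled, rotated ellipse: centre (r,c), semi-axes (a along the
# orientation phi, b across), returned as (row, col) integer matrix
ellipseCells <- function(r, c, a, b, phi) {
  ext <- ceiling(max(a, b)) + 1L
  rr <- seq(floor(r - ext), ceiling(r + ext))
  cc <- seq(floor(c - ext), ceiling(c + ext))
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - r; dc <- g$col - c
  u <- dc * cos(phi) + dr * sin(phi)
  v <- -dc * sin(phi) + dr * cos(phi)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# clip (row, col) cell lists to an H x W raster (1-based)
clipCells <- function(cells, h, w) {
  keep <- cells[, 1] >= 1 & cells[, 1] <= h & cells[, 2] >= 1 &
    cells[, 2] <= w
  cells[keep, , drop = FALSE]
}

# paint `value` at cells into a single-channel matrix
paintCells <- function(mat, cells, value) {
  if (nrow(cells)) mat[cbind(cells[, 1], cells[, 2])] <- value
  mat
}

# bounding box (0-based half-open x0,y0,x1,y1) of a set of (row,col) cells
cellsBox <- function(cells) {
  c(x0 = min(cells[, 2]) - 1L, y0 = min(cells[, 1]) - 1L,
    x1 = max(cells[, 2]), y1 = max(cells[, 1]))
}

# resize an H x W x C array (or matrix) bilinearly via EBImage; EBImage uses
# (x, y) storage, our arrays are (row, col), so transpose around the call
resizeArray <- function(img, h, w) {
  if (is.matrix(img)) {
    t(EBImage::resize(EBImage::Image(t(img)), w = w, h = h,
                      filter = "bilinear")@.Data)
  } else {
    r <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = w, h = h, filter = "bilinear")
    aperm(r@.Data, c(2, 1, 3))
  }
}
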