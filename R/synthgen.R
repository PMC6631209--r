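# Synthetic observation-pad scenes with exact ground truth.
#
# A scene is a near-white pad with a mild linear illumination ramp and
# Gaussian sensor noise. Mosquito sprites are dark elongated ellipse bodies
# with 4-6 one-pixel leg strokes and faint wings; distractors are round
# specks, irregular blotches or elongated smudges that are equally dark but
# carry no leg/wing structure. Only mosquito pixels enter the mask, the
# boxes and the count.

# --- sprite renderers (local coordinates around (0, 0)) --------------------

# returns list(cells = mask cells, values, deco = list(cells, values, blend))
renderMosquitoSprite <- function(L) {
  a <- runif(1, 0.26, 0.34) * L          # body semi-major
  b <- runif(1, 0.09, 0.13) * L          # body semi-minor
  phi <- runif(1, 0, pi)
  body <- ellipseCells(0, 0, a, b, phi)
  nLegs <- sample(4:6, 1)
  legCells <- NULL
  side <- rep(c(1, -1), length.out = nLegs)
  for (k in seq_len(nLegs)) {
    # attachment point along the body, slightly inside the outline
    t <- runif(1, -0.7, 0.7)
    ar <- t * a * 0.9
    att <- c(ar * sin(phi) + side[k] * b * 0.6 * cos(phi),
             ar * cos(phi) - side[k] * b * 0.6 * sin(phi))
    # two-segment leg bending away from the body
    base <- atan2(side[k] * cos(phi), -side[k] * sin(phi))
    a1 <- base + runif(1, -0.6, 0.6)
    len1 <- runif(1, 0.14, 0.22) * L
    joint <- att + len1 * c(sin(a1), cos(a1))
    a2 <- a1 + runif(1, -0.8, 0.8)
    len2 <- runif(1, 0.12, 0.2) * L
    tip <- joint + len2 * c(sin(a2), cos(a2))
    # keep the tip within the nominal footprint
    rad <- sqrt(sum(tip^2))
    if (rad > L / 2 - 1) tip <- tip * ((L / 2 - 1) / rad)
    legCells <- rbind(legCells,
                      line4(att[1], att[2], joint[1], joint[2]),
                      line4(joint[1], joint[2], tip[1], tip[2]))
  }
  wings <- NULL
  if (runif(1) < 0.85) {
    for (s in c(-1, 1)) {
      wc <- c(s * b * 1.3 * cos(phi) - 0.15 * a * sin(phi),
              -s * b * 1.3 * sin(phi) - 0.15 * a * cos(phi))
      wings <- rbind(wings, ellipseCells(wc[1], wc[2], 0.55 * a, 0.35 * b + 1,
                                         phi + s * runif(1, 0.15, 0.45)))
    }
  }
  list(body = body, legs = legCells, wings = wings)
}

renderDistractorSprite <- function(type, L) {
  if (type == "speck") {
    r <- runif(1, 0.18, 0.30) * L
    ellipseCells(0, 0, r, r * runif(1, 0.85, 1), runif(1, 0, pi))
  } else if (type == "blotch") {
    # irregular radial outline: smooth noise on top of a base radius
    r0 <- runif(1, 0.16, 0.28) * L
    k <- runif(2, -0.35, 0.35)
    ph <- runif(2, 0, 2 * pi)
    ext <- ceiling(r0 * 1.5) + 1
    g <- expand.grid(row = -ext:ext, col = -ext:ext)
    th <- atan2(g$row, g$col)
    rad <- r0 * (1 + k[1] * sin(2 * th + ph[1]) + k[2] * sin(3 * th + ph[2]))
    keep <- sqrt(g$row^2 + g$col^2) <= rad
    as.matrix(g[keep, , drop = FALSE])
  } else {  # smudge: elongated body-like blob without appendages
    a <- runif(1, 0.26, 0.36) * L
    b <- runif(1, 0.10, 0.17) * L
    ellipseCells(0, 0, a, b, runif(1, 0, pi))
  }
}

# --- scene assembly --------------------------------------------------------

# sample a non-overlapping position for a w x h bounding box; boxes are kept
# `gap` pixels apart. Returns centre (row, col) or NULL.
placeBox <- function(extR, extC, placed, H, W, margin, gap = 3,
                     tries = 200L) {
  loR <- margin + extR / 2 + 1; hiR <- H - margin - extR / 2
  loC <- margin + extC / 2 + 1; hiC <- W - margin - extC / 2
  if (loR >= hiR || loC >= hiC) return(NULL)
  for (i in seq_len(tries)) {
    r <- runif(1, loR, hiR); c <- runif(1, loC, hiC)
    box <- c(r - extR / 2 - gap, c - extC / 2 - gap,
             r + extR / 2 + gap, c + extC / 2 + gap)
    ok <- TRUE
    if (length(placed))
      for (p in placed)
        if (box[1] < p[3] && p[1] < box[3] && box[2] < p[4] &&
            p[2] < box[4]) { ok <- FALSE; break }
    if (ok) return(c(r, c))
  }
  NULL
}

#' Generate one synthetic observation-pad scene
#'
#' Renders the scene described by a \linkS4class{SceneSpec} and returns it
#' together with exact ground truth (mosquito count, bounding boxes and a
#' pixel mask). Generation is bit-reproducible: the same spec (including its
#' seed) always yields the identical scene. All mask-positive pixels are at
#' least \code{minContrast} gray values darker than the local noise-free
#' background, so a dark-object threshold can always separate them;
#' distractors are rendered into the image but never enter the ground truth.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return A \linkS4class{PadScene}.
#' @examples
#' sc <- generateScene(SceneSpec(nMosquitoes = 3, nDistractors = 2,
#'                               width = 200, height = 200,
#'                               spriteSizeRange = c(16, 30), seed = 7))
#' sceneCount(sc)
#' @export
generateScene <- function(spec) {
  validObject(spec)
  H <- spec@height; W <- spec@width
  withSeed(spec@seed, {
    b0 <- spec@backgroundLevel / 255
    amp <- spec@illuminationGradient
    theta <- runif(1, 0, 2 * pi)
    proj <- outer(seq_len(H) / H, rep(sin(theta), W)) +
      outer(rep(cos(theta), H), seq_len(W) / W)
    proj <- (proj - min(proj)) / max(1e-9, diff(range(proj)))
    shade <- 1 - amp * proj
    tint <- c(1, 0.995, 0.985)           # faintly warm pad illumination
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- b0 * shade * tint[ch]
    lumBg <- luma(img)                   # noise-free background luminance
    minC <- spec@minContrast / 255

    mask <- matrix(0L, H, W)
    boxes <- matrix(0L, 0, 4,
                    dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
    placed <- list()

    paintSprite <- function(cells, value) {
      for (ch in 1:3) {
        m <- img[, , ch]
        m[cbind(cells[, 1], cells[, 2])] <- value
        img[, , ch] <<- m
      }
    }

    # ---- mosquitoes
    for (k in seq_len(spec@nMosquitoes)) {
      sp <- NULL
      for (try in 1:50) {
        L <- runif(1, spec@spriteSizeRange[1], spec@spriteSizeRange[2])
        cand <- renderMosquitoSprite(L)
        cells <- rbind(cand$body, cand$legs)
        ext <- c(diff(range(cells[, 1])), diff(range(cells[, 2]))) + 1
        if (max(ext) >= spec@spriteSizeRange[1] &&
            max(ext) <= spec@spriteSizeRange[2]) { sp <- cand; break }
      }
      if (is.null(sp))
        stop("could not render a sprite within the size range after ",
             "50 attempts")
      cells <- rbind(sp$body, sp$legs)
      extR <- diff(range(cells[, 1])) + 1
      extC <- diff(range(cells[, 2])) + 1
      pos <- placeBox(extR, extC, placed, H, W, spec@placementMargin)
      if (is.null(pos))
        stop("sprite placement failed after 200 retries: image ",
             W, "x", H, " too crowded for ", spec@nMosquitoes,
             " mosquitoes + ", spec@nDistractors, " distractors")
      shift <- function(cl) {
        cl[, 1] <- round(cl[, 1] + pos[1]); cl[, 2] <- round(cl[, 2] + pos[2])
        clipCells(cl, H, W)
      }
      body <- shift(sp$body); legs <- shift(sp$legs)
      allc <- unique(rbind(body, legs))
      # darkest admissible value given the local background
      cap <- min(lumBg[cbind(allc[, 1], allc[, 2])]) - minC - 2 / 255
      v <- min(runif(1, 0.06, 0.28), cap)
      if (!is.null(sp$wings)) {
        wc <- shift(sp$wings)
        wc <- wc[!((wc[, 1] + (wc[, 2] - 1) * H) %in%
                     (allc[, 1] + (allc[, 2] - 1) * H)), , drop = FALSE]
        if (nrow(wc)) {
          al <- 0.22
          for (ch in 1:3) {
            m <- img[, , ch]
            idx <- cbind(wc[, 1], wc[, 2])
            m[idx] <- (1 - al) * m[idx] + al * v
            img[, , ch] <- m
          }
        }
      }
      paintSprite(body, v)
      paintSprite(legs, min(v + 0.08, cap))
      mask <- paintCells(mask, allc, 1L)
      boxes <- rbind(boxes, cellsBox(allc))
      bb <- cellsBox(allc)
      placed[[length(placed) + 1]] <- c(bb["y0"] + 1, bb["x0"] + 1,
                                        bb["y1"], bb["x1"])
    }

    # ---- distractors (image only, never ground truth)
    for (k in seq_len(spec@nDistractors)) {
      type <- sample(c("speck", "blotch", "smudge"), 1,
                     prob = c(0.4, 0.3, 0.3))
      L <- runif(1, mean(spec@spriteSizeRange) * 0.8,
                 mean(spec@spriteSizeRange) * 1.2)
      cells <- renderDistractorSprite(type, L)
      extR <- diff(range(cells[, 1])) + 1
      extC <- diff(range(cells[, 2])) + 1
      pos <- placeBox(extR, extC, placed, H, W, spec@placementMargin)
      if (is.null(pos))
        stop("distractor placement failed after 200 retries: image too ",
             "crowded")
      cells[, 1] <- round(cells[, 1] + pos[1])
      cells[, 2] <- round(cells[, 2] + pos[2])
      cells <- clipCells(cells, H, W)
      cap <- min(lumBg[cbind(cells[, 1], cells[, 2])]) - 60 / 255
      v <- min(runif(1, 0.08, 0.35), cap)
      paintSprite(cells, v)
      bb <- cellsBox(cells)
      placed[[length(placed) + 1]] <- c(bb["y0"] + 1, bb["x0"] + 1,
                                        bb["y1"], bb["x1"])
    }

    # ---- sensor noise
    if (spec@noiseSigma > 0)
      img <- img + array(rnorm(length(img), 0, spec@noiseSigma / 255),
                         dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
    rownames(boxes) <- NULL
    storage.mode(boxes) <- "integer"
    new("PadScene", image = img, count = spec@nMosquitoes, boxes = boxes,
        mask = mask, spec = spec)
  })
}

#' Generate a count-labelled scene dataset
#'
#' Produces \code{perLabel} scenes for every label in \code{labels}
#' (default 0--5). Scenes assigned the top label 5 contain, with probability
#' \code{over5Fraction}, a true count of 6--8 mosquitoes, mirroring the
#' pooling of ">5" observations into the top bin. The per-scene distractor
#' count varies by up to 2 around the base spec's value. Everything is
#' deterministic under \code{seed}.
#'
#' @param perLabel scenes per label (>= 1).
#' @param baseSpec template \linkS4class{SceneSpec} (size, illumination,
#'   noise, sprite sizes, distractor load).
#' @param seed integer seed for the whole dataset.
#' @param labels integer label bins (default \code{0:5}).
#' @param over5Fraction fraction of top-bin scenes whose true count exceeds
#'   the label.
#' @return list of \linkS4class{PadScene}; use \code{\link{sceneLabels}} for
#'   the clamped labels.
#' @export
generateCountDataset <- function(perLabel, baseSpec = SceneSpec(),
                                 seed = 1L, labels = 0:5,
                                 over5Fraction = 1 / 3) {
  stopifnot(perLabel >= 1)
  top <- max(labels)
  plan <- withSeed(seed, {
    n <- perLabel * length(labels)
    data.frame(
      label = rep(labels, each = perLabel),
      count = unlist(lapply(rep(labels, each = perLabel), function(l) {
        if (l == top && runif(1) < over5Fraction) sample((top + 1):(top + 3), 1)
        else l
      })),
      nd = pmax(0L, baseSpec@nDistractors +
                  sample(-2:2, n, replace = TRUE)),
      seed = subSeeds(seed + 1L, n))
  })
  lapply(seq_len(nrow(plan)), function(i) {
    sp <- baseSpec
    sp@nMosquitoes <- as.integer(plan$count[i])
    sp@nDistractors <- as.integer(plan$nd[i])
    sp@seed <- as.integer(plan$seed[i])
    generateScene(sp)
  })
}

#' Clamped labels of a scene list
#'
#' @param scenes list of \linkS4class{PadScene}.
#' @param top top label bin (default 5); true counts above it are clamped.
#' @return integer vector of labels.
#' @export
sceneLabels <- function(scenes, top = 5L) {
  pmin(vapply(scenes, sceneCount, integer(1)), as.integer(top))
}

#' Generate a labelled 60x60 patch dataset
#'
#' Mosquito patches contain one centred sprite; non-mosquito patches contain
#' a distractor (70\%) or plain background (30\%). Patch backgrounds carry
#' the same illumination and noise model as full scenes, so patches look
#' like crops from them.
#'
#' @param nMosquito,nNon patch counts per class.
#' @param seed integer seed.
#' @param baseSpec appearance template \linkS4class{SceneSpec}.
#' @param patchSize patch side in pixels (default 60).
#' @return list with \code{patches} (list of \code{patchSize x patchSize x 3}
#'   arrays) and \code{labels} (integer, 1 = mosquito, 0 = non-mosquito).
#' @export
generatePatchDataset <- function(nMosquito, nNon, seed = 1L,
                                 baseSpec = SceneSpec(), patchSize = 60L) {
  stopifnot(nMosquito >= 0, nNon >= 0)
  n <- nMosquito + nNon
  labels <- rep(c(1L, 0L), c(nMosquito, nNon))
  seeds <- subSeeds(seed, max(1L, n))
  maxL <- min(baseSpec@spriteSizeRange[2], patchSize - 12)
  minL <- min(baseSpec@spriteSizeRange[1], maxL - 2)
  patches <- lapply(seq_len(n), function(i) {
    withSeed(seeds[i], {
      b0 <- baseSpec@backgroundLevel / 255
      shade <- 1 - baseSpec@illuminationGradient *
        matrix(runif(1), patchSize, patchSize) # local patch of a slow ramp
      tint <- c(1, 0.995, 0.985)
      img <- array(0, c(patchSize, patchSize, 3))
      for (ch in 1:3) img[, , ch] <- b0 * shade * tint[ch]
      lumBg <- luma(img)
      centre <- patchSize / 2 + runif(2, -3, 3)
      paint <- function(cells, value) {
        cells <- clipCells(cells, patchSize, patchSize)
        for (ch in 1:3) {
          m <- img[, , ch]
          m[cbind(cells[, 1], cells[, 2])] <- value
          img[, , ch] <<- m
        }
        cells
      }
      if (labels[i] == 1L) {
        L <- runif(1, minL, maxL)
        sp <- renderMosquitoSprite(L)
        off <- function(cl) {
          cl[, 1] <- round(cl[, 1] + centre[1])
          cl[, 2] <- round(cl[, 2] + centre[2]); cl
        }
        allc <- clipCells(off(rbind(sp$body, sp$legs)), patchSize, patchSize)
        cap <- min(lumBg[cbind(allc[, 1], allc[, 2])]) -
          baseSpec@minContrast / 255 - 2 / 255
        v <- min(runif(1, 0.06, 0.28), cap)
        if (!is.null(sp$wings)) {
          wc <- clipCells(off(sp$wings), patchSize, patchSize)
          if (nrow(wc)) {
            for (ch in 1:3) {
              m <- img[, , ch]
              idx <- cbind(wc[, 1], wc[, 2])
              m[idx] <- 0.78 * m[idx] + 0.22 * v
              img[, , ch] <- m
            }
          }
        }
        paint(off(sp$body), v)
        paint(off(sp$legs), min(v + 0.08, cap))
      } else if (runif(1) < 0.7) {
        type <- sample(c("speck", "blotch", "smudge"), 1,
                       prob = c(0.4, 0.3, 0.3))
        L <- runif(1, mean(baseSpec@spriteSizeRange) * 0.8,
                   min(mean(baseSpec@spriteSizeRange) * 1.2, maxL))
        cells <- renderDistractorSprite(type, L)
        cells[, 1] <- round(cells[, 1] + centre[1])
        cells[, 2] <- round(cells[, 2] + centre[2])
        cells <- clipCells(cells, patchSize, patchSize)
        cap <- min(lumBg[cbind(cells[, 1], cells[, 2])]) - 60 / 255
        paint(cells, min(runif(1, 0.08, 0.35), cap))
      }  # else: plain background patch
      if (baseSpec@noiseSigma > 0)
        img <- img + array(rnorm(length(img), 0, baseSpec@noiseSigma / 255),
                           dim(img))
      img[img < 0] <- 0; img[img > 1] <- 1
      img
    })
  })
  list(patches = patches, labels = labels)
}
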