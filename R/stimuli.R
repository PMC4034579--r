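#' @include geometry.R
NULL

## ---------------------------------------------------------------------------
## Seeded generators for pop-out psychophysical stimulus arrays and for
## center-biased synthetic fixations, so every pipeline stage and metric is
## testable with no external data.
## ---------------------------------------------------------------------------

PATTERN_KINDS <- c("color_singleton", "orientation_singleton", "conjunction",
                   "curvature", "intersection", "symmetry", "size_singleton",
                   "dense_texture")

#' Specification of a pop-out stimulus array
#'
#' Describes a grid of distractor items with exactly one target item that
#' differs in a single distinguishing attribute (color hue, bar orientation,
#' feature conjunction, curvature, junction type, axial symmetry, or size),
#' plus a dense-texture segmentation variant.  Item geometry defaults: bars
#' of 3:1 aspect at half the cell size, red target among green distractors,
#' 15% positional jitter.
#'
#' @param kind one of `"color_singleton"`, `"orientation_singleton"`,
#'   `"conjunction"`, `"curvature"`, `"intersection"`, `"symmetry"`,
#'   `"size_singleton"`, `"dense_texture"`.
#' @param grid `c(rows, cols)` of items (default 6 x 6).
#' @param imageSize canvas side in pixels (square, default 256).
#' @param jitter positional jitter as a fraction of the cell size.
#' @param seed integer seed; the layout is deterministic per seed.
#' @return A list with class `"pattern_spec"`.
#' @export
patternSpec <- function(kind = PATTERN_KINDS, grid = c(6L, 6L),
                        imageSize = 256L, jitter = 0.15, seed = 0L) {
  kind <- match.arg(kind)
  if (length(grid) == 1L) grid <- c(grid, grid)
  stopifnot(all(grid >= 2L), imageSize >= 16L, jitter >= 0, jitter < 0.5)
  if (imageSize / max(grid) < 8)
    stop("infeasible geometry: cells smaller than 8 px")
  structure(list(kind = kind, grid = as.integer(grid),
                 imageSize = as.integer(imageSize), jitter = jitter,
                 seed = as.integer(seed)),
            class = "pattern_spec")
}

## paint `color` over `mask` pixels of the window rows/cols of canvas planes
paintMask <- function(planes, rows, cols, mask, color) {
  for (ch in 1:3) {
    plane <- planes[[ch]]
    sub <- plane[rows, cols, drop = FALSE]
    sub[mask] <- color[ch]
    plane[rows, cols] <- sub
    planes[[ch]] <- plane
  }
  planes
}

## Membership masks on a local (y, x) window grid, all vectorized.
## theta: orientation from vertical, radians.
shapeMask <- function(ys, xs, cy, cx, len, wid, theta, shape) {
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * cos(theta) + dx * sin(theta)     # along the bar
  v <- -dy * sin(theta) + dx * cos(theta)    # across the bar
  switch(shape,
    bar = abs(u) <= len / 2 & abs(v) <= wid / 2,
    cross = (abs(u) <= len / 2 & abs(v) <= wid / 2) |
            (abs(v) <= len / 2 & abs(u) <= wid / 2),
    arc = {
      r <- sqrt(dy^2 + dx^2)
      ang <- atan2(dx, -dy)                  # 0 = up, clockwise positive
      abs(r - len / 3) <= wid / 2 & abs(ang) <= 75 * pi / 180
    },
    ell = {                                  # asymmetric L: bar + right foot
      (abs(u) <= len / 2 & abs(v) <= wid / 2) |
        (u >= len / 2 - wid & u <= len / 2 &
           v >= 0 & v <= len / 2)
    },
    tee = {                                  # axially symmetric T
      (abs(u) <= len / 2 & abs(v) <= wid / 2) |
        (u >= -len / 2 & u <= -len / 2 + wid & abs(v) <= len / 2)
    },
    stop("unknown shape ", shape))
}

## draw one item; returns updated planes
drawItem <- function(planes, H, W, cy, cx, len, wid, theta, shape, color) {
  r <- ceiling(len * 0.8) + 2L
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  m <- shapeMask(rows, cols, cy, cx, len, wid, theta, shape)
  paintMask(planes, rows, cols, m, color)
}

#' Generate a pop-out stimulus array with its target mask
#'
#' Renders the distractor grid with one target item differing only in the
#' spec's distinguishing attribute, and a binary mask marking the target
#' item's footprint (its bounding square, which covers the item at any
#' orientation).  Deterministic for a fixed spec and seed.
#'
#' @param spec a [patternSpec()].
#' @param targetAsDistractor if `TRUE`, the target cell is rendered as a
#'   plain distractor instead (an all-distractor control image with the
#'   identical layout and jitter) -- useful for render-and-diff checks.
#' @return A list with elements `image` (`H x W x 3` array), `mask`
#'   (binary `H x W` matrix), `targetCell` (`c(row, col)` in the item grid)
#'   and `targetCenter` (`c(row, col)` pixel coordinates, 1-based).
#' @examples
#' p <- generatePattern(patternSpec("color_singleton", seed = 1))
#' dim(p$image); sum(p$mask)
#' @export
generatePattern <- function(spec, targetAsDistractor = FALSE) {
  stopifnot(inherits(spec, "pattern_spec"))
  H <- spec$imageSize; W <- spec$imageSize
  gr <- spec$grid[1]; gc <- spec$grid[2]
  cellH <- H / gr; cellW <- W / gc
  cell <- min(cellH, cellW)
  len <- 0.5 * cell; wid <- len / 3
  bg <- 0.1
  green <- c(0.05, 0.65, 0.05); red <- c(0.85, 0.05, 0.05)
  set.seed(spec$seed)
  n <- gr * gc
  jit <- matrix(stats::runif(2L * n, -spec$jitter, spec$jitter) * cell, n, 2L)
  conjType <- sample(c(0L, 1L), n, replace = TRUE)  # for conjunction arrays
  targetIdx <- sample.int(n, 1L)
  planes <- list(matrix(bg, H, W), matrix(bg, H, W), matrix(bg, H, W))
  targetCenter <- c(NA_real_, NA_real_)
  maskHalf <- len / 2 + 2
  for (i in seq_len(n)) {
    gi <- (i - 1L) %/% gc; gj <- (i - 1L) %% gc
    cy <- (gi + 0.5) * cellH + jit[i, 1]
    cx <- (gj + 0.5) * cellW + jit[i, 2]
    isTarget <- (i == targetIdx) && !targetAsDistractor
    it <- itemFor(spec$kind, isTarget, conjType[i], len, wid, green, red)
    if (spec$kind == "dense_texture") {
      sub <- len / 2.2; off <- cell / 4
      for (oy in c(-off, off)) for (ox in c(-off, off))
        planes <- drawItem(planes, H, W, cy + oy, cx + ox, sub, sub / 3,
                           it$theta, "bar", it$color)
      if (i == targetIdx) maskHalf <- cell / 2.4 + 2
    } else {
      planes <- drawItem(planes, H, W, cy, cx, it$len, it$wid, it$theta,
                         it$shape, it$color)
      if (i == targetIdx) maskHalf <- it$len / 2 + 2
    }
    if (i == targetIdx) targetCenter <- c(cy, cx)
  }
  img <- array(c(planes[[1]], planes[[2]], planes[[3]]), c(H, W, 3L))
  mask <- matrix(0L, H, W)
  rr <- max(1L, floor(targetCenter[1] - maskHalf)):
    min(H, ceiling(targetCenter[1] + maskHalf))
  cc <- max(1L, floor(targetCenter[2] - maskHalf)):
    min(W, ceiling(targetCenter[2] + maskHalf))
  mask[rr, cc] <- 1L
  list(image = img, mask = mask,
       targetCell = c((targetIdx - 1L) %/% gc + 1L,
                      (targetIdx - 1L) %% gc + 1L),
       targetCenter = targetCenter)
}

## item geometry/color for one cell of each pattern kind
itemFor <- function(kind, isTarget, conjType, len, wid, green, red) {
  it <- list(len = len, wid = wid, theta = 0, shape = "bar", color = green)
  switch(kind,
    color_singleton = if (isTarget) it$color <- red,
    orientation_singleton = if (isTarget) it$theta <- pi / 4,
    conjunction = {
      # distractors: red-vertical or green-oblique; target: red-oblique
      if (isTarget) { it$color <- red; it$theta <- pi / 4 }
      else if (conjType == 0L) it$color <- red
      else it$theta <- pi / 4
    },
    curvature = if (isTarget) it$shape <- "arc",
    intersection = if (isTarget) it$shape <- "cross",
    symmetry = { it$shape <- "ell"; if (isTarget) it$shape <- "tee" },
    size_singleton = if (isTarget) { it$len <- 1.5 * len; it$wid <- 1.5 * wid },
    dense_texture = if (isTarget) it$theta <- pi / 2)
  it
}

#' Generate center-biased synthetic fixations
#'
#' Draws fixations from an isotropic Gaussian at the image center with
#' standard deviation `biasSigmaFraction * width`, rejection-sampled into
#' bounds, with the *identical* distribution for every image -- the shared
#' spatial bias that the shuffled-AUC metric is designed to cancel.
#'
#' @param nImages number of images.
#' @param nFixPerImage fixations per image.
#' @param imageSize `c(H, W)` in pixels (a scalar means square).
#' @param biasSigmaFraction Gaussian sigma as a fraction of image width.
#' @param seed integer seed.
#' @return A fixation `data.frame` (`image_id`, 0-based `x`, `y`);
#'   image ids are `"img001"`, `"img002"`, ...
#' @export
generateCenterBiasFixations <- function(nImages, nFixPerImage,
                                        imageSize = c(512L, 512L),
                                        biasSigmaFraction = 0.2, seed = 0L) {
  stopifnot(nImages >= 1L, nFixPerImage >= 1L)
  if (length(imageSize) == 1L) imageSize <- c(imageSize, imageSize)
  H <- imageSize[1]; W <- imageSize[2]
  sigma <- biasSigmaFraction * W
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  set.seed(seed)
  total <- nImages * nFixPerImage
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < total) {
    need <- (total - length(xs)) * 2L + 16L
    x <- round(stats::rnorm(need, cx, sigma))
    y <- round(stats::rnorm(need, cy, sigma))
    ok <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
  }
  data.frame(
    image_id = rep(sprintf("img%03d", seq_len(nImages)),
                   each = nFixPerImage),
    x = as.integer(xs[seq_len(total)]), y = as.integer(ys[seq_len(total)]),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic natural-statistics image
#'
#' Colored noise with an approximately 1/f amplitude spectrum per channel
#' and correlated channels -- the second-order statistics that make ICA
#' patch bases Gabor-like.  Useful for exercising the sparse branch without
#' photographs.
#'
#' @param height,width image extents in pixels.
#' @param seed integer seed.
#' @param channelCorrelation weight of the shared luminance component in
#'   `[0, 1]`.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
generateNaturalImage <- function(height = 60L, width = 80L, seed = 0L,
                                 channelCorrelation = 0.7) {
  set.seed(seed)
  oneOverF <- function() {
    fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
    fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
    f <- sqrt(outer(fy^2, fx^2, `+`))
    f[1, 1] <- Inf                          # kill DC
    spec <- stats::fft(matrix(stats::rnorm(height * width), height)) / f
    Re(stats::fft(spec, inverse = TRUE)) / (height * width)
  }
  shared <- oneOverF()
  img <- array(0, c(height, width, 3L))
  for (ch in 1:3) {
    v <- channelCorrelation * shared + (1 - channelCorrelation) * oneOverF()
    img[, , ch] <- (v - min(v)) / (max(v) - min(v))
  }
  img
}
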