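#' @include csd.R
NULL

#' Build the 5-dimensional color + position feature image
#'
#' Every pixel becomes the vector `(R, G, B, x, y)`: raw color in `[0, 1]`
#' plus the pixel's image-global coordinates normalized to `[0, 1]`
#' (`x = (col - 1)/(W - 1)`, `y = (row - 1)/(H - 1)`; a 1-pixel extent maps
#' to 0).  No gradient or orientation features are included: orientation
#' structure is carried by the sparse branch, whose adaptive basis functions
#' are Gabor-like.
#'
#' @param img `H x W x 3` image array in `[0, 1]`.
#' @return `H x W x 5` numeric array; planes R, G, B, x, y.
#' @export
buildFeatureMatrix <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  H <- dim(img)[1]; W <- dim(img)[2]
  F <- array(0, c(H, W, 5L))
  F[, , 1:3] <- img
  F[, , 4] <- matrix(if (W > 1) (seq_len(W) - 1) / (W - 1) else 0,
                     H, W, byrow = TRUE)
  F[, , 5] <- matrix(if (H > 1) (seq_len(H) - 1) / (H - 1) else 0, H, W)
  F
}

#' Covariance descriptor of a square region
#'
#' Unbiased covariance (divisor `m - 1`) and mean of the `m = size^2`
#' per-pixel feature vectors of the region whose top-left corner is at
#' 1-based `(top, left)`.
#'
#' @param F feature array from [buildFeatureMatrix()] (or any `H x W x d`
#'   numeric array).
#' @param top,left 1-based region origin.
#' @param size region side in pixels, `>= 2`.
#' @return A [RegionCovariance-class].
#' @export
regionCovariance <- function(F, top, left, size) {
  stopifnot(length(dim(F)) == 3L)
  H <- dim(F)[1]; W <- dim(F)[2]; d <- dim(F)[3]
  if (size < 2L) stop("region size must be >= 2")
  if (top < 1L || left < 1L || top + size - 1L > H || left + size - 1L > W)
    stop(sprintf("region (%d,%d)+%d out of bounds for %d x %d", top, left,
                 size, H, W))
  px <- matrix(0, size * size, d)
  for (ch in seq_len(d))
    px[, ch] <- as.vector(F[top:(top + size - 1L), left:(left + size - 1L), ch])
  mu <- colMeans(px)
  C <- crossprod(sweep(px, 2L, mu)) / (nrow(px) - 1)
  C <- (C + t(C)) / 2
  new("RegionCovariance", covariance = C, mean = mu,
      pixelCount = nrow(px))
}

## Sigma-point embedding of (mu, C): concat(mu, mu + sqrt(d) l_i,
## mu - sqrt(d) l_i) where l_i are the Cholesky columns of C (+ jitter).
## Returns a numeric vector of length (2d + 1) d.
sigmaEmbed <- function(mu, C, label = "region") {
  d <- length(mu)
  if (max(abs(C)) == 0) {
    L <- matrix(0, d, d)
  } else {
    eps <- 1e-10 * sum(diag(C)) / d
    L <- NULL
    for (esc in 0:3) {
      L <- tryCatch(t(chol(C + diag(eps * 10^esc, d))),
                    error = function(e) NULL)
      if (!is.null(L)) break
    }
    if (is.null(L))
      stop("Cholesky failed for ", label, " after jitter escalation")
  }
  pts <- cbind(mu, mu + sqrt(d) * L, mu - sqrt(d) * L)
  as.vector(pts)
}

#' Embed first-order statistics into a covariance descriptor
#'
#' Expands a region's `(mu, C)` into `2d + 1` sigma points built from the
#' Cholesky factorization `C + eps I = L L'`:
#' `(mu, mu + sqrt(d) l_1, ..., mu + sqrt(d) l_d, mu - sqrt(d) l_1, ...)`,
#' concatenated into one vector.  The biased covariance of the 2d offset
#' points recovers `C` exactly (up to the jitter `eps`), and the first block
#' is `mu`, so the embedding encodes both moments losslessly in vector form
#' -- which is what the center--surround L1 distance needs.
#'
#' The jitter is `eps = 1e-10 trace(C)/d`, escalated tenfold up to 3 times
#' if the factorization fails; an exactly zero covariance embeds as `mu`
#' repeated `2d + 1` times.
#'
#' @param rc a [RegionCovariance-class].
#' @return A [SigmaFeature-class] of length `(2d + 1) d` (55 for d = 5).
#' @examples
#' F <- buildFeatureMatrix(array(runif(48), c(4, 4, 3)))
#' embedFirstOrder(regionCovariance(F, 1, 1, 4))
#' @export
embedFirstOrder <- function(rc) {
  stopifnot(is(rc, "RegionCovariance"))
  d <- length(rc@mean)
  new("SigmaFeature", vector = sigmaEmbed(rc@mean, rc@covariance),
      alpha = sqrt(d), d = as.integer(d))
}

#' Covariance-branch configuration
#'
#' Defaults: the image is resized to 512 x 512 and windows of 8, 16, 32, 64
#' and 128 pixels (l = 5 scales) are slid at half-window stride, with
#' window-local coordinate planes.
#'
#' @param resolution working resolution (square), pixels.
#' @param patchSizes integer vector of window sizes; each must divide
#'   `resolution`.
#' @param coordinateMode `"local"` (default): the x, y planes are
#'   window-relative, so the embedding is translation-invariant -- two
#'   identical patches anywhere in the image have identical descriptors and
#'   the coordinate planes contribute exactly their covariance with color
#'   (which is what encodes oriented structure); `"global"`: image-global
#'   normalized coordinates, adding the window position itself to the
#'   descriptor mean, which acts as an additional spatial dissimilarity
#'   term (and makes even a constant image inhomogeneous).
#' @param strideFraction window stride as a fraction of the window size
#'   (default 1/2: half-overlapping windows, which averages out the phase
#'   of structure relative to window borders).  1 gives a non-overlapping
#'   tiling.
#' @param minStride smallest stride in pixels (default 8), bounding the
#'   window count per scale.
#' @return A list with class `"cov_branch_config"`.
#' @export
covBranchConfig <- function(resolution = 512L,
                            patchSizes = c(8L, 16L, 32L, 64L, 128L),
                            coordinateMode = c("local", "global"),
                            strideFraction = 0.5, minStride = 8L) {
  stopifnot(all(patchSizes >= 2L), all(resolution %% patchSizes == 0),
            strideFraction > 0, strideFraction <= 1)
  strides <- pmax(pmin(as.integer(round(patchSizes * strideFraction)),
                       patchSizes), as.integer(minStride))
  structure(list(resolution = as.integer(resolution),
                 patchSizes = as.integer(patchSizes),
                 strides = strides,
                 coordinateMode = match.arg(coordinateMode)),
            class = "cov_branch_config")
}

## Vectorized per-scale tile statistics: returns list(psi = ntiles x 55,
## centers = ntiles x 2) for the non-overlapping tiling at side s.
## coordinateMode "local" replaces the x, y planes with tile-relative
## offsets (same normalization), identical for every tile.
tileSigmaFeatures <- function(F, s, coordinateMode = "global", stride = s) {
  tileSigmaFeaturesRaw(F, s, stride, coordinateMode)
}

tileSigmaFeaturesRaw <- function(F, s, stride = s,
                                 coordinateMode = "global") {
  H <- dim(F)[1]; W <- dim(F)[2]; d <- dim(F)[3]
  tops <- seq(1L, H - s + 1L, by = stride)
  lefts <- seq(1L, W - s + 1L, by = stride)
  gr <- length(tops); gc <- length(lefts); n <- gr * gc; m <- s * s
  ## tile-major pixel matrices, one per feature plane (raster tile order)
  P <- vector("list", d)
  for (ch in seq_len(d)) P[[ch]] <- matrix(0, m, n)
  if (n <= m) {
    for (t in seq_len(n)) {
      gi <- (t - 1L) %/% gc; gj <- (t - 1L) %% gc
      rows <- tops[gi + 1L]:(tops[gi + 1L] + s - 1L)
      cols <- lefts[gj + 1L]:(lefts[gj + 1L] + s - 1L)
      for (ch in seq_len(d)) P[[ch]][, t] <- as.vector(F[rows, cols, ch])
    }
  } else {
    for (ch in seq_len(d)) {
      plane <- F[, , ch]
      idx <- 0L
      for (dc in 0:(s - 1L)) for (dr in 0:(s - 1L)) {
        idx <- idx + 1L
        P[[ch]][idx, ] <- as.vector(t(plane[tops + dr, lefts + dc,
                                            drop = FALSE]))
      }
    }
  }
  if (coordinateMode == "local" && d == 5L) {
    ## window-relative coordinates: the same local pattern for every window
    ## (pixel order is column-major within the window, matching P above),
    ## normalized like the global planes so scales stay comparable
    localx <- rep((0:(s - 1L)) / max(W - 1L, 1L), each = s)
    localy <- rep((0:(s - 1L)) / max(H - 1L, 1L), times = s)
    P[[4L]] <- matrix(localx, m, n)
    P[[5L]] <- matrix(localy, m, n)
  }
  mus <- vapply(P, colMeans, numeric(n))          # n x d
  if (n == 1L) mus <- matrix(mus, 1L, d)
  ## raw cross-products per tile, one n-vector per (a, b) pair
  cross <- vector("list", d * d)
  for (a in seq_len(d)) for (b in a:d)
    cross[[(a - 1L) * d + b]] <- colSums(P[[a]] * P[[b]])
  psi <- matrix(0, n, (2L * d + 1L) * d)
  Ct <- matrix(0, d, d)
  for (t in seq_len(n)) {
    for (a in seq_len(d)) for (b in a:d) {
      v <- cross[[(a - 1L) * d + b]][t] - m * mus[t, a] * mus[t, b]
      v <- v / (m - 1)
      # snap cancellation dust to exact zero so constant planes stay exact
      if (abs(v) < 1e-14) v <- 0
      Ct[a, b] <- Ct[b, a] <- v
    }
    psi[t, ] <- sigmaEmbed(mus[t, ], Ct,
                           label = sprintf("tile %d (size %d)", t, s))
  }
  off <- (s - 1) / 2
  centers <- cbind(rep(tops + off, each = gc), rep(lefts + off, times = gr))
  list(psi = psi, centers = centers, gridRows = gr, gridCols = gc)
}

#' Saliency from the color region-covariance branch
#'
#' The image is resized to the working resolution; for each configured
#' window size the (half-overlapping) sliding windows are summarized by
#' region covariances of the `(R, G, B, x, y)` features, embedded into
#' sigma-point vectors, and scored by center--surround dissimilarity on
#' those vectors (dissimilarity-weighted mean).  The per-scale
#' maps are each normalized, multiplied elementwise across scales, and the
#' product normalized.  This branch is fully deterministic.
#'
#' A constant image carries no color evidence at all, so it maps to an
#' all-zero map directly (under global coordinates the tile coordinate
#' means alone would otherwise manufacture structure from nothing).
#'
#' @param img `H x W x 3` image array in `[0, 1]`.
#' @param config a [covBranchConfig()] list.
#' @return A normalized [SaliencyMap-class] at `resolution x resolution`.
#' @export
covarianceSaliencyMap <- function(img, config = covBranchConfig()) {
  stopifnot(length(dim(img)) == 3L)
  res <- config$resolution
  colorRange <- vapply(1:3, function(ch) diff(range(img[, , ch])), numeric(1))
  if (max(colorRange) == 0)
    return(SaliencyMap(matrix(0, res, res), normalized = TRUE))
  F <- buildFeatureMatrix(resizeBilinear(img, res, res))
  maps <- lapply(seq_along(config$patchSizes), function(i) {
    s <- config$patchSizes[i]
    ts <- tileSigmaFeatures(F, s, config$coordinateMode, config$strides[i])
    scores <- csdScores(ts$psi, ts$centers, extent = c(res, res),
                        average = "weight")
    lattice <- matrix(scores, ts$gridRows, ts$gridCols, byrow = TRUE)
    off <- 1 + (s - 1) / 2
    latticeToMap(lattice, off, config$strides[i], off, config$strides[i],
                 res, res, res, res)
  })
  multiscaleCombine(maps)
}
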