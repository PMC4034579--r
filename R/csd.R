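#' @include geometry.R
NULL

#' Center--surround dissimilarity scores
#'
#' Scores each patch by its average feature dissimilarity to all other
#' patches ("the surround"), damped by the spatial distance between patch
#' centers:
#' \deqn{S(p_i) = \frac{1}{n-1} \sum_{j \ne i}
#'   \frac{\lVert \alpha_i - \alpha_j \rVert_1}
#'        {1 + \lVert X_i - X_j \rVert_2}}
#' where \eqn{\alpha_i} is patch i's feature vector (sparse coefficients or
#' sigma-point covariance embedding) and \eqn{X_i} its center in coordinates
#' normalized to `[0, 1]` per axis, which makes the `+1` in the denominator
#' resolution-free.  Patches that differ strongly from everything nearby get
#' high scores; far-away patches contribute with smoothly decaying weight.
#'
#' @param features n x q numeric matrix, one row per patch.
#' @param centers n x 2 numeric matrix of `(row, col)` patch centers.  If
#'   `extent` is supplied they are interpreted as 1-based pixel coordinates
#'   and normalized by `(H - 1, W - 1)`; if `extent` is `NULL` they are used
#'   as given (assumed already normalized).
#' @param extent optional `c(H, W)` source-image extent in pixels.
#' @param average `"count"` (default): divide each patch's weighted
#'   dissimilarity sum by `n - 1`; `"weight"`: divide by the patch's total
#'   weight mass `sum_j 1/(1 + dist_ij)`, i.e. a true weighted mean.  The
#'   weighted mean cancels the position dependence of the weight mass
#'   (central patches are nearer to everything), so saliency reflects
#'   feature dissimilarity only; the branch pipelines use it.
#' @return Numeric vector of n non-negative scores.  With a single patch the
#'   score is 0 (with a warning): there is no surround to differ from.
#' @examples
#' csdScores(matrix(c(0, 0, 3)), cbind(0, c(0, 1, 2)))  # 0.5 0.75 1.25
#' @export
csdScores <- function(features, centers, extent = NULL,
                      average = c("count", "weight")) {
  average <- match.arg(average)
  features <- as.matrix(features); centers <- as.matrix(centers)
  n <- nrow(features)
  stopifnot(nrow(centers) == n, ncol(centers) == 2L)
  if (any(!is.finite(features))) stop("features must be finite")
  if (n < 2L) {
    warning("csdScores: fewer than 2 patches; returning 0")
    return(rep(0, n))
  }
  if (!is.null(extent)) {
    H <- extent[1]; W <- extent[2]
    centers <- cbind(
      if (H > 1) (centers[, 1] - 1) / (H - 1) else rep(0, n),
      if (W > 1) (centers[, 2] - 1) / (W - 1) else rep(0, n))
  }
  sums <- .csd_sums_cpp(t(features), t(centers))
  if (average == "count") sums[1, ] / (n - 1) else sums[1, ] / sums[2, ]
}

#' @rdname normalizeMap
#' @export
setMethod("normalizeMap", "SaliencyMap", function(x) {
  if (isTRUE(x@normalized)) return(x)
  SaliencyMap(normalizeMatrix(x@values), normalized = TRUE)
})

#' @rdname normalizeMap
#' @export
setMethod("normalizeMap", "matrix", function(x) normalizeMatrix(x))

normalizeMatrix <- function(v) {
  rng <- range(v)
  if (!all(is.finite(rng))) stop("map values must be finite")
  if (rng[1] == rng[2]) {
    if (rng[1] == 0) return(v * 0)
    return(v * 0 + 1)
  }
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Combine per-scale maps multiplicatively
#'
#' Each map is normalized to a common dynamic range by dividing by its
#' maximum, the maps are multiplied elementwise across scales, and the
#' product is min--max normalized.  Dividing by the maximum (rather than
#' min--max rescaling each scale) equalizes ranges without subtracting each
#' scale's floor, which would zero out the product wherever any single
#' scale touches its minimum.  With a single scale this reduces to plain
#' min--max normalization.
#'
#' @param maps list of [SaliencyMap-class] objects or matrices, all at the
#'   same resolution.
#' @return A normalized [SaliencyMap-class].
#' @export
multiscaleCombine <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("'maps' must be a non-empty list")
  vals <- lapply(maps, mapValues)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1))))
    stop("all maps must share one resolution")
  prod <- Reduce(`*`, lapply(vals, function(v) {
    mx <- max(v)
    if (mx > 0) v / mx else v
  }))
  SaliencyMap(normalizeMatrix(prod), normalized = TRUE)
}

## Triangle-wave fold of 1-based indices into [1, n]: mirror reflection
## about the edge pixels (edge not duplicated).
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  m <- ((i - 1L) %% p + p) %% p
  as.integer(ifelse(m < n, m, p - m) + 1L)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable convolution with a truncated, normalized Gaussian kernel
#' (radius `ceiling(4 * sigma)`), pixels beyond the border mirrored about
#' the edge.  `sigma = 0` returns the input unchanged.
#'
#' @param x a [SaliencyMap-class] or numeric matrix.
#' @param sigma standard deviation in pixels of the smoothing kernel.
#' @return The same kind of object, smoothed.
#' @export
gaussianSmooth <- function(x, sigma) {
  v <- mapValues(x)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  H <- nrow(v); W <- ncol(v)
  ridx <- reflectIndex((1L - r):(H + r), H)
  tmp <- matrix(0, H, W)
  padded <- v[ridx, , drop = FALSE]
  for (k in seq_along(kern))
    tmp <- tmp + kern[k] * padded[(k - 1L) + seq_len(H), , drop = FALSE]
  cidx <- reflectIndex((1L - r):(W + r), W)
  out <- matrix(0, H, W)
  padded <- tmp[, cidx, drop = FALSE]
  for (k in seq_along(kern))
    out <- out + kern[k] * padded[, (k - 1L) + seq_len(W), drop = FALSE]
  if (is(x, "SaliencyMap")) SaliencyMap(pmax(out, 0)) else out
}

#' Fusion configuration
#'
#' @param sigmaFraction smoothing Gaussian sigma expressed as a fraction of
#'   the fusion-resolution image width.  Default 0.04, the optimal smoothing
#'   found for fixation prediction on natural-scene benchmarks.
#' @return A list with class `"fusion_config"`.
#' @export
fusionConfig <- function(sigmaFraction = 0.04) {
  stopifnot(sigmaFraction >= 0)
  structure(list(sigmaFraction = sigmaFraction), class = "fusion_config")
}

#' Fuse the sparse and covariance branch maps
#'
#' The sparse-branch map is bilinearly resized to the covariance-branch
#' resolution, the two maps are multiplied elementwise and normalized, the
#' product is Gaussian-smoothed with `sigma = sigmaFraction * width`
#' (reflective boundaries), and the result is resized to the requested
#' output resolution and normalized.
#'
#' @param sparseMap,covMap normalized [SaliencyMap-class] objects from the
#'   two branches.
#' @param fusion a [fusionConfig()] list.
#' @param outHeight,outWidth output resolution (typically the input image's
#'   native size).
#' @return A normalized [SaliencyMap-class].
#' @export
fuseAndSmooth <- function(sparseMap, covMap, fusion = fusionConfig(),
                          outHeight, outWidth) {
  sv <- mapValues(sparseMap); cv <- mapValues(covMap)
  sv <- resizeMatrixBilinear(sv, nrow(cv), ncol(cv))
  fused <- normalizeMatrix(sv * cv)
  sigma <- fusion$sigmaFraction * ncol(cv)
  if (sigma > 0) fused <- pmax(gaussianSmooth(fused, sigma), 0)
  out <- normalizeMatrix(resizeMatrixBilinear(fused, outHeight, outWidth))
  SaliencyMap(out, normalized = TRUE)
}

#' Run the full dual-representation saliency model
#'
#' Computes the adaptive sparse-coding branch ([sparseSaliencyMap()]) and the
#' color region-covariance branch ([covarianceSaliencyMap()]), fuses them
#' multiplicatively with Gaussian smoothing ([fuseAndSmooth()]), and returns
#' the final map at the input image's native resolution.
#'
#' If the sparse branch is degenerate (e.g. a constant image admits no
#' dictionary), the covariance branch is smoothed alone, with a warning.
#'
#' @param img `H x W x 3` image array in `[0, 1]` (see [loadImage()]).
#' @param sparse a [sparseBranchConfig()] list.
#' @param cov a [covBranchConfig()] list.
#' @param fusion a [fusionConfig()] list.
#' @return A normalized [SaliencyMap-class] at the image's native resolution.
#' @examples
#' \donttest{
#' img <- generatePattern(patternSpec("color_singleton", seed = 1))$image
#' sal <- runFullModel(img)
#' }
#' @export
runFullModel <- function(img, sparse = sparseBranchConfig(),
                         cov = covBranchConfig(), fusion = fusionConfig()) {
  stopifnot(length(dim(img)) == 3L)
  sMap <- sparseSaliencyMap(img, sparse)
  cMap <- covarianceSaliencyMap(img, cov)
  if (isTRUE(attr(sMap, "degenerate")) || max(mapValues(sMap)) == 0) {
    if (max(mapValues(cMap)) > 0)
      warning("sparse branch degenerate; using covariance branch alone")
    # multiplicative identity: the fused map becomes the covariance branch
    sMap <- SaliencyMap(matrix(1, nrow(mapValues(cMap)),
                               ncol(mapValues(cMap))), normalized = FALSE)
  }
  fuseAndSmooth(sMap, cMap, fusion, dim(img)[1], dim(img)[2])
}
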