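#' @include csd.R
NULL

#' Rank (ROC) AUC of positive vs negative score samples
#'
#' Mann--Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, ties counted 1/2.  Identical to the
#' trapezoidal area under the ROC curve swept over all thresholds.
#'
#' @param positives,negatives non-empty numeric vectors of saliency values
#'   at fixated (positive) and control (negative) pixels.
#' @return AUC in `[0, 1]`.
#' @examples
#' rankAUC(c(1, 2, 3), c(0, 0, 0))  # 1
#' rankAUC(c(2, 0), c(1, 1))        # 0.5
#' @export
rankAUC <- function(positives, negatives) {
  nP <- length(positives); nN <- length(negatives)
  if (nP == 0L || nN == 0L)
    stop("rank AUC is undefined for empty positive or negative sets")
  if (any(!is.finite(positives)) || any(!is.finite(negatives)))
    stop("scores must be finite")
  r <- rank(c(positives, negatives), ties.method = "average")
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Read saliency at fixation coordinates
#'
#' Nearest-pixel lookup of map values at 0-based fixation coordinates
#' (`x` = column, `y` = row), after resizing the map to the image's native
#' resolution when needed.  Coordinates are clamped into bounds.
#'
#' @param map a [SaliencyMap-class] or matrix.
#' @param x,y numeric vectors of 0-based fixation coordinates.
#' @param imageHeight,imageWidth native image resolution the coordinates
#'   refer to; defaults to the map's own resolution.
#' @return Numeric vector of saliency values.
#' @export
saliencyAt <- function(map, x, y, imageHeight = NULL, imageWidth = NULL) {
  v <- mapValues(map)
  if (is.null(imageHeight)) imageHeight <- nrow(v)
  if (is.null(imageWidth)) imageWidth <- ncol(v)
  if (nrow(v) != imageHeight || ncol(v) != imageWidth)
    v <- resizeMatrixBilinear(v, imageHeight, imageWidth)
  rows <- pmin(pmax(round(y) + 1L, 1L), imageHeight)
  cols <- pmin(pmax(round(x) + 1L, 1L), imageWidth)
  v[cbind(rows, cols)]
}

#' Shuffled AUC for eye-fixation prediction
#'
#' Scores a saliency map against human fixations while cancelling shared
#' spatial (center) bias: positives are the fixations on this image;
#' negatives are drawn from fixations recorded on *other* images of the
#' dataset.  A map that merely reproduces the shared fixation distribution
#' -- e.g. a centered Gaussian blob -- scores at the 0.5 chance level.
#'
#' Per repetition, as many negatives as there are positives are sampled from
#' the pool (without replacement when the pool is large enough), both point
#' sets are read off the map by nearest-pixel lookup, and the rank AUC is
#' computed; the mean and standard deviation over `nReps` repetitions are
#' returned.  Deterministic for a fixed seed.
#'
#' @param map a [SaliencyMap-class] or matrix.
#' @param fixations data.frame with 0-based columns `x`, `y`: fixations on
#'   the evaluated image (at least one).
#' @param otherFixations data.frame with columns `x`, `y`: the pooled
#'   fixations of the other images (non-empty).
#' @param nReps number of negative-resampling repetitions (default 20).
#' @param seed integer seed.
#' @param imageHeight,imageWidth native resolution the coordinates refer to.
#' @return List with elements `mean`, `sd`, and `scores` (per repetition).
#' @export
shuffledAUC <- function(map, fixations, otherFixations, nReps = 20L,
                        seed = 0L, imageHeight = NULL, imageWidth = NULL) {
  if (nrow(fixations) == 0L)
    stop("shuffled AUC needs at least one fixation on the image")
  if (nrow(otherFixations) == 0L)
    stop("shuffled AUC needs a non-empty pool of other-image fixations")
  v <- mapValues(map)
  if (is.null(imageHeight)) imageHeight <- nrow(v)
  if (is.null(imageWidth)) imageWidth <- ncol(v)
  if (nrow(v) != imageHeight || ncol(v) != imageWidth)
    v <- resizeMatrixBilinear(v, imageHeight, imageWidth)
  pos <- saliencyAt(v, fixations$x, fixations$y)
  poolVals <- saliencyAt(v, otherFixations$x, otherFixations$y)
  nP <- length(pos)
  set.seed(seed)
  scores <- vapply(seq_len(nReps), function(i) {
    neg <- if (length(poolVals) >= nP) sample(poolVals, nP)
      else sample(poolVals, nP, replace = TRUE)
    rankAUC(pos, neg)
  }, numeric(1))
  list(mean = mean(scores), sd = stats::sd(scores), scores = scores)
}

#' Dice similarity curve of a saliency map against an object mask
#'
#' Binarizes the map at each of `nThresholds` uniform levels in `[0, 1]`
#' (`map >= t`) and computes the Dice similarity coefficient
#' `DSC = 2 |A intersect B| / (|A| + |B|)` against the ground-truth mask
#' (defined as 0 when both sets are empty).  The curve's maximum is the
#' peak DSC, the standard single-number summary of salient-object overlap.
#'
#' @param map a [SaliencyMap-class] or matrix, same resolution as `mask`.
#' @param mask binary matrix (0/1 or logical), nonzero = salient object.
#' @param nThresholds number of uniform threshold levels (default 256).
#' @return An object of class `"dsc_curve"`: list with `thresholds`,
#'   `dsc`, and `peak`.
#' @seealso [peakDSC()]
#' @export
dscCurve <- function(map, mask, nThresholds = 256L) {
  v <- mapValues(map)
  mask <- as.matrix(mask)
  if (!identical(dim(v), dim(mask)))
    stop("map and mask resolutions differ")
  if (sum(mask != 0) == 0L) stop("ground-truth mask is empty")
  B <- mask != 0
  nB <- sum(B)
  thresholds <- seq(0, 1, length.out = nThresholds)
  dsc <- vapply(thresholds, function(t) {
    A <- v >= t
    nA <- sum(A)
    if (nA + nB == 0L) return(0)
    2 * sum(A & B) / (nA + nB)
  }, numeric(1))
  structure(list(thresholds = thresholds, dsc = dsc, peak = max(dsc)),
            class = "dsc_curve")
}

#' Peak of a Dice similarity curve
#'
#' @param curve a `"dsc_curve"` from [dscCurve()].
#' @return The maximum DSC over the threshold lattice.
#' @export
peakDSC <- function(curve) {
  stopifnot(inherits(curve, "dsc_curve"))
  curve$peak
}

#' @export
print.dsc_curve <- function(x, ...) {
  cat(sprintf("DSC curve: %d thresholds, peak DSC = %.4f at t = %.4f\n",
              length(x$thresholds), x$peak,
              x$thresholds[which.max(x$dsc)]))
  invisible(x)
}

#' Sweep the smoothing sigma and re-evaluate
#'
#' Re-smooths an *unsmoothed* fused saliency map at each candidate sigma
#' (expressed as a fraction of the map width), normalizes, and evaluates a
#' user-supplied metric, reporting the score per sigma and the argmax.
#'
#' @param map a [SaliencyMap-class] or matrix (unsmoothed).
#' @param sigmaFractions ascending numeric vector of width fractions.
#' @param scoreFun function taking a normalized [SaliencyMap-class] and
#'   returning a single numeric score (e.g. a shuffled-AUC or peak-DSC
#'   closure over fixed ground truth).
#' @return A `data.frame` with columns `sigma_fraction` and `score`, with
#'   attribute `"best"` holding the argmax row.
#' @export
sigmaSweep <- function(map, sigmaFractions, scoreFun) {
  stopifnot(length(sigmaFractions) >= 1L, !is.unsorted(sigmaFractions))
  v <- mapValues(map)
  scores <- vapply(sigmaFractions, function(f) {
    sm <- if (f > 0) gaussianSmooth(v, f * ncol(v)) else v
    scoreFun(SaliencyMap(normalizeMatrix(pmax(sm, 0)), normalized = TRUE))
  }, numeric(1))
  out <- data.frame(sigma_fraction = sigmaFractions, score = scores)
  attr(out, "best") <- out[which.max(scores), ]
  out
}
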