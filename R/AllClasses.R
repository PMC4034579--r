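#' @include salicsd-package.R
NULL

## ---------------------------------------------------------------------------
## Central S4 containers.  Validity methods enforce the structural invariants
## that downstream numerics rely on; accessors (below and in AllGenerics.R)
## are the supported interface -- slots are internal.
## ---------------------------------------------------------------------------

#' SaliencyMap: a non-negative 2-D conspicuity field
#'
#' Wraps an `H x W` matrix of finite, non-negative saliency values together
#' with a flag recording whether the map has been min--max normalized to
#' `[0, 1]` (see [normalizeMap()]).
#'
#' @slot values numeric matrix, finite and `>= 0`.
#' @slot normalized logical scalar; if `TRUE` the values span `[0, 1]`
#'   (a constant map is all 0 or all 1, see [normalizeMap()]).
#' @seealso [normalizeMap()], [assemblePatchMap()], [runFullModel()]
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(values = "matrix", normalized = "logical"),
  prototype(values = matrix(0, 1, 1), normalized = FALSE),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (any(!is.finite(v))) return("saliency values must all be finite")
    if (any(v < 0)) return("saliency values must be non-negative")
    if (length(object@normalized) != 1L) return("'normalized' must be a scalar")
    if (isTRUE(object@normalized)) {
      rng <- range(v)
      constant <- rng[1] == rng[2]
      ok <- if (constant) rng[1] %in% c(0, 1) else
        abs(rng[1]) < 1e-8 && abs(rng[2] - 1) < 1e-8
      if (!ok) return("normalized map must span [0,1] (or be constant 0/1)")
    }
    TRUE
  })

#' Construct a SaliencyMap
#'
#' @param values numeric matrix of non-negative saliency values.
#' @param normalized logical; whether `values` are already min--max
#'   normalized to `[0, 1]`.
#' @return A [SaliencyMap-class] object.
#' @examples
#' SaliencyMap(matrix(runif(12), 3, 4))
#' @export
SaliencyMap <- function(values, normalized = FALSE) {
  if (is(values, "SaliencyMap")) values <- values@values
  new("SaliencyMap", values = as.matrix(values), normalized = normalized)
}

#' PatchGrid: vectorized image patches on a regular lattice
#'
#' Rows of `patchVectors` are raster-ordered (row-major over grid positions);
#' within a patch, pixels are vectorized row-major per channel and channels
#' concatenated R|G|B (then x|y when present).  Centers are 1-based
#' `(row, col)` coordinates in the source image, kept fractional for even
#' patch sizes.
#'
#' @slot patchVectors n x d numeric matrix, one row per patch.
#' @slot patchSize integer, square patch side in pixels.
#' @slot stride integer stride in pixels.
#' @slot gridRows,gridCols integer lattice extents; `n = gridRows * gridCols`.
#' @slot centers n x 2 numeric matrix of `(row, col)` patch centers.
#' @slot sourceHeight,sourceWidth integer source image extents.
#' @slot channels character, `"rgb"` or `"rgbxy"`.
#' @seealso [extractPatches()], [assemblePatchMap()]
#' @exportClass PatchGrid
setClass("PatchGrid",
  representation(patchVectors = "matrix", patchSize = "integer",
    stride = "integer", gridRows = "integer", gridCols = "integer",
    centers = "matrix", sourceHeight = "integer", sourceWidth = "integer",
    channels = "character"),
  validity = function(object) {
    n <- nrow(object@patchVectors)
    if (n != object@gridRows * object@gridCols)
      return("patch count must equal gridRows * gridCols")
    if (nrow(object@centers) != n || ncol(object@centers) != 2L)
      return("'centers' must be an n x 2 matrix")
    if (any(object@centers[, 1] < 1 | object@centers[, 1] > object@sourceHeight) ||
        any(object@centers[, 2] < 1 | object@centers[, 2] > object@sourceWidth))
      return("every patch center must lie inside the source image")
    nchan <- switch(object@channels, rgb = 3L, rgbxy = 5L, NA_integer_)
    if (is.na(nchan)) return("channels must be 'rgb' or 'rgbxy'")
    if (ncol(object@patchVectors) != object@patchSize^2 * nchan)
      return("patch vector dimension must be patchSize^2 * channel count")
    TRUE
  })

#' AdaptiveDictionary: a per-image ICA basis
#'
#' The basis `A` (columns are basis functions), the unmixing matrix `W`
#' mapping centered patch vectors to coefficients, and the per-dimension
#' means removed before learning.  When the dictionary is complete
#' (`m' = d`), `W %*% A` is the identity to high precision, making the
#' encode/reconstruct round trip exact.
#'
#' @slot basis d x m' numeric matrix (`A`).
#' @slot unmixing m' x d numeric matrix (`W`).
#' @slot dimensionMeans length-d numeric vector of centering offsets.
#' @slot converged logical; `FALSE` when FastICA did not converge and the
#'   whitening basis was used instead.
#' @slot seed integer seed all stochastic initialization flowed through.
#' @seealso [learnAdaptiveDictionary()], [encodePatches()]
#' @exportClass AdaptiveDictionary
setClass("AdaptiveDictionary",
  representation(basis = "matrix", unmixing = "matrix",
    dimensionMeans = "numeric", converged = "logical", seed = "integer"),
  validity = function(object) {
    A <- object@basis; W <- object@unmixing
    if (any(!is.finite(A)) || any(!is.finite(W)))
      return("basis and unmixing must be finite")
    if (ncol(A) != nrow(W) || nrow(A) != ncol(W))
      return("unmixing must be the transpose shape of basis")
    if (length(object@dimensionMeans) != nrow(A))
      return("dimensionMeans length must equal the patch dimension d")
    if (any(sqrt(colSums(A^2)) < 1e-12))
      return("basis columns must have nonzero norm")
    if (ncol(A) == nrow(A)) {
      dev <- max(abs(W %*% A - diag(nrow(A))))
      if (dev >= 1e-6)
        return(sprintf("complete dictionary must satisfy W A = I (dev %.2e)", dev))
    }
    TRUE
  })

#' SparseCodeSet: sparse coefficient vectors of a patch grid
#'
#' @slot codes n x m' numeric matrix; row k is patch k's coefficient vector.
#' @slot dictionary the [AdaptiveDictionary-class] the codes live in.
#' @slot grid the [PatchGrid-class] the codes were computed from.
#' @seealso [encodePatches()], [reconstructPatches()]
#' @exportClass SparseCodeSet
setClass("SparseCodeSet",
  representation(codes = "matrix", dictionary = "AdaptiveDictionary",
    grid = "PatchGrid"),
  validity = function(object) {
    if (nrow(object@codes) != nrow(object@grid@patchVectors))
      return("one code row per patch is required")
    if (ncol(object@codes) != ncol(object@dictionary@basis))
      return("code dimension must match the dictionary component count")
    TRUE
  })

#' RegionCovariance: second-order statistics of a pixel region
#'
#' Unbiased covariance (divisor `m - 1`) and mean of the per-pixel feature
#' vectors of a square region.
#'
#' @slot covariance d x d symmetric numeric matrix.
#' @slot mean length-d numeric vector.
#' @slot pixelCount integer m, the number of pixels in the region.
#' @seealso [regionCovariance()], [embedFirstOrder()]
#' @exportClass RegionCovariance
setClass("RegionCovariance",
  representation(covariance = "matrix", mean = "numeric",
    pixelCount = "integer"),
  validity = function(object) {
    C <- object@covariance
    if (nrow(C) != ncol(C)) return("covariance must be square")
    if (length(object@mean) != nrow(C))
      return("mean length must match covariance dimension")
    if (max(abs(C - t(C))) > 1e-10) return("covariance must be symmetric")
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return("covariance must be positive semi-definite (within 1e-8)")
    if (object@pixelCount < 2L) return("a region needs at least 2 pixels")
    TRUE
  })

#' SigmaFeature: vector-form embedding of (mean, covariance)
#'
#' The sigma-point expansion of a [RegionCovariance-class]: the mean followed
#' by the `2d` points `mu +/- sqrt(d) * l_i` built from the Cholesky columns
#' `l_i` of the covariance, concatenated into one vector of length
#' `(2d + 1) * d`.  The construction is exactly invertible: the first block
#' is the mean and the biased covariance of the 2d offset points recovers the
#' covariance matrix.
#'
#' @slot vector numeric vector of length `(2d + 1) * d`.
#' @slot alpha numeric, the sigma-point scaling used (`sqrt(d)`).
#' @slot d integer feature dimension.
#' @seealso [embedFirstOrder()]
#' @exportClass SigmaFeature
setClass("SigmaFeature",
  representation(vector = "numeric", alpha = "numeric", d = "integer"),
  validity = function(object) {
    if (length(object@vector) != (2L * object@d + 1L) * object@d)
      return("sigma feature length must be (2d + 1) * d")
    if (any(!is.finite(object@vector))) return("sigma feature must be finite")
    TRUE
  })
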