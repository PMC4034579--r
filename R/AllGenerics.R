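#' @include AllClasses.R
NULL

#' Extract the value matrix of a SaliencyMap
#'
#' @param x a [SaliencyMap-class] (or a bare matrix, returned as-is).
#' @return The underlying numeric `H x W` matrix.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "SaliencyMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "matrix", function(x) x)

#' Has a map been min-max normalized?
#'
#' @param x a [SaliencyMap-class].
#' @return Logical scalar.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "SaliencyMap", function(x) x@normalized)

#' @describeIn SaliencyMap dimensions of the underlying matrix.
#' @param x a `SaliencyMap`.
#' @export
setMethod("dim", "SaliencyMap", function(x) dim(x@values))

#' Number of patches in a grid
#'
#' @param x a [PatchGrid-class] or [SparseCodeSet-class].
#' @return Integer patch count.
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname nPatches
#' @export
setMethod("nPatches", "PatchGrid", function(x) nrow(x@patchVectors))

#' @rdname nPatches
#' @export
setMethod("nPatches", "SparseCodeSet", function(x) nrow(x@codes))

#' Patch vectors and centers of a grid
#'
#' @param x a [PatchGrid-class].
#' @return `patchVectors()`: the n x d matrix of vectorized patches;
#'   `patchCenters()`: the n x 2 matrix of 1-based `(row, col)` centers.
#' @export
setGeneric("patchVectors", function(x) standardGeneric("patchVectors"))

#' @rdname patchVectors
#' @export
setMethod("patchVectors", "PatchGrid", function(x) x@patchVectors)

#' @rdname patchVectors
#' @export
setGeneric("patchCenters", function(x) standardGeneric("patchCenters"))

#' @rdname patchVectors
#' @export
setMethod("patchCenters", "PatchGrid", function(x) x@centers)

#' Dictionary accessors
#'
#' @param x an [AdaptiveDictionary-class] or [SparseCodeSet-class].
#' @return `dictionaryBasis()`: the d x m' basis matrix A;
#'   `dictionaryUnmixing()`: the m' x d unmixing matrix W;
#'   `codeMatrix()`: the n x m' coefficient matrix of a code set.
#' @export
setGeneric("dictionaryBasis", function(x) standardGeneric("dictionaryBasis"))

#' @rdname dictionaryBasis
#' @export
setMethod("dictionaryBasis", "AdaptiveDictionary", function(x) x@basis)

#' @rdname dictionaryBasis
#' @export
setMethod("dictionaryBasis", "SparseCodeSet", function(x) x@dictionary@basis)

#' @rdname dictionaryBasis
#' @export
setGeneric("dictionaryUnmixing",
  function(x) standardGeneric("dictionaryUnmixing"))

#' @rdname dictionaryBasis
#' @export
setMethod("dictionaryUnmixing", "AdaptiveDictionary", function(x) x@unmixing)

#' @rdname dictionaryBasis
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))

#' @rdname dictionaryBasis
#' @export
setMethod("codeMatrix", "SparseCodeSet", function(x) x@codes)

#' Min-max normalize a saliency map
#'
#' Rescales a map to `[0, 1]`.  A constant map maps to all 0 when the
#' constant is 0 and to all 1 otherwise, so that an all-zero (fully
#' non-salient) map stays all-zero.  Idempotent.
#'
#' @param x a [SaliencyMap-class] or numeric matrix.
#' @return The same kind of object, normalized.
#' @examples
#' mapValues(normalizeMap(matrix(c(2, 4, 3, 2), 2)))
#' @export
setGeneric("normalizeMap", function(x) standardGeneric("normalizeMap"))

#' Bilinear resize of an image or map
#'
#' Area-symmetric bilinear interpolation: output pixel centers are mapped
#' linearly into the input pixel lattice, so resizing to the input size
#' returns the input value-for-value and the output range never exceeds the
#' input range.  Arrays are resized per channel.
#'
#' @param x an `H x W (x C)` numeric array/matrix or a [SaliencyMap-class].
#' @param outHeight,outWidth positive integer target extents in pixels.
#' @return The same kind of object at the target resolution.
#' @examples
#' resizeBilinear(matrix(c(0, 1, 1, 0), 2), 1, 1)  # 0.5
#' @export
setGeneric("resizeBilinear",
  function(x, outHeight, outWidth) standardGeneric("resizeBilinear"))

setMethod("show", "SaliencyMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("SaliencyMap %d x %d (%s), range [%.4g, %.4g]\n",
    d[1], d[2], if (object@normalized) "normalized" else "raw",
    min(object@values), max(object@values)))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf(
    "PatchGrid: %d patches (%d x %d lattice), %d x %d px, stride %d, %s (d = %d)\n",
    nPatches(object), object@gridRows, object@gridCols, object@patchSize,
    object@patchSize, object@stride, object@channels,
    ncol(object@patchVectors)))
})

setMethod("show", "AdaptiveDictionary", function(object) {
  cat(sprintf("AdaptiveDictionary: d = %d, m' = %d, %s (seed %d)\n",
    nrow(object@basis), ncol(object@basis),
    if (object@converged) "converged" else "NOT converged", object@seed))
})

setMethod("show", "SparseCodeSet", function(object) {
  cat(sprintf("SparseCodeSet: %d patches x %d coefficients\n",
    nrow(object@codes), ncol(object@codes)))
})

setMethod("show", "RegionCovariance", function(object) {
  cat(sprintf("RegionCovariance: d = %d, m = %d pixels\n",
    nrow(object@covariance), object@pixelCount))
})

setMethod("show", "SigmaFeature", function(object) {
  cat(sprintf("SigmaFeature: d = %d, length %d, alpha = %.4f\n",
    object@d, length(object@vector), object@alpha))
})
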