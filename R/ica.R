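#' @include AllGenerics.R
NULL

## Seeded random orthogonal init for the FastICA rotation.
randomRotation <- function(nc, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
}

#' Learn a per-image ICA dictionary from patches
#'
#' Centers the patch vectors per dimension, whitens, and runs symmetric
#' FastICA (logcosh contrast) to obtain a basis `A` whose columns are the
#' independent components of this image's own patch statistics -- the
#' *adaptive* dictionary: learned afresh for every input image rather than
#' once from an image ensemble, so the complete (`m' = d`) representation
#' loses no information.  The unmixing matrix is the pseudoinverse of the
#' basis, so `W A = I` holds exactly up to floating point for any `m'`.
#'
#' If the patch matrix is numerically rank deficient, the component count is
#' reduced to the rank.  The FastICA iterate at `maxit` is used even when
#' the strict rotation-change criterion was not met (the `converged` slot
#' records which); on hard numerical failure the fit is restarted up to 3
#' times with incremented seeds and finally the PCA whitening basis is used.
#' A constant image (zero-variance patches) has no dictionary and raises a
#' `degenerateDictionaryError`.
#'
#' @param grid a [PatchGrid-class], or a plain n x d numeric matrix of
#'   observation vectors (one row per patch); at least `nComponents` rows.
#' @param nComponents number of basis functions `m'` (default: the patch
#'   dimension d, i.e. a complete dictionary).
#' @param seed integer seed; all stochastic initialization flows through it.
#' @param maxit,tol FastICA iteration cap and convergence tolerance.
#' @return An [AdaptiveDictionary-class].
#' @examples
#' img <- array(runif(40 * 40 * 3), c(40, 40, 3))
#' d <- learnAdaptiveDictionary(extractPatches(img, 3, 2))
#' max(abs(dictionaryUnmixing(d) %*% dictionaryBasis(d) - diag(27)))  # ~0
#' @export
learnAdaptiveDictionary <- function(grid, nComponents = NULL, seed = 0L,
                                    maxit = 100L, tol = 1e-4) {
  X <- if (is(grid, "PatchGrid")) grid@patchVectors else as.matrix(grid)
  d <- ncol(X)
  if (is.null(nComponents)) nComponents <- d
  if (nrow(X) < nComponents)
    stop("need at least nComponents patches")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  rank <- sum(sv > max(sv) * max(dim(Xc)) * .Machine$double.eps * 10)
  if (rank == 0L) {
    cond <- simpleError("degenerate dictionary: all patches are identical (constant image)")
    class(cond) <- c("degenerateDictionaryError", class(cond))
    stop(cond)
  }
  nc <- min(nComponents, rank)
  fit <- NULL; converged <- FALSE
  for (attempt in 0:3) {
    Rmat <- if (attempt == 0 && seed == 0L) diag(nc)
      else randomRotation(nc, seed + attempt)
    fit <- tryCatch(
      ica::icafast(Xc, nc, center = FALSE, maxit = maxit, tol = tol,
                   Rmat = Rmat, alg = "par", fun = "logcosh"),
      error = function(e) NULL)
    ok <- !is.null(fit) && all(is.finite(fit$M)) &&
      all(sqrt(colSums(fit$M^2)) >= 1e-12)
    # a usable iterate is kept even when the strict rotation-change
    # criterion was not met at maxit; restarts are for hard failures
    if (ok) { converged <- isTRUE(fit$converged); break }
    fit <- NULL
  }
  A <- if (!is.null(fit)) fit$M else NULL    # d x nc mixing (basis)
  if (is.null(A) || any(!is.finite(A)) ||
      any(sqrt(colSums(A^2)) < 1e-12)) {
    # fall back to the PCA whitening basis
    eg <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
    keep <- seq_len(nc)
    A <- eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[keep], 0)), nc)
    converged <- FALSE
  }
  W <- solve(crossprod(A), t(A))             # pseudoinverse: (A'A)^-1 A'
  new("AdaptiveDictionary", basis = A, unmixing = W, dimensionMeans = mu,
      converged = converged, seed = as.integer(seed))
}

#' Encode patches as sparse coefficient vectors
#'
#' Projects centered patch vectors onto the dictionary:
#' code row k = `W (patch_k - dimensionMeans)`.
#'
#' @param grid a [PatchGrid-class] whose vector dimension matches the
#'   dictionary's d.
#' @param dict an [AdaptiveDictionary-class].
#' @return A [SparseCodeSet-class].
#' @export
encodePatches <- function(grid, dict) {
  stopifnot(is(grid, "PatchGrid"), is(dict, "AdaptiveDictionary"))
  if (ncol(grid@patchVectors) != length(dict@dimensionMeans))
    stop("patch dimension does not match the dictionary")
  Xc <- sweep(grid@patchVectors, 2L, dict@dimensionMeans)
  new("SparseCodeSet", codes = Xc %*% t(dict@unmixing), dictionary = dict,
      grid = grid)
}

#' Reconstruct patches from sparse codes
#'
#' Row k of the result is `A code_k + dimensionMeans`.  With a complete
#' dictionary (`m' = d`) the encode -> reconstruct round trip reproduces the
#' original patches to floating-point precision; an undercomplete dictionary
#' (`m' < d`), e.g. one learned from *different* images, leaves a nonzero
#' residual -- the information a fixed dictionary loses.
#'
#' @param codes a [SparseCodeSet-class].
#' @return n x d numeric matrix of reconstructed patch vectors.
#' @export
reconstructPatches <- function(codes) {
  stopifnot(is(codes, "SparseCodeSet"))
  sweep(codes@codes %*% t(codes@dictionary@basis), 2L,
        codes@dictionary@dimensionMeans, `+`)
}
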