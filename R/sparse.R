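#' @include ica.R csd.R
NULL

#' Sparse-branch configuration
#'
#' Defaults follow the model's operating point for natural scenes: the image
#' is resized to 80 x 60 (width x height), 5 x 5 color patches (d = 75) are
#' taken with stride 1, and a complete adaptive dictionary (m' = 75) is
#' learned per image.  A single scale is used; additional scales (halved and
#' doubled resolution) may be requested via `scales` and are combined
#' multiplicatively.
#'
#' @param resolutionW,resolutionH working resolution in pixels.
#' @param patchSize patch side in pixels.
#' @param stride patch stride in pixels.
#' @param nComponents dictionary size m' (`NULL` = complete, m' = d).
#' @param seed integer seed for the ICA initialization.
#' @param scales number of scales (1, 2 or 3).  Scale ladders are the base
#'   resolution, half, then double.
#' @return A list with class `"sparse_branch_config"`.
#' @export
sparseBranchConfig <- function(resolutionW = 80L, resolutionH = 60L,
                               patchSize = 5L, stride = 1L,
                               nComponents = NULL, seed = 0L, scales = 1L) {
  stopifnot(resolutionW >= patchSize, resolutionH >= patchSize,
            stride >= 1L, scales >= 1L, scales <= 3L)
  structure(list(resolutionW = as.integer(resolutionW),
                 resolutionH = as.integer(resolutionH),
                 patchSize = as.integer(patchSize),
                 stride = as.integer(stride),
                 nComponents = nComponents, seed = as.integer(seed),
                 scales = as.integer(scales)),
            class = "sparse_branch_config")
}

## Resolution ladder for multi-scale sparse saliency: base, half, double.
sparseScaleLadder <- function(config) {
  base <- c(config$resolutionH, config$resolutionW)
  lad <- list(base, pmax(round(base / 2), config$patchSize), base * 2)
  lad[seq_len(config$scales)]
}

#' Saliency from the adaptive sparse-coding branch
#'
#' The image is resized to the working resolution, overlapping color patches
#' are extracted and encoded over a per-image ICA dictionary, and each
#' patch's sparse coefficient vector is scored by center--surround
#' dissimilarity ([csdScores()]).  Per-scale maps are normalized, multiplied
#' and renormalized ([multiscaleCombine()]).
#'
#' A degenerate image (constant: no dictionary exists) yields a constant
#' zero map with a warning and a `degenerate` attribute.
#'
#' @param img `H x W x 3` image array in `[0, 1]`.
#' @param config a [sparseBranchConfig()] list.
#' @return A normalized [SaliencyMap-class] at the branch's base resolution
#'   (`resolutionH x resolutionW`).
#' @export
sparseSaliencyMap <- function(img, config = sparseBranchConfig()) {
  stopifnot(length(dim(img)) == 3L)
  base <- c(config$resolutionH, config$resolutionW)
  maps <- list()
  for (res in sparseScaleLadder(config)) {
    small <- resizeBilinear(img, res[1], res[2])
    grid <- extractPatches(small, config$patchSize, config$stride, "rgb")
    dict <- tryCatch(
      learnAdaptiveDictionary(grid, config$nComponents, config$seed),
      degenerateDictionaryError = function(e) NULL)
    if (is.null(dict)) {
      warning("degenerate dictionary (constant image); zero saliency map")
      out <- SaliencyMap(matrix(0, base[1], base[2]), normalized = TRUE)
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    codes <- encodePatches(grid, dict)
    scores <- csdScores(codes@codes, grid@centers, extent = res,
                        average = "weight")
    maps[[length(maps) + 1L]] <-
      assemblePatchMap(scores, grid, base[1], base[2])
  }
  multiscaleCombine(maps)
}
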