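#' @include AllGenerics.R
NULL

## constraint: every public entry point sees images as H x W x 3 arrays in
## [0,1]; this is the one place file formats are touched.

#' Load an RGB image
#'
#' Reads a PNG or JPEG file into an `H x W x 3` array of intensities in
#' `[0, 1]` (8-bit values divided by 255).  Single-channel images are
#' replicated to three identical channels; an alpha channel is dropped.
#'
#' @param path path to a readable PNG or JPEG file.
#' @return `H x W x 3` numeric array with a `"source_path"` attribute.
#' @export
loadImage <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot load image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  readers <- switch(ext,
    png = list(png::readPNG),
    jpg = , jpeg = list(jpeg::readJPEG),
    list(png::readPNG, jpeg::readJPEG))
  img <- NULL
  for (rd in readers) {
    img <- tryCatch(rd(path), error = function(e) NULL)
    if (!is.null(img)) break
  }
  if (is.null(img))
    stop("cannot load image (not a decodable PNG/JPEG): ", path)
  img <- asImageRGB(img)
  attr(img, "source_path") <- path
  img
}

## Coerce a decoded raster (matrix or H x W x {1,2,3,4}) to H x W x 3.
asImageRGB <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  stopifnot(length(dim(img)) == 3L)
  nc <- dim(img)[3]
  img <- if (nc == 1L) array(rep(img, 3L), c(dim(img)[1:2], 3L))
    else if (nc == 2L) array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
    else img[, , 1:3, drop = FALSE]
  storage.mode(img) <- "double"
  img
}

#' Write a saliency map to disk
#'
#' Writes an 8-bit grayscale PNG (min--max stretched) and/or a plain-text CSV
#' of the raw float values for bit-faithful inspection.
#'
#' @param map a [SaliencyMap-class] or numeric matrix.
#' @param pngPath,csvPath output paths; either may be `NULL` to skip.
#' @return Invisibly, the map.
#' @export
writeSaliencyMap <- function(map, pngPath = NULL, csvPath = NULL) {
  v <- mapValues(map)
  if (!is.null(pngPath)) {
    rng <- range(v)
    s <- if (rng[1] == rng[2]) v * 0 else (v - rng[1]) / (rng[2] - rng[1])
    png::writePNG(s, pngPath)
  }
  if (!is.null(csvPath))
    utils::write.table(v, csvPath, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(map)
}

## Area-symmetric bilinear sampling positions: output pixel center i (1-based)
## maps to input coordinate (i - 0.5) * scale + 0.5, clamped to the lattice.
bilinearAxis <- function(nIn, nOut) {
  src <- (seq_len(nOut) - 0.5) * (nIn / nOut) + 0.5
  src <- pmin(pmax(src, 1), nIn)
  i0 <- pmin(floor(src), nIn - 1L)
  if (nIn == 1L) i0 <- rep(1, nOut)
  w <- src - i0
  list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, nIn)), w = w)
}

resizeMatrixBilinear <- function(m, outH, outW) {
  if (outH < 1L || outW < 1L) stop("target size must be positive")
  H <- nrow(m); W <- ncol(m)
  if (H == outH && W == outW) return(m)
  r <- bilinearAxis(H, outH); cc <- bilinearAxis(W, outW)
  wr <- r$w; wc <- matrix(cc$w, outH, outW, byrow = TRUE)
  rowInterp0 <- m[r$i0, cc$i0, drop = FALSE] * (1 - wc) +
    m[r$i0, cc$i1, drop = FALSE] * wc
  rowInterp1 <- m[r$i1, cc$i0, drop = FALSE] * (1 - wc) +
    m[r$i1, cc$i1, drop = FALSE] * wc
  (1 - wr) * rowInterp0 + wr * rowInterp1
}

#' @rdname resizeBilinear
#' @export
setMethod("resizeBilinear", "matrix", function(x, outHeight, outWidth) {
  resizeMatrixBilinear(x, as.integer(outHeight), as.integer(outWidth))
})

#' @rdname resizeBilinear
#' @export
setMethod("resizeBilinear", "array", function(x, outHeight, outWidth) {
  stopifnot(length(dim(x)) == 3L)
  out <- array(0, c(outHeight, outWidth, dim(x)[3]))
  for (ch in seq_len(dim(x)[3]))
    out[, , ch] <- resizeMatrixBilinear(x[, , ch], outHeight, outWidth)
  out
})

#' @rdname resizeBilinear
#' @export
setMethod("resizeBilinear", "SaliencyMap", function(x, outHeight, outWidth) {
  SaliencyMap(resizeMatrixBilinear(x@values, outHeight, outWidth),
              normalized = FALSE)
})

#' Extract square patches on a regular grid
#'
#' Slides a `patchSize x patchSize` window over the image with the given
#' stride, taking only fully interior patches (no padding), and vectorizes
#' each patch row-major per channel with channels concatenated R|G|B (then
#' normalized x|y planes for `channels = "rgbxy"`).
#'
#' @param img `H x W x 3` image array in `[0, 1]`.
#' @param patchSize square patch side in pixels; must not exceed either
#'   image dimension.
#' @param stride step between patch origins, `>= 1`.
#' @param channels `"rgb"` (d = patchSize^2 * 3) or `"rgbxy"` (adds the
#'   image-global normalized coordinate planes, d = patchSize^2 * 5).
#' @return A [PatchGrid-class]; `floor((H - k)/stride) + 1` rows of patches by
#'   the analogous number of columns.
#' @examples
#' img <- array(runif(60 * 80 * 3), c(60, 80, 3))
#' extractPatches(img, 5, 1)        # 56 x 76 lattice, 4256 patches
#' @export
extractPatches <- function(img, patchSize, stride = 1L,
                           channels = c("rgb", "rgbxy")) {
  channels <- match.arg(channels)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  H <- dim(img)[1]; W <- dim(img)[2]
  k <- as.integer(patchSize); stride <- as.integer(stride)
  if (k > H || k > W)
    stop(sprintf("patchSize %d exceeds image dimensions %d x %d", k, H, W))
  if (stride < 1L) stop("stride must be >= 1")
  if (channels == "rgbxy") {
    xy <- array(0, c(H, W, 2))
    xy[, , 1] <- matrix(if (W > 1) (seq_len(W) - 1) / (W - 1) else 0,
                        H, W, byrow = TRUE)
    xy[, , 2] <- matrix(if (H > 1) (seq_len(H) - 1) / (H - 1) else 0, H, W)
    img <- array(c(img, xy), c(H, W, 5L))
  }
  nchan <- dim(img)[3]
  tops <- seq(1L, H - k + 1L, by = stride)   # 1-based patch origins
  lefts <- seq(1L, W - k + 1L, by = stride)
  gr <- length(tops); gc <- length(lefts); n <- gr * gc
  vec <- matrix(0, n, k * k * nchan)
  for (ch in seq_len(nchan)) {
    plane <- img[, , ch]
    for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
      col <- (ch - 1L) * k * k + dr * k + dc + 1L
      vec[, col] <- as.vector(t(plane[tops + dr, lefts + dc, drop = FALSE]))
    }
  }
  off <- (k - 1) / 2
  centers <- cbind(rep(tops + off, each = gc), rep(lefts + off, times = gr))
  new("PatchGrid", patchVectors = vec, patchSize = k, stride = stride,
      gridRows = gr, gridCols = gc, centers = centers,
      sourceHeight = as.integer(H), sourceWidth = as.integer(W),
      channels = channels)
}

## Bilinear interpolation of a score lattice onto a pixel raster, anchored
## at the true patch centers: lattice node (i, j) sits at source-image
## position (c1r + (i-1) * strideR, c1c + (j-1) * strideC), and the source
## raster is mapped area-symmetrically onto the output raster.  Values are
## clamped (constant) beyond the outermost centers.
latticeToMap <- function(lattice, c1r, strideR, c1c, strideC,
                         srcH, srcW, outH, outW) {
  axis <- function(nLat, c1, spacing, nSrc, nOut) {
    p <- (seq_len(nOut) - 0.5) * (nSrc / nOut) + 0.5   # output centers in src px
    g <- if (nLat == 1L) rep(1, nOut) else (p - c1) / spacing + 1
    g <- pmin(pmax(g, 1), nLat)
    i0 <- pmin(floor(g), max(nLat - 1L, 1L))
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, nLat)),
         w = g - i0)
  }
  r <- axis(nrow(lattice), c1r, strideR, srcH, outH)
  cc <- axis(ncol(lattice), c1c, strideC, srcW, outW)
  wc <- matrix(cc$w, outH, outW, byrow = TRUE)
  top <- lattice[r$i0, cc$i0, drop = FALSE] * (1 - wc) +
    lattice[r$i0, cc$i1, drop = FALSE] * wc
  bot <- lattice[r$i1, cc$i0, drop = FALSE] * (1 - wc) +
    lattice[r$i1, cc$i1, drop = FALSE] * wc
  (1 - r$w) * top + r$w * bot
}

#' Reassemble per-patch scores into a saliency map
#'
#' Places one score per patch at that patch's center on the source-image
#' raster (raster order matching [extractPatches()]) and bilinearly
#' interpolates between centers, clamping beyond the outermost centers,
#' while mapping the source raster onto the requested output resolution.
#' Non-negativity is preserved (all interpolation weights are convex).
#'
#' @param values numeric vector of length `nPatches(grid)`.
#' @param grid the [PatchGrid-class] the scores belong to.
#' @param outHeight,outWidth target map resolution in pixels.
#' @return An (unnormalized) [SaliencyMap-class].
#' @export
assemblePatchMap <- function(values, grid, outHeight, outWidth) {
  stopifnot(is(grid, "PatchGrid"))
  if (length(values) != nPatches(grid))
    stop(sprintf("got %d scores for %d patches", length(values),
                 nPatches(grid)))
  lattice <- matrix(values, grid@gridRows, grid@gridCols, byrow = TRUE)
  off <- (grid@patchSize - 1) / 2
  SaliencyMap(latticeToMap(lattice, 1 + off, grid@stride, 1 + off,
                           grid@stride, grid@sourceHeight, grid@sourceWidth,
                           outHeight, outWidth))
}

#' Read an eye-fixation table
#'
#' Parses a CSV with header `image_id,x,y` where `x` is the 0-based column
#' and `y` the 0-based row pixel index of each fixation.  Use `origin = 1`
#' for files recorded with 1-based coordinates; coordinates are shifted to
#' the package's on-disk 0-based convention.
#'
#' @param path CSV file path.
#' @param origin 0 (default) or 1; the coordinate origin used in the file.
#' @return A `data.frame` with columns `image_id` (character), `x`, `y`
#'   (integer, 0-based).
#' @export
readFixations <- function(path, origin = 0L) {
  tab <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("fixation CSV must have columns image_id,x,y; found: ",
         paste(names(tab), collapse = ","))
  if (nrow(tab) == 0L)
    return(data.frame(image_id = character(), x = integer(), y = integer()))
  for (cn in c("x", "y")) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf(
        "fixation CSV %s: non-numeric or negative '%s' at data row %d ('%s')",
        path, cn, bad[1], tab[[cn]][bad[1]]))
    tab[[cn]] <- as.integer(round(v)) - as.integer(origin)
  }
  data.frame(image_id = tab$image_id, x = tab$x, y = tab$y,
             stringsAsFactors = FALSE)
}

#' Write an eye-fixation table
#'
#' @param fixations data.frame with columns `image_id`, `x`, `y` (0-based).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeFixations <- function(fixations, path) {
  utils::write.csv(fixations[, c("image_id", "x", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
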