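test_that("loadImage scales, replicates gray, and drops alpha", {
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 1, 0.5, 1), 2), tmp)   # grayscale 2x2
  img <- loadImage(tmp)
  expect_equal(dim(img), c(2L, 2L, 3L))
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
  expect_equal(max(img), 1)                         # 8-bit 255 -> exactly 1

  rgba <- array(runif(2 * 3 * 4), c(2, 3, 4))
  png::writePNG(rgba, tmp)
  img <- loadImage(tmp)
  expect_equal(dim(img), c(2L, 3L, 3L))             # alpha dropped
})

test_that("loadImage fails cleanly on missing or undecodable files", {
  expect_error(loadImage("/nonexistent/file.png"), "file not found")
  tmp <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(1:32), tmp)                       # not a PNG
  expect_error(loadImage(tmp), "PNG/JPEG")
})

test_that("bilinear resize: identity, constants, and the 2x2 -> 1x1 mean", {
  m <- matrix(runif(35), 5, 7)
  expect_identical(resizeBilinear(m, 5, 7), m)      # value-for-value
  expect_equal(resizeBilinear(matrix(0.3, 4, 4), 9, 2),
               matrix(0.3, 9, 2))
  expect_equal(resizeBilinear(matrix(c(0, 1, 1, 0), 2), 1, 1)[1, 1], 0.5)
  expect_error(resizeBilinear(m, 0, 3))
})

test_that("bilinear resize never leaves the input range", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(runif(120), 10, 12)
    out <- resizeBilinear(m, sample(1:25, 1), sample(1:25, 1))
    expect_gte(min(out), min(m))
    expect_lte(max(out), max(m))
  }
})

test_that("patch extraction: grid geometry and error contracts", {
  img <- array(runif(60 * 80 * 3), c(60, 80, 3))
  g <- extractPatches(img, 5, 1)                    # 80x60 (W x H) image
  expect_equal(c(g@gridRows, g@gridCols), c(56L, 76L))
  expect_equal(nPatches(g), 4256L)
  expect_equal(ncol(patchVectors(g)), 75L)

  img2 <- array(runif(512 * 512 * 3), c(512, 512, 3))
  g2 <- extractPatches(img2, 8, 8)
  expect_equal(c(g2@gridRows, g2@gridCols), c(64L, 64L))
  expect_equal(nPatches(g2), 4096L)

  expect_error(extractPatches(array(runif(48), c(4, 4, 3)), 5, 1),
               "exceeds image dimensions")
})

test_that("patch vectorization is raster-ordered, channel-concatenated", {
  img <- gradientImage(6, 8)
  g <- extractPatches(img, 2, 2)
  # patch (1,1) occupies rows 1:2, cols 1:2; vector is row-major per channel
  expect_equal(patchVectors(g)[1, ],
               c(t(img[1:2, 1:2, 1]), t(img[1:2, 1:2, 2]),
                 t(img[1:2, 1:2, 3])))
  # second patch in raster order is grid position (1,2) -> cols 3:4
  expect_equal(patchVectors(g)[2, 1:4], c(t(img[1:2, 3:4, 1])))
  # centers are fractional for even patch sizes
  expect_equal(patchCenters(g)[1, ], c(1.5, 1.5))
})

test_that("stride = patchSize tiles the image exactly", {
  img <- gradientImage(12, 16)
  g <- extractPatches(img, 4, 4)
  expect_equal(nPatches(g) * 16L, 12L * 16L)
  # each pixel appears exactly once: per-channel sums match
  expect_equal(sum(patchVectors(g)), sum(img))
})

test_that("extract + reassemble per-patch means of a constant is exact", {
  img <- array(0.37, c(12, 16, 3))
  g <- extractPatches(img, 4, 4)
  means <- rowMeans(patchVectors(g))
  out <- assemblePatchMap(means, g, 12, 16)
  expect_equal(mapValues(out), matrix(0.37, 12, 16))
})

test_that("assemblePatchMap handles constants, single patches, midpoints", {
  img <- gradientImage(4, 4)
  g <- extractPatches(img, 2, 2)                    # 2x2 lattice
  out <- mapValues(assemblePatchMap(c(0, 1, 1, 0), g, 3, 3))
  expect_equal(out[2, 2], 0.5)                      # bilinear midpoint
  expect_true(all(out >= 0))

  g1 <- extractPatches(img, 4, 4)                   # single patch
  expect_equal(mapValues(assemblePatchMap(0.8, g1, 5, 6)),
               matrix(0.8, 5, 6))
  expect_error(assemblePatchMap(1:3, g, 3, 3), "scores")
})

test_that("fixation CSV round trip, origin offset, and parse errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  fix <- data.frame(image_id = c("a", "a", "b"), x = c(0L, 5L, 2L),
                    y = c(1L, 3L, 0L))
  writeFixations(fix, tmp)
  expect_equal(readFixations(tmp), fix)
  shifted <- readFixations(tmp, origin = 1L)
  expect_equal(shifted$x, fix$x - 1L)

  writeLines("image_id,x,y", tmp)
  expect_equal(nrow(readFixations(tmp)), 0L)        # empty data section

  writeLines(c("image_id,x,y", "a,1,2", "a,a,2"), tmp)
  expect_error(readFixations(tmp), "row 2")
  writeLines(c("image_id,col,row", "a,1,2"), tmp)
  expect_error(readFixations(tmp), "image_id,x,y")
})

test_that("saliency maps write as stretched PNG plus bit-faithful CSV", {
  m <- matrix(runif(30), 5, 6)
  tmpPng <- withr::local_tempfile(fileext = ".png")
  tmpCsv <- withr::local_tempfile(fileext = ".csv")
  writeSaliencyMap(SaliencyMap(m), tmpPng, tmpCsv)
  back <- as.matrix(utils::read.csv(tmpCsv, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, m)                             # CSV is exact
  stretched <- png::readPNG(tmpPng)
  expect_equal(range(stretched), c(0, 1), tolerance = 1 / 255)
})
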