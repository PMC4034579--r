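test_that("complete adaptive dictionary inverts exactly", {
  set.seed(1)
  img <- array(runif(20 * 24 * 3), c(20, 24, 3))    # full-rank patches
  g <- extractPatches(img, 3, 2)
  d <- learnAdaptiveDictionary(g, seed = 1L)
  WA <- dictionaryUnmixing(d) %*% dictionaryBasis(d)
  expect_lt(max(abs(WA - diag(27))), 1e-6)
  # learn -> encode -> reconstruct is exact for m' = d, any seed
  for (s in c(0L, 5L)) {
    ds <- learnAdaptiveDictionary(g, seed = s)
    rec <- reconstructPatches(encodePatches(g, ds))
    expect_lt(max(abs(rec - patchVectors(g))), 1e-6)
  }
})

test_that("ICA recovers a known mixing up to permutation/sign/scale", {
  sim <- mixedSources(4000, 9, seed = 11)
  d <- learnAdaptiveDictionary(sim$X, nComponents = 9, seed = 1L)
  P <- dictionaryUnmixing(d) %*% sim$A0
  expect_lt(amariIndex(P), 0.1)
})

test_that("codes of mixed sparse sources are more leptokurtic than inputs", {
  sim <- mixedSources(4000, 9, seed = 23)
  d <- learnAdaptiveDictionary(sim$X, nComponents = 9, seed = 1L)
  codes <- sweep(sim$X, 2, d@dimensionMeans) %*% t(dictionaryUnmixing(d))
  kurt <- function(v) mean((v - mean(v))^4) / stats::var(v)^2 - 3
  excessCodes <- mean(apply(codes, 2, kurt))
  excessMixed <- mean(apply(sim$X, 2, kurt))
  expect_gt(excessCodes, 0)                         # leptokurtic codes
  expect_gt(excessCodes, excessMixed)               # sparser than mixtures
})

test_that("encoding is centering plus projection", {
  idDict <- new("AdaptiveDictionary", basis = diag(12), unmixing = diag(12),
                dimensionMeans = rep(0, 12), converged = TRUE, seed = 0L)
  img <- gradientImage(4, 6)
  g <- extractPatches(img, 2, 2)
  expect_equal(codeMatrix(encodePatches(g, idDict)), patchVectors(g))

  # a patch equal to the dimension means encodes to an all-zero row
  mu <- patchVectors(g)[3, ]
  muDict <- new("AdaptiveDictionary", basis = diag(12), unmixing = diag(12),
                dimensionMeans = mu, converged = TRUE, seed = 0L)
  expect_equal(codeMatrix(encodePatches(g, muDict))[3, ], rep(0, 12))
  # all-zero codes reconstruct to the dimension means
  cs <- encodePatches(g, muDict)
  cs@codes[] <- 0
  expect_equal(reconstructPatches(cs)[1, ], mu)
})

test_that("own-image complete dictionary beats a foreign undercomplete one", {
  imgs <- lapply(1:4, function(s) generateNaturalImage(30, 40, seed = s))
  target <- extractPatches(imgs[[1]], 3, 2)
  own <- learnAdaptiveDictionary(target, seed = 0L)
  ownRes <- max(abs(reconstructPatches(encodePatches(target, own)) -
                      patchVectors(target)))
  expect_lt(ownRes, 1e-6)                           # lossless when m' = d

  foreignPatches <- do.call(rbind, lapply(imgs[-1], function(im)
    patchVectors(extractPatches(im, 3, 2))))
  fixed <- learnAdaptiveDictionary(foreignPatches, nComponents = 12L,
                                   seed = 0L)
  Xc <- sweep(patchVectors(target), 2, fixed@dimensionMeans)
  rec <- Xc %*% t(fixed@unmixing) %*% t(fixed@basis)
  fixedRes <- max(abs(rec - Xc))
  expect_gt(fixedRes, ownRes)                       # information is lost
})

test_that("a constant image has no dictionary", {
  img <- array(0.5, c(20, 20, 3))
  g <- extractPatches(img, 3, 2)
  expect_error(learnAdaptiveDictionary(g),
               class = "degenerateDictionaryError")
})

test_that("sparse saliency of a constant image is a zero map", {
  img <- array(0.5, c(32, 32, 3))
  expect_warning(m <- sparseSaliencyMap(img, smallSparseConfig()),
                 "degenerate")
  expect_equal(max(mapValues(m)), 0)
})

test_that("sparse saliency is seed-deterministic; centering removes DC", {
  img <- generateNaturalImage(30, 40, seed = 2) * 0.6 + 0.1
  m1 <- sparseSaliencyMap(img, smallSparseConfig(seed = 3L))
  m2 <- sparseSaliencyMap(img, smallSparseConfig(seed = 3L))
  expect_identical(mapValues(m1), mapValues(m2))

  # a global intensity shift is absorbed by the per-dimension centering:
  # under a common dictionary, shifted patches encode identically, so the
  # CSD scores (and hence the map) cannot see the shift
  g <- extractPatches(img, 5, 2)
  gShift <- extractPatches(img + 0.15, 5, 2)        # stays inside [0, 1]
  dict <- learnAdaptiveDictionary(g, seed = 3L)
  dictShift <- dict                                 # same basis, new means
  dictShift@dimensionMeans <- colMeans(patchVectors(gShift))
  codes <- codeMatrix(encodePatches(g, dict))
  codesShift <- codeMatrix(encodePatches(gShift, dictShift))
  expect_lt(max(abs(codes - codesShift)), 1e-10)
  s1 <- csdScores(codes, patchCenters(g), extent = c(30, 40))
  s2 <- csdScores(codesShift, patchCenters(gShift), extent = c(30, 40))
  expect_lt(max(abs(s1 - s2)), 1e-10)
})

test_that("a single high-contrast patch dominates the sparse map", {
  img <- array(0.45, c(30, 40, 3))
  img[, , 1] <- 0.45 + matrix(rnorm(1200, 0, 0.01), 30)  # mild texture
  img[, , 1] <- pmin(pmax(img[, , 1], 0), 1)
  img[14:19, 20:25, 1] <- 1                          # bright red block
  img[14:19, 20:25, 2:3] <- 0
  m <- mapValues(sparseSaliencyMap(img, smallSparseConfig()))
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_true(am[1] >= 11 && am[1] <= 22 && am[2] >= 17 && am[2] <= 28)
})
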