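test_that("csd scores reproduce the three-patch hand computation", {
  s <- csdScores(matrix(c(0, 0, 3)), cbind(0, c(0, 1, 2)))
  expect_equal(s, c(0.5, 0.75, 1.25))
})

test_that("csd scores: zeros on uniform features, homogeneity, equivariance", {
  feats <- matrix(0.7, 9, 4)
  cent <- cbind(rep(1:3, each = 3), rep(1:3, 3))
  expect_equal(csdScores(feats, cent), rep(0, 9))
  expect_equal(csdScores(feats, cent, average = "weight"), rep(0, 9))

  set.seed(41)
  f <- matrix(rnorm(60), 12, 5); ctr <- matrix(runif(24), 12, 2)
  expect_equal(csdScores(2 * f, ctr), 2 * csdScores(f, ctr))

  perm <- sample(12)
  expect_equal(csdScores(f[perm, ], ctr[perm, ]), csdScores(f, ctr)[perm])
})

test_that("vectorized csd agrees with the brute-force double loop", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(2:60, 1); q <- sample(1:8, 1)
    f <- matrix(rnorm(n * q), n, q)
    ctr <- matrix(runif(2 * n), n, 2)
    for (avg in c("count", "weight"))
      expect_lt(max(abs(csdScores(f, ctr, average = avg) -
                          csdOracle(f, ctr, avg))), 1e-10)
  }
})

test_that("center normalization by extent matches manual scaling", {
  f <- matrix(rnorm(10), 5, 2)
  ctr <- cbind(seq(1, 9, 2), seq(1, 5, 1))
  byExtent <- csdScores(f, ctr, extent = c(9, 5))
  manual <- csdScores(f, cbind((ctr[, 1] - 1) / 8, (ctr[, 2] - 1) / 4))
  expect_equal(byExtent, manual)
})

test_that("distance damping is monotone: remoter deviants contribute less", {
  f <- matrix(c(0, 0, 5), 3, 1)
  near <- csdScores(f, cbind(0, c(0, 0.2, 0.4)))
  far <- csdScores(f, cbind(0, c(0, 0.2, 0.9)))
  expect_lt(far[1], near[1])                        # deviant moved away
  expect_lt(far[2], near[2])
})

test_that("single patch scores zero with a warning", {
  expect_warning(s <- csdScores(matrix(1), matrix(c(1, 1), 1)), "fewer")
  expect_equal(s, 0)
})

test_that("map normalization: endpoints, constants, idempotence", {
  expect_equal(normalizeMap(matrix(c(2, 4), 1)), matrix(c(0, 1), 1))
  expect_equal(normalizeMap(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_equal(normalizeMap(matrix(7, 2, 2)), matrix(1, 2, 2))
  set.seed(3)
  m <- matrix(runif(40), 5, 8)
  expect_equal(normalizeMap(normalizeMap(m)), normalizeMap(m))
  sm <- normalizeMap(SaliencyMap(m))
  expect_s4_class(sm, "SaliencyMap")
  expect_true(isNormalized(sm))
  expect_identical(normalizeMap(sm), sm)            # idempotent on S4 too
})

test_that("multiscale combination multiplies and renormalizes", {
  m <- matrix(c(0, 0.5, 1, 0.25), 2)
  single <- multiscaleCombine(list(m))
  expect_equal(mapValues(single), normalizeMap(m))

  two <- multiscaleCombine(list(matrix(c(0, 0.5, 1), 1),
                                matrix(c(0, 0.5, 1), 1)))
  expect_equal(mapValues(two), matrix(c(0, 0.25, 1), 1))

  withOnes <- multiscaleCombine(list(m, matrix(1, 2, 2)))
  expect_equal(mapValues(withOnes), normalizeMap(m))

  expect_error(multiscaleCombine(list()), "non-empty")
  expect_error(multiscaleCombine(list(m, matrix(1, 3, 3))), "resolution")
})

test_that("gaussian smoothing matches a direct 2-D kernel on an impulse", {
  H <- 41; W <- 41; sigma <- 3
  m <- matrix(0, H, W); m[21, 21] <- 1
  sm <- gaussianSmooth(m, sigma)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  expected <- outer(k, k)                           # separable 2-D kernel
  expect_lt(max(abs(sm[(21 - r):(21 + r), (21 - r):(21 + r)] - expected)),
            1e-6)
  expect_identical(gaussianSmooth(m, 0), m)         # sigma = 0 is identity
  expect_equal(sum(sm), 1, tolerance = 1e-12)       # reflective: mass kept
})

test_that("fusion identities: all-ones partner, zero annihilator", {
  sp <- SaliencyMap(normalizeMap(matrix(runif(24), 4, 6)), normalized = TRUE)
  ones <- SaliencyMap(matrix(1, 4, 6))
  out <- fuseAndSmooth(sp, ones, fusionConfig(sigmaFraction = 0), 4, 6)
  expect_equal(mapValues(out), mapValues(sp))

  zero <- SaliencyMap(matrix(0, 4, 6))
  out0 <- fuseAndSmooth(sp, zero, fusionConfig(), 4, 6)
  expect_equal(max(mapValues(out0)), 0)
})

test_that("full model: constant image yields an all-zero map", {
  img <- array(0.6, c(32, 32, 3))
  out <- suppressWarnings(
    runFullModel(img, smallSparseConfig(), smallCovConfig()))
  expect_equal(max(mapValues(out)), 0)
  expect_equal(dim(mapValues(out)), c(32L, 32L))    # native resolution
})

test_that("full model is deterministic for a fixed seed", {
  img <- generateNaturalImage(32, 32, seed = 9)
  o1 <- runFullModel(img, smallSparseConfig(seed = 2L), smallCovConfig())
  o2 <- runFullModel(img, smallSparseConfig(seed = 2L), smallCovConfig())
  expect_identical(mapValues(o1), mapValues(o2))
})

test_that("final maps stay in [0, 1] regardless of the input route", {
  img <- generateNaturalImage(24, 28, seed = 4)
  img8 <- round(img * 255) / 255                    # 8-bit quantized copy
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img8, tmp)
  viaFile <- runFullModel(loadImage(tmp), smallSparseConfig(),
                          smallCovConfig())
  direct <- runFullModel(img8, smallSparseConfig(), smallCovConfig())
  expect_identical(mapValues(viaFile), mapValues(direct))
  expect_gte(min(mapValues(viaFile)), 0)
  expect_lte(max(mapValues(viaFile)), 1)
})
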