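# Shared fixtures and independent oracles, all built in code.

# deterministic smooth test image (no RNG)
gradientImage <- function(H = 24, W = 32) {
  r <- matrix(seq(0, 1, length.out = H), H, W)
  g <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
  array(c(r, g, (r + g) / 2), c(H, W, 3L))
}

# brute-force CSD oracle: plain double loop over patch pairs
csdOracle <- function(features, centers, average = "count") {
  n <- nrow(features)
  num <- numeric(n); mass <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      w <- 1 / (1 + sqrt(sum((centers[i, ] - centers[j, ])^2)))
      num[i] <- num[i] + w * sum(abs(features[i, ] - features[j, ]))
      mass[i] <- mass[i] + w
    }
  }
  if (average == "count") num / (n - 1) else num / mass
}

# brute-force rank-AUC oracle: exhaustive pair counting, ties = 1/2
aucOracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# Amari separation index of P = W %*% A0; 0 iff P is a scaled permutation
amariIndex <- function(P) {
  m <- abs(P)
  rowTerm <- sum(rowSums(m / apply(m, 1, max)) - 1)
  colTerm <- sum(colSums(t(t(m) / apply(m, 2, max))) - 1)
  (rowTerm + colTerm) / (2 * nrow(m) * (nrow(m) - 1))
}

# Laplacian-sparse sources mixed by a random square A0 (seeded)
mixedSources <- function(n, d, seed) {
  set.seed(seed)
  S0 <- matrix(sign(stats::rnorm(n * d)) * stats::rexp(n * d), n, d)
  A0 <- matrix(stats::rnorm(d * d), d, d)
  list(X = S0 %*% t(A0), A0 = A0, S0 = S0)
}

# small isotropic Gaussian blob map centered in an H x W frame
gaussianBlobMap <- function(H, W, sigmaFraction = 0.25) {
  s <- sigmaFraction * W
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry <- exp(-((seq_len(H) - cy)^2) / (2 * s^2))
  rx <- exp(-((seq_len(W) - cx)^2) / (2 * s^2))
  outer(ry, rx)
}

# fast configs so end-to-end tests stay light
smallSparseConfig <- function(seed = 0L)
  sparseBranchConfig(resolutionW = 40L, resolutionH = 30L, seed = seed)
smallCovConfig <- function()
  covBranchConfig(resolution = 64L, patchSizes = c(8L, 16L))
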