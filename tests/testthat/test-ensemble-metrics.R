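test_that("radius of gyration matches hand-computed geometries", {
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(10, 0, 0))), 5)
  expect_equal(radiusOfGyration(matrix(2, 4, 3)), 0)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radiusOfGyration(sq), sqrt(0.5))
  expect_error(radiusOfGyration(matrix(0, 1, 3)), "at least 2")
})

test_that("radius of gyration is rigid-transform invariant", {
  withr::with_seed(71, {
    x <- matrix(stats::rnorm(60), 20, 3)
    r0 <- radiusOfGyration(x)
    for (rep in 1:5) {
      q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      shift <- stats::rnorm(3, sd = 50)
      y <- x %*% q + matrix(shift, 20, 3, byrow = TRUE)
      expect_lt(abs(radiusOfGyration(y) - r0), 1e-10)
    }
  })
})

test_that("free-energy differences equal kT log count ratios", {
  # two equal-width bins holding n and 2n samples: dF = kT log 2
  samples <- c(rep(0.25, 1000), rep(0.75, 2000))
  prof <- freeEnergyProfile(samples, nBins = 5, allowSmall = FALSE)
  F <- prof$F[!is.na(prof$F)]
  expect_equal(length(F), 2L)
  expect_equal(max(F) - min(F), log(2))
  expect_equal(min(F), 0)
  # kT scales linearly
  prof2 <- freeEnergyProfile(samples, nBins = 5, kT = 2.5)
  F2 <- prof2$F[!is.na(prof2$F)]
  expect_equal(max(F2), 2.5 * log(2))
})

test_that("a uniform observable has a flat profile", {
  withr::with_seed(99, u <- stats::runif(1e5))
  prof <- freeEnergyProfile(u, nBins = 20)
  expect_lt(max(abs(prof$F), na.rm = TRUE), 0.1)
})

test_that("Gaussian samples yield the quadratic closed-form profile", {
  withr::with_seed(100, x <- stats::rnorm(2e5))
  prof <- freeEnergyProfile(x, nBins = 80)
  ok <- !is.na(prof$F)
  Fat <- stats::approx(prof$center[ok], prof$F[ok], xout = c(-1, 0, 1))$y
  # F(mu +- sigma) - F(mu) = kT/2 up to binning error
  expect_lt(abs((Fat[1L] - Fat[2L]) - 0.5), 0.06)
  expect_lt(abs((Fat[3L] - Fat[2L]) - 0.5), 0.06)
})

test_that("degenerate identical samples produce a single-bin profile", {
  expect_warning(prof <- freeEnergyProfile(rep(1, 200)), "identical")
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$F, 0)
})

test_that("pair distance distributions are normalized point estimates", {
  one <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 11.4, 0, 0), 4, 3,
                byrow = TRUE)
  ens <- ensembleFromArray(array(rep(one, each = 10),
                                 dim = c(10, 4, 3)))
  # identical conformers: point mass in one bin
  dd <- pairwiseDistanceDistribution(ens, 1, 4)
  expect_equal(sum(dd$p), 1)
  expect_equal(nrow(dd), 1L)
  expect_error(pairDistances(ens, 2, 2), "differ")
  expect_error(pairDistances(ens, 3, 2), "i < j")

  withr::with_seed(8, coords <- array(stats::rnorm(50 * 6 * 3), c(50, 6, 3)))
  dd <- pairwiseDistanceDistribution(ensembleFromArray(coords), 1, 6, 12)
  expect_equal(sum(dd$p), 1, tolerance = 1e-12)
})

test_that("contact maps honor the cutoff and sequence-separation mask", {
  # residues 1-2 bonded at 3.8 A: masked; residues 1 and 5 placed at 8 A
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(30, 0, 0), c(60, 0, 0),
               c(8, 0, 0))
  cm <- contactMap(ensembleFromArray(xyz), cutoff = 9.5, minSeqSep = 3)
  m <- contactMatrix(cm)
  expect_equal(m[1, 2], 0)   # |i-j| < 3
  expect_equal(m[1, 5], 1)   # 8 A <= 9.5 A, separation 4
  expect_equal(m[1, 4], 0)   # 60 A apart
  expect_true(isSymmetric(m))
})

test_that("contact probabilities move by at most 1/n per added conformer", {
  withr::with_seed(12, coords <- array(stats::rnorm(21 * 8 * 3, sd = 4),
                                       c(21, 8, 3)))
  full <- contactMatrix(contactMap(ensembleFromArray(coords), 9.5, 2))
  part <- contactMatrix(contactMap(
    ensembleFromArray(coords[1:20, , , drop = FALSE]), 9.5, 2))
  expect_lt(max(abs(full - part)), 1 / 21 + 1e-12)
  expect_true(all(full >= 0 & full <= 1))
})

test_that("contact PCA matches a brute-force covariance eigen-oracle", {
  withr::with_seed(31, coords <- array(stats::rnorm(40 * 15 * 3, sd = 3),
                                       c(40, 15, 3)))
  ens <- ensembleFromArray(coords)
  pca <- contactPCA(ens, cutoff = 9.5, minSeqSep = 3, nModes = 2)

  # oracle: explicit binary contact matrix, stats::cov, base eigen
  pairs <- expand.grid(i = 1:15, j = 1:15)
  pairs <- pairs[pairs$j - pairs$i >= 3, ]
  pairs <- pairs[order(pairs$j, pairs$i), ]
  X <- t(vapply(seq_len(40), function(k) {
    xyz <- conformer(ens, k)
    d <- as.matrix(stats::dist(xyz))
    as.numeric(d[cbind(pairs$i, pairs$j)] <= 9.5)
  }, numeric(nrow(pairs))))
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(pca@eigenvalues, eg$values[1:2], tolerance = 1e-8)
  for (m in 1:2) {
    v <- eg$vectors[, m]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_lt(max(abs(pca@modes[, m] - v)), 1e-8)
  }
  # spectral identity: total variance is preserved
  expect_equal(sum(eg$values), sum(diag(stats::cov(X))), tolerance = 1e-8)
  # orthonormality of the returned modes
  expect_lt(max(abs(crossprod(pca@modes) - diag(2))), 1e-8)
})

test_that("mutually exclusive contact sets load PC1 with opposite signs", {
  # 20 residues far apart on a line; type A brings residue 10 to residue 1,
  # type B brings residue 20 to residue 11
  base <- cbind(12 * (0:19), 0, 0)
  mkA <- function() { x <- base; x[10, ] <- c(0, 5, 0); x }
  mkB <- function() { x <- base; x[20, ] <- c(12 * 10, 5, 0); x }
  coords <- array(NA_real_, c(20, 20, 3))
  for (k in 1:10) coords[k, , ] <- mkA()
  for (k in 11:20) coords[k, , ] <- mkB()
  pca <- contactPCA(ensembleFromArray(coords), 9.5, 3, 2)
  pi1 <- pca@pairIndex
  cA <- pca@modes[pi1$i == 1 & pi1$j == 10, 1]
  cB <- pca@modes[pi1$i == 11 & pi1$j == 20, 1]
  expect_true(abs(cA) > 0.1 && abs(cB) > 0.1)
  expect_lt(cA * cB, 0)
})

test_that("degenerate ensembles are rejected by contact PCA", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(30, 0, 0),
               c(34, 0, 0))
  coords <- array(rep(xyz, each = 5), c(5, 5, 3))
  expect_error(contactPCA(ensembleFromArray(coords), 9.5, 3, 2),
               "degenerate")
})

test_that("turn propensity is zero for straight chains, one for tight bends", {
  straight <- cbind(3.8 * (0:9), 0, 0)
  tp <- turnPropensity(ensembleFromArray(straight))
  expect_true(all(tp[4:7] == 0))
  expect_true(all(is.na(tp[c(1:3, 8:10)])))

  # square bend at residues 4..7: d(4,7) = 3.8 A, internal angles 90 deg
  bend <- rbind(c(-11.4, 0, 0), c(-7.6, 0, 0), c(-3.8, 0, 0), c(0, 0, 0),
                c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0), c(0, 7.6, 0),
                c(-3.8, 7.6, 0), c(-7.6, 7.6, 0))
  tp <- turnPropensity(ensembleFromArray(bend))
  expect_equal(tp[4], 1)
})

test_that("PAGE4 region definitions are the canonical segments", {
  reg <- pageRegions()
  expect_identical(reg$n_motif, 4:12)
  expect_identical(reg$central_acidic, 43:62)
  expect_identical(reg$transient_helix, 65:73)
  expect_identical(reg$c_motif, 82:95)
})
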