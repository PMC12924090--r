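test_that("DCT high-pass removes drift, keeps pass-band signal, zeroes constants", {
  tt <- seq(0, 597, by = 3)                      # 200 volumes at TR 3
  drift <- cbind(0.05 * tt)                      # pure linear drift
  fd <- dctHighpass(drift, trS = 3, cutoffHz = 0.01)
  expect_lt(var(fd[, 1]), 0.10 * var(drift[, 1]))

  sine <- cbind(sin(2 * pi * 0.05 * tt))         # 0.05 Hz, well above cutoff
  fs <- dctHighpass(sine, trS = 3, cutoffHz = 0.01)
  expect_gt(var(fs[, 1]), 0.90 * var(sine[, 1]))

  const <- cbind(rep(7, 200))
  expect_equal(max(abs(dctHighpass(const, trS = 3))), 0)

  expect_error(dctHighpass(sine, trS = 3, cutoffHz = 0.2), "Nyquist")
})

test_that("scans with non-uniform sampling refuse frequency-domain filtering", {
  scan <- BoldScan(array(rnorm(4 * 4 * 3 * 40), c(4, 4, 3, 40)), trS = 3)
  ext <- extractVolumes(scan, c(0:5, 12:20))
  expect_error(dctHighpass(ext, trS = 3), "BEFORE")
  expect_error(denoiseScan(ext, BrainMask(array(TRUE, c(4, 4, 3)))), "BEFORE")
  # the full scan filters fine
  expect_s4_class(dctHighpass(scan, trS = 3), "BoldScan")
})

test_that("CompCor keeps the smallest component count reaching the variance threshold", {
  set.seed(4)
  # rank-1 noise matrix
  u <- rnorm(30); w <- runif(12)
  r1 <- outer(u, w)
  cc <- compcorComponents(r1, 0.5)
  expect_equal(ncol(cc), 1)
  expect_gt(abs(cor(cc[, 1], u - mean(u))), 1 - 1e-8)
  # orthonormal over time
  expect_equal(unname(crossprod(cc)), diag(1), tolerance = 1e-10)

  # threshold 1 -> full rank
  X <- matrix(rnorm(30 * 5), 30, 5)
  expect_equal(ncol(compcorComponents(X, 1.0)), 5)

  # two equal-variance sources mixed into 10 voxels: k satisfies the
  # cumulative-variance contract, checked against a direct eigen oracle
  s1 <- rnorm(200); s2 <- rnorm(200)
  M <- cbind(s1, s2) %*% matrix(rnorm(20), 2, 10)
  cc2 <- compcorComponents(M, 0.5)
  k <- ncol(cc2)
  Xc <- sweep(M, 2, colMeans(M))
  ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  cumvar <- cumsum(ev) / sum(ev)
  expect_gte(cumvar[k], 0.5)
  if (k > 1) expect_lt(cumvar[k - 1], 0.5)

  expect_error(compcorComponents(matrix(0, 10, 3)), "degenerate")
  expect_error(compcorComponents(matrix(1:10, 10, 1)), "2 noise voxels")
})

test_that("motion expansion yields the 24-regressor set", {
  set.seed(8)
  m <- matrix(rnorm(30), 5, 6)
  e <- motionExpansion(m)
  expect_equal(ncol(e), 24)
  expect_equal(nrow(e), 5)

  # independent finite-difference oracle on a hand-sized example
  m3 <- matrix(c(1, 2, 4,  0, 1, 3,  2, 2, 2,  1, 0, 1,  5, 5, 6,  0, 2, 4),
               3, 6)
  e3 <- motionExpansion(m3)
  for (j in 1:6) {
    dj <- c(0, m3[-1, j] - m3[-3, j])
    expect_equal(unname(e3[, 6 + j]), dj)
    expect_equal(unname(e3[, 12 + j]), m3[, j]^2)
    expect_equal(unname(e3[, 18 + j]), dj^2)
  }

  cm <- motionExpansion(matrix(3, 4, 6))
  expect_true(all(cm[, 7:12] == 0))              # constant motion -> zero derivatives
  expect_error(motionExpansion(matrix(0, 5, 5)), "6 motion")
})

test_that("confound regression orthogonalizes, standardizes and is idempotent", {
  set.seed(10)
  arr <- array(rnorm(3 * 3 * 2 * 50), c(3, 3, 2, 50))
  conf <- cbind(rnorm(50), rnorm(50))
  arr[1, 1, 1, ] <- conf[, 1] * 2 + 5            # voxel equal to a confound
  scan <- BoldScan(arr, trS = 2)
  mask <- BrainMask(array(TRUE, c(3, 3, 2)))

  res <- regressConfounds(scan, mask, conf, standardize = FALSE)
  expect_lt(max(abs(scanData(res)[1, 1, 1, ])), 1e-8 * max(abs(arr[1, 1, 1, ])))
  R <- t(asVoxelMatrixForTest(scanData(res)))
  ortho <- abs(cor(R[, apply(R, 2, sd) > 0], conf))
  expect_lt(max(ortho), 1e-8)

  std <- regressConfounds(scan, mask, conf, standardize = TRUE)
  sds <- apply(asVoxelMatrixForTest(scanData(std)), 1, sd)
  expect_equal(unname(sds[sds > 0]), rep(1, sum(sds > 0)), tolerance = 1e-6)

  twice <- regressConfounds(std, mask, conf, standardize = TRUE)
  expect_equal(scanData(twice), scanData(std), tolerance = 1e-8)

  expect_warning(regressConfounds(scan, mask, cbind(conf, conf[, 1]),
                                  standardize = FALSE), "rank-deficient")
})

test_that("Gaussian smoothing has the stated kernel width and mass behaviour", {
  expect_equal(fwhmToSigma(6, 3), 6 / (2 * sqrt(2 * log(2)) * 3))
  expect_equal(round(fwhmToSigma(6, 3), 4), 0.8493)

  const <- BoldScan(array(5, c(8, 8, 6, 2)), trS = 1)
  expect_equal(scanData(smoothGaussian(const, 6)), scanData(const),
               tolerance = 1e-12)

  # interior delta (beyond the kernel's reach of any edge): mass 1
  arr <- array(0, c(19, 19, 17, 1)); arr[10, 10, 9, 1] <- 1
  sm <- smoothGaussian(BoldScan(arr, trS = 1), 6)
  expect_equal(sum(scanData(sm)), 1, tolerance = 1e-6)
  # smoothing never increases the max of a nonnegative volume
  expect_lte(max(scanData(sm)), 1)

  set.seed(3)
  pos <- array(abs(rnorm(8 * 8 * 6 * 2)), c(8, 8, 6, 2))
  smp <- smoothGaussian(BoldScan(pos, trS = 1), 8)
  expect_lte(max(scanData(smp)), max(pos))

  expect_error(smoothGaussian(const, 0), "positive")
})

test_that("per-volume operations commute with rest extraction", {
  spec <- smallSpec()
  sub <- simulateSubject(spec, taskProtocol = smallTaskProtocol(),
                         restProtocol = smallRestProtocol(), seed = 7)
  mask <- fullMask(spec)
  idx <- restVolumeIndices(makeBlockDesign(smallTaskProtocol()),
                           ExtractionScheme(3, 2, 5))
  den <- denoiseScan(sub$task, mask, cutoffHz = 0.01, fwhmMm = 6)
  # extracting from the denoised series selects exactly those volumes
  ext <- extractVolumes(den, idx)
  expect_identical(scanData(ext), scanData(den)[, , , idx + 1L])
  # smoothing (a purely per-volume operation) commutes with extraction
  a <- extractVolumes(smoothGaussian(sub$task, 6), idx)
  b <- smoothGaussian(extractVolumes(sub$task, idx), 6)
  expect_equal(scanData(a), scanData(b), tolerance = 1e-12)
})
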