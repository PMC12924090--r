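# build a valid ICADecomposition from given maps (helper for matching tests)
decompFromMaps <- function(maps, mask) {
  z <- t(apply(maps, 1, function(r) (r - mean(r)) / sd(r)))
  new("ICADecomposition", spatialMaps = z,
      mixing = matrix(rnorm(20 * nrow(maps)), 20, nrow(maps)),
      nComponents = nrow(maps), seed = 0L, mask = mask)
}

test_that("subject concatenation stacks variance-normalized blocks", {
  spec <- smallSpec()
  mask <- fullMask(spec)
  scans <- lapply(1:3, function(k)
    simulateSubject(spec, taskProtocol = smallTaskProtocol(),
                    restProtocol = restProtocol(216, 3), seed = k)$rest)  # 72 vols
  X <- concatSubjects(scans, mask)
  expect_equal(nrow(X), 3 * 72)
  expect_equal(ncol(X), sum(maskData(mask)))
  for (b in 1:3) {
    blk <- X[(b - 1) * 72 + 1:72, ]
    expect_equal(sum(apply(blk, 2, var)), 1, tolerance = 1e-10)
  }
  one <- concatSubjects(scans[1], mask)
  expect_equal(one, X[1:72, ])

  short <- extractVolumes(scans[[1]], 0:8)
  expect_error(concatSubjects(list(short), mask), "10 volumes")
})

test_that("spatial ICA recovers planted sources and is seed-deterministic", {
  set.seed(7)
  V <- 800; Tn <- 60
  S <- matrix(0, 3, V)
  S[1, 1:40] <- 3; S[2, 101:140] <- 3; S[3, 201:260] <- 2
  S <- S + matrix(rnorm(3 * V, sd = 0.05), 3)
  X <- matrix(rnorm(Tn * 3), Tn, 3) %*% S
  mask <- BrainMask(array(TRUE, c(V, 1, 1)))

  dec <- spatialIca(X, 3, seed = 1, mask = mask)
  cc <- abs(cor(t(spatialMaps(dec)), t(S)))
  # each source matched by some component up to sign/permutation
  expect_true(all(apply(cc, 2, max) > 0.95))

  dec2 <- spatialIca(X, 3, seed = 1, mask = mask)
  expect_identical(spatialMaps(dec), spatialMaps(dec2))
  expect_identical(mixingMatrix(dec), mixingMatrix(dec2))

  expect_error(spatialIca(X[1:2, ], 3, seed = 1, mask = mask), "at least 3")
})

test_that("mixing x maps reconstructs the data up to the PCA-discarded variance", {
  set.seed(12)
  Tn <- 40; V <- 500
  # sources must be non-Gaussian (here skewed) for the ICA model to apply
  X <- matrix(rnorm(Tn * 5), Tn, 5) %*% matrix(rexp(5 * V) - 1, 5, V) +
    matrix(rnorm(Tn * V, sd = 0.3), Tn, V)
  mask <- BrainMask(array(TRUE, c(V, 1, 1)))
  n <- 5
  dec <- spatialIca(X, n, seed = 2, mask = mask)
  Xc <- sweep(X, 2, colMeans(X)); Xc <- Xc - rowMeans(Xc)
  Xhat <- mixingMatrix(dec) %*% spatialMaps(dec)
  resid <- sum((Xc - Xhat)^2)
  ev <- eigen(tcrossprod(Xc) / V, symmetric = TRUE, only.values = TRUE)$values
  discarded <- sum(ev[-seq_len(n)]) * V
  expect_lt(resid, discarded * (1 + 1e-6) + 1e-8)
})

test_that("template matching picks the right component regardless of sign or order", {
  spec <- smallSpec()
  mask <- fullMask(spec)
  template <- specTemplateAtlas(spec)
  V <- sum(maskData(mask))
  tmplVec <- as.numeric(labelMap(template)[maskData(mask)] == 1)  # alpha

  set.seed(5)
  maps <- rbind(rnorm(V), tmplVec, rnorm(V))
  dec <- decompFromMaps(maps, mask)
  m <- matchToTemplate(dec, template, "alpha")
  expect_equal(m@component, 2L)
  expect_equal(m@r, 1, tolerance = 1e-10)
  expect_equal(m@sign, 1)

  # negated template map: selected with r = 1 after sign alignment
  decNeg <- decompFromMaps(rbind(rnorm(V), -tmplVec, rnorm(V)), mask)
  mNeg <- matchToTemplate(decNeg, template, "alpha")
  expect_equal(mNeg@component, 2L)
  expect_equal(mNeg@r, 1, tolerance = 1e-10)
  expect_equal(mNeg@sign, -1)

  # reordering the components moves the index but not the correlation
  decPerm <- decompFromMaps(maps[c(3, 1, 2), ], mask)
  mPerm <- matchToTemplate(decPerm, template, "alpha")
  expect_equal(mPerm@component, 3L)
  expect_equal(mPerm@r, m@r, tolerance = 1e-10)

  expect_error(matchToTemplate(dec, template, "gamma"), "unknown")
})

test_that("map thresholding is monotone and may select nothing", {
  set.seed(6)
  m <- array(rnorm(24 * 24 * 18), c(24, 24, 18))
  lo <- thresholdMap(m, 1); hi <- thresholdMap(m, 2)
  expect_true(all(which(hi) %in% which(lo)))     # higher threshold -> subset
  expect_false(any(thresholdMap(m, 99)))         # empty selection allowed
})

test_that("intersection labelling finds spatially distinct ROIs", {
  dm <- c(16, 12, 8)
  a <- array(FALSE, dm); b <- array(FALSE, dm)
  blob1 <- cbind(2:6, 3, 3)                      # 5-voxel line
  blob2 <- cbind(10:15, 8, 5)                    # 6-voxel line
  a[blob1] <- a[blob2] <- TRUE
  b[blob1] <- b[blob2] <- TRUE
  b[1, 1, 1] <- TRUE                             # only in b: must vanish

  atlas <- intersectAndLabel(a, b, minSize = 5, connectivity = 26)
  expect_length(roiLabels(atlas), 2)
  sizes <- tabulate(labelMap(atlas)[labelMap(atlas) > 0])
  expect_equal(sizes, c(6, 5))                   # descending size order

  # identical masks: intersection is the mask itself
  same <- intersectAndLabel(a, a, minSize = 5)
  expect_equal(labelMap(same) > 0, a)
  # commutative
  swapped <- intersectAndLabel(b, a, minSize = 5, connectivity = 26)
  expect_identical(labelMap(swapped), labelMap(atlas))

  # a 3-voxel blob is dropped at minSize 5
  c3 <- array(FALSE, dm); c3[cbind(2:4, 2, 2)] <- TRUE
  expect_error(intersectAndLabel(c3, c3, minSize = 5), "minimum ROI size")
  expect_length(roiLabels(intersectAndLabel(c3, c3, minSize = 3)), 1)

  expect_error(intersectAndLabel(a, !a, minSize = 1), "empty")
})

test_that("ROI count is non-increasing in the size threshold", {
  set.seed(9)
  m <- array(rnorm(20 * 20 * 10), c(20, 20, 10)) > 1.2
  counts <- vapply(c(1, 2, 4, 8), function(ms) {
    length(roiLabels(intersectAndLabel(m, m, minSize = ms)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
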