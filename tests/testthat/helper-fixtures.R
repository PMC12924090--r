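# Shared fixtures, all generated in code.

# small planted-network spec for fast module tests: two networks on a
# 14 x 14 x 10 grid
smallSpec <- function(alphaBeta = 0.3) {
  rois <- data.frame(
    name = c("a1", "a2", "b1"),
    x = c(4, 10, 7), y = c(4, 4, 10), z = c(5, 5, 5),
    radius = 2,
    network = c("alpha", "alpha", "beta"),
    loading = c(1.0, 0.8, 1.0),
    stringsAsFactors = FALSE)
  S <- matrix(c(1, alphaBeta, alphaBeta, 1), 2,
              dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  NetworkSpec(gridShape = c(14L, 14L, 10L), voxelSizeMm = 3, rois = rois,
              networkCovariance = S, taskNetworks = "beta")
}

smallTaskProtocol <- function() ScanProtocol(trS = 3, nVolumes = 80L,
                                             blockLenS = 30, nBlockPairs = 4L,
                                             startsWith = "rest")
smallRestProtocol <- function() restProtocol(durationS = 180, trS = 3)  # 60 vols

fullMask <- function(spec) BrainMask(array(TRUE, spec@gridShape),
                                     affine = diag(c(rep(spec@voxelSizeMm, 3), 1)))

quietNoise <- function(whiteSd = 1) NoiseModel(whiteSd = whiteSd, driftAmp = 0,
                                               ar1Phi = 0, baseline = 100)

# Independent brute-force oracle for interleaved rest extraction: literal
# per-volume evaluation of the selection rule over the label sequence.
bruteForceRestIndices <- function(labels, d0, keep, d5) {
  n <- length(labels)
  blockId <- cumsum(c(1L, as.integer(labels[-1] != labels[-n])))
  restBlockIds <- unique(blockId[labels == "rest"])
  firstRestBlock <- if (length(restBlockIds)) min(restBlockIds) else NA_integer_
  kept <- integer(0)
  for (i in seq_len(n)) {
    b <- blockId[i]
    posInBlock <- sum(blockId[seq_len(i)] == b) - 1L   # 0-based
    keepIt <- if (labels[i] == "rest") {
      if (b == firstRestBlock) posInBlock >= d0 else posInBlock >= d5
    } else {
      posInBlock < keep
    }
    if (keepIt) kept <- c(kept, i - 1L)                # 0-based volume index
  }
  kept
}

# random contiguous block design with block lengths that keep every scheme
# count feasible
randomBlockDesign <- function(minBlockLen = 6L, maxBlockLen = 12L,
                              maxBlocks = 8L) {
  nb <- sample(2:maxBlocks, 1)
  lens <- sample(minBlockLen:maxBlockLen, nb, replace = TRUE)
  start <- sample(c("rest", "task"), 1)
  vals <- rep(c(start, setdiff(c("rest", "task"), start)), length.out = nb)
  BlockDesign(rep(vals, times = lens))
}

# cached expensive pipeline runs shared across test files
.fixtureCache <- new.env(parent = emptyenv())

demoReport <- function() {
  if (is.null(.fixtureCache$demo)) {
    .fixtureCache$demo <- runValidation(validationConfig(),
                                        outDir = file.path(tempdir(), "demo_run"))
  }
  .fixtureCache$demo
}

symmetryReport <- function() {
  if (is.null(.fixtureCache$symmetry)) {
    .fixtureCache$symmetry <- runValidation(
      validationConfig(symmetryControl = TRUE),
      outDir = file.path(tempdir(), "symmetry_run"))
  }
  .fixtureCache$symmetry
}

# flatten a 4-D array to voxels x time (test-local reshaper)
asVoxelMatrixForTest <- function(arr4d) matrix(arr4d, ncol = dim(arr4d)[4])

# Dice coefficient of two index sets (test-local)
diceForTest <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))
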