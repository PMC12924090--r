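test_that("the blocked protocol retains 72 volumes with the documented pattern", {
  design <- makeBlockDesign(taskProtocol())
  idx <- restVolumeIndices(design, fairScheme())
  expect_length(idx, 72)                         # 7 + 10*2 + 9*5
  expect_equal(idx[1:7], 3:9)                    # first rest block minus 3
  expect_true(all(c(10, 11) %in% idx))           # task-block starts kept
  expect_false(any(c(12, 20, 21) %in% idx))      # task body / rest discard dropped
  expect_true(all(diff(idx) > 0))

  labs <- designLabels(design)
  blockId <- cumsum(c(1L, as.integer(labs[-1] != labs[-200])))
  posInBlock <- sequence(rle(labs)$lengths) - 1L
  keptLabs <- labs[idx + 1L]
  # every retained index is rest-labelled or among the first 2 of a task block
  expect_true(all(keptLabs == "rest" | posInBlock[idx + 1L] < 2))
})

test_that("rest extraction agrees with the literal per-volume oracle", {
  set.seed(42)
  for (i in 1:50) {
    design <- randomBlockDesign()
    d0 <- sample(0:3, 1); keep <- sample(0:3, 1); d5 <- sample(0:5, 1)
    scheme <- ExtractionScheme(d0, keep, d5)
    got <- tryCatch(restVolumeIndices(design, scheme), error = function(e) e)
    want <- bruteForceRestIndices(designLabels(design), d0, keep, d5)
    if (length(want) == 0) {
      expect_s3_class(got, "error")
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("degenerate schemes and blocks are rejected with useful messages", {
  design <- BlockDesign(rep(c("rest", "task", "rest", "task"), each = 2))
  expect_error(restVolumeIndices(design, ExtractionScheme(0, 0, 5)),
               "shorter than its discard")
  expect_error(restVolumeIndices(design, ExtractionScheme(0, 3, 0)),
               "shorter than its keep")
  # 0/0/0 keeps every rest volume and nothing from task blocks
  idx <- restVolumeIndices(design, ExtractionScheme(0, 0, 0))
  expect_equal(idx, which(designLabels(design) == "rest") - 1L)
  # everything discarded -> empty-result error
  allTask <- BlockDesign(rep("task", 10))
  expect_error(restVolumeIndices(allTask, ExtractionScheme(0, 0, 0)),
               "no volumes")
})

test_that("extractVolumes subsets volumes and keeps original acquisition times", {
  set.seed(2)
  arr <- array(rnorm(4 * 4 * 3 * 20), c(4, 4, 3, 20))
  scan <- BoldScan(arr, trS = 3)

  one <- extractVolumes(scan, 0L)
  expect_equal(scanData(one)[, , , 1], arr[, , , 1])
  expect_equal(nVolumes(one), 1)

  ident <- extractVolumes(scan, 0:19)
  expect_identical(scanData(ident), arr)
  expect_identical(volumeTimes(ident), volumeTimes(scan))

  sub <- extractVolumes(scan, c(3L, 10L, 11L))
  expect_equal(volumeTimes(sub), c(9, 30, 33))   # original times preserved
  expect_equal(scanData(sub)[, , , 2], arr[, , , 11])

  expect_error(extractVolumes(scan, c(0L, 20L)), "out of range")
  expect_error(extractVolumes(scan, c(5L, 5L)), "strictly increasing")
})

test_that("the 72-volume extraction of the blocked scan starts 9 s in", {
  spec <- smallSpec()
  sub <- simulateSubject(spec, seed = 1)
  idx <- restVolumeIndices(makeBlockDesign(taskProtocol()), fairScheme())
  out <- extractVolumes(sub$task, idx)
  expect_equal(nVolumes(out), 72)
  expect_equal(volumeTimes(out)[1], 9.0)         # index 3 at TR 3 s
})

test_that("middle subsampling takes the centred segment with floor tie-break", {
  arr <- array(seq_len(2 * 2 * 2 * 170), c(2, 2, 2, 170))
  scan <- BoldScan(arr, trS = 3)
  mid <- middleSubsample(scan, 72)
  expect_equal(nVolumes(mid), 72)
  expect_equal(volumeTimes(mid)[1], 49 * 3)      # start index floor((170-72)/2)=49
  expect_equal(scanData(mid)[, , , 1], arr[, , , 50])
  expect_equal(scanData(mid)[, , , 72], arr[, , , 121])

  five <- BoldScan(array(1:5, c(1, 1, 1, 5)), trS = 1)
  two <- middleSubsample(five, 2)
  expect_equal(as.numeric(scanData(two)), c(2, 3))   # start floor(1.5) = 1

  expect_identical(scanData(middleSubsample(scan, 170)), arr)
  expect_error(middleSubsample(scan, 171), "exceeds")
  expect_error(middleSubsample(scan, 0), "positive")
})

test_that("retained indices round-trip through the sidecar formats", {
  idx <- restVolumeIndices(makeBlockDesign(taskProtocol()), fairScheme())
  fj <- tempfile(fileext = ".json")
  writeIndexSidecar(idx, fj)
  expect_equal(unlist(jsonlite::read_json(fj)), idx)
  ft <- tempfile(fileext = ".txt")
  writeIndexSidecar(idx, ft)
  expect_equal(as.integer(readLines(ft)), idx)
})
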