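test_that("block design expands the protocol into contiguous labels", {
  d <- makeBlockDesign(taskProtocol())
  labs <- designLabels(d)
  expect_length(labs, 200)
  expect_equal(labs[1:10], rep("rest", 10))     # volumes 0-9
  expect_equal(labs[11:20], rep("task", 10))    # volumes 10-19
  expect_equal(sum(labs == "task"), 100)

  tiny <- ScanProtocol(trS = 2, nVolumes = 2L, blockLenS = 2, nBlockPairs = 1L)
  expect_equal(designLabels(makeBlockDesign(tiny)), c("rest", "task"))

  expect_error(ScanProtocol(trS = 3, nVolumes = 10L, blockLenS = 7,
                            nBlockPairs = 1L), "divisible")
  expect_equal(designLabels(makeBlockDesign(smallRestProtocol())),
               rep("rest", 60))
})

test_that("canonical HRF has the conventional double-gamma shape", {
  expect_equal(canonicalHrf(0), 0)
  grid <- seq(0, 32, by = 0.1)
  h <- canonicalHrf(grid)
  expect_equal(max(h), 1, tolerance = 1e-4)     # unit peak normalization
  expect_lt(abs(grid[which.max(h)] - 5.0), 0.2)
  expect_lt(abs(canonicalHrf(32)), 0.01 * max(h))
  expect_lt(min(h), 0)                          # undershoot exists
  expect_error(canonicalHrf(-1), ">= 0")
})

test_that("simulated subjects have the protocol volume counts and are seed-reproducible", {
  spec <- smallSpec()
  s1 <- simulateSubject(spec, seed = 3)         # default protocols
  expect_equal(nVolumes(s1$task), 200)
  expect_equal(nVolumes(s1$rest), 170)
  expect_equal(s1$truth@conditionLabels,
               designLabels(makeBlockDesign(taskProtocol())))

  s2 <- simulateSubject(spec, seed = 3)
  expect_identical(scanData(s1$task), scanData(s2$task))
  expect_identical(scanData(s1$rest), scanData(s2$rest))
  s3 <- simulateSubject(spec, seed = 4)
  expect_false(identical(scanData(s3$rest), scanData(s1$rest)))
})

test_that("long noiseless runs recover the planted correlation structure", {
  spec <- smallSpec(alphaBeta = 0.4)
  noiseless <- NoiseModel(whiteSd = 0, driftAmp = 0, ar1Phi = 0, baseline = 0)
  sub <- simulateSubject(spec, taskProtocol = smallTaskProtocol(),
                         restProtocol = restProtocol(15000, 3),  # 5000 volumes
                         noise = noiseless, seed = 11)
  ts <- roiTimeseries(sub$rest, specRoiAtlas(spec))
  emp <- cor(t(ts))
  expect_lt(max(abs(emp - sub$truth@roiCorrelation)), 0.05)
  # ground truth: same-network 1, across-network the latent correlation
  expect_equal(sub$truth@roiCorrelation["a1", "a2"], 1)
  expect_equal(sub$truth@roiCorrelation["a1", "b1"], 0.4)
})

test_that("task blocks raise task-network ROI signal in the task scan", {
  spec <- smallSpec()
  sub <- simulateSubject(spec, taskProtocol = smallTaskProtocol(),
                         restProtocol = smallRestProtocol(),
                         noise = quietNoise(), seed = 9, taskAmplitude = 3)
  ts <- roiTimeseries(sub$task, specRoiAtlas(spec))
  labs <- designLabels(makeBlockDesign(smallTaskProtocol()))
  taskRoi <- ts["b1", ]                         # beta is the task network
  expect_gt(mean(taskRoi[labs == "task"]), mean(taskRoi[labs == "rest"]))
  # non-task network unaffected in expectation: difference small
  restRoi <- ts["a1", ]
  expect_lt(abs(mean(restRoi[labs == "task"]) - mean(restRoi[labs == "rest"])),
            abs(mean(taskRoi[labs == "task"]) - mean(taskRoi[labs == "rest"])))
})

test_that("cohort generation shifts only the designated pair and is stream-stable", {
  spec <- smallSpec()
  c0 <- simulateCohort(2, spec = spec, effect = 0, seed = 21,
                       pair = c("alpha", "beta"),
                       taskProtocol = smallTaskProtocol(),
                       restProtocol = smallRestProtocol())
  expect_identical(c0$specA@networkCovariance, c0$specB@networkCovariance)

  c1 <- simulateCohort(2, spec = spec, effect = 0.3, seed = 21,
                       pair = c("alpha", "beta"),
                       taskProtocol = smallTaskProtocol(),
                       restProtocol = smallRestProtocol())
  expect_equal(c1$specB@networkCovariance["alpha", "beta"], 0.6)
  expect_equal(c1$specB@networkCovariance["alpha", "alpha"], 1)

  # subject k does not depend on the cohort size
  c2 <- simulateCohort(3, spec = spec, effect = 0.3, seed = 21,
                       pair = c("alpha", "beta"),
                       taskProtocol = smallTaskProtocol(),
                       restProtocol = smallRestProtocol())
  expect_identical(scanData(c1$subjects[[2]]$rest),
                   scanData(c2$subjects[[2]]$rest))

  expect_error(simulateCohort(1, spec = spec, effect = 0, seed = 1), ">= 2")
  expect_error(simulateCohort(2, spec = spec, effect = 0.9, seed = 1,
                              pair = c("alpha", "beta"),
                              taskProtocol = smallTaskProtocol(),
                              restProtocol = smallRestProtocol()),
               "positive-definite")
})

test_that("a planted group effect shows up with the right sign in Fisher z", {
  spec <- smallSpec(alphaBeta = 0.2)
  cohort <- simulateCohort(8, spec = spec, effect = 0.3, seed = 33,
                           pair = c("alpha", "beta"),
                           taskProtocol = smallTaskProtocol(),
                           restProtocol = restProtocol(510, 3),
                           noise = quietNoise())
  atlas <- specRoiAtlas(spec)
  zAB <- vapply(cohort$subjects, function(s) {
    zValues(fisherZMatrix(roiTimeseries(s$rest, atlas)))["a1", "b1"]
  }, numeric(1))
  grp <- vapply(cohort$subjects, `[[`, character(1), "group")
  expect_gt(mean(zAB[grp == "B"]) - mean(zAB[grp == "A"]), 0)
})

test_that("a cohort can be written to disk with its ground-truth sidecar", {
  spec <- smallSpec()
  cohort <- simulateCohort(2, spec = spec, effect = 0, seed = 5,
                           pair = c("alpha", "beta"),
                           taskProtocol = smallTaskProtocol(),
                           restProtocol = smallRestProtocol())
  dir <- file.path(tempdir(), "cohort_out")
  writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "sub-01_task.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth_rois.nii.gz")))
  side <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  expect_equal(side$seed, 5)
  expect_equal(unlist(side$roiNames), c("a1", "a2", "b1"))
  back <- loadScan(file.path(dir, "sub-01_rest.nii.gz"), trS = 3)
  expect_equal(scanData(back), scanData(cohort$subjects[[1]]$rest),
               tolerance = 1e-4)
})
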