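test_that("generated splits have exact sizes, counts and determinism", {
  spec <- syntheticSpec(nTrain = 50, nVal = 20, nTest = 100,
                        positiveFraction = 0.7, seed = 9)
  sets <- generateSyntheticData(spec)
  expect_equal(length(sets$train), 50L)
  expect_equal(length(sets$validation), 20L)
  expect_equal(length(sets$test), 100L)
  expect_equal(sum(labels(sets$test) == 1L), 70L)
  expect_equal(sum(labels(sets$train) == 1L), 35L)
  expect_equal(splitRole(sets$validation), "validation")
  # ids are unique across splits
  allIds <- c(imageIds(sets$train), imageIds(sets$validation),
              imageIds(sets$test))
  expect_equal(anyDuplicated(allIds), 0L)
  # pixel-level determinism
  sets2 <- generateSyntheticData(spec)
  expect_identical(images(sets2$train), images(sets$train))
  expect_identical(labels(sets2$test), labels(sets$test))
  # different seed, different pixels
  sets3 <- generateSyntheticData(syntheticSpec(nTrain = 50, nVal = 20,
                                               nTest = 100, seed = 10))
  expect_false(identical(images(sets3$train), images(sets$train)))
  # container invariants hold
  expect_true(validObject(sets$train))
  expect_null(generateSyntheticData(syntheticSpec(nTrain = 10, nVal = 0,
                                                  nTest = 10))$validation)
})

test_that("motif sensitivity flags match the construction", {
  expect_true(motifSensitivityCheck("corner_marker", "rotation"))
  expect_true(motifSensitivityCheck("corner_marker", "tilt"))
  expect_false(motifSensitivityCheck("corner_marker", "blur"))
  expect_true(motifSensitivityCheck("fine_texture", "blur"))
  expect_true(motifSensitivityCheck("band_intensity", "contrast"))
  expect_false(motifSensitivityCheck("plain_blob", "rotation"))
  # any motif degrades under strong enough noise
  for (m in c("corner_marker", "fine_texture", "band_intensity",
              "plain_blob"))
    expect_true(motifSensitivityCheck(m, "noise"))
  expect_error(motifSensitivityCheck("stripes", "blur"))
})

test_that("rotation degrades the corner-marker classifier as designed", {
  sets <- generateSyntheticData(syntheticSpec(nTrain = 200, nVal = 0,
                                              nTest = 100, seed = 17))
  f <- trainBaseline(sets$train, seed = 1)
  clean <- evaluateClassifier(f, sets$test)$errorRate
  rot <- resamplePerturbedTestSets(sets$test,
    testResampleSpec(100, "rotation", nReplicates = 5, seed = 2))
  rotErr <- mean(vapply(rot, function(s)
    evaluateClassifier(f, s)$errorRate, numeric(1)))
  expect_gt(rotErr, clean + 0.1)
})

test_that("blur at raised severity degrades the fine-texture motif", {
  sets <- generateSyntheticData(syntheticSpec(nTrain = 200, nVal = 0,
                                              nTest = 100,
                                              motif = "fine_texture",
                                              seed = 19))
  f <- trainBaseline(sets$train, seed = 1)
  clean <- evaluateClassifier(f, sets$test)$errorRate
  cfg <- perturbationConfig(blurKernel = 5, blurSigma = 2)
  blurSets <- resamplePerturbedTestSets(sets$test,
    testResampleSpec(100, "blur", nReplicates = 3, seed = 3), cfg)
  blurErr <- mean(vapply(blurSets, function(s)
    evaluateClassifier(f, s)$errorRate, numeric(1)))
  expect_gt(blurErr, clean + 0.1)
  # and the mean SSIM drops accordingly
  expect_lt(meanSetSsim(sets$test, blurSets[1]), 0.99)
})

test_that("synthetic sets round-trip through the archive format", {
  sets <- generateSyntheticData(syntheticSpec(nTrain = 10, nVal = 0,
                                              nTest = 10, seed = 23))
  path <- file.path(withr::local_tempdir(), "synth.rds")
  saveImageSet(sets$test, path)
  back <- loadImageSet(path, split = "test")
  expect_identical(images(back), images(sets$test))
  expect_identical(labels(back), labels(sets$test))
})
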