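test_that("training-set replacement keeps size, ids, labels and order", {
  train <- makeTestSet(10, size = 10, split = "train", seed = 31)
  spec <- trainVariantSpec(20, "noise", seed = 5)
  out <- buildPerturbedTrainingSet(train, spec)
  expect_equal(length(out), 10L)
  expect_identical(labels(out), labels(train))
  expect_identical(imageIds(out), imageIds(train))
  # exactly k = round(20 * 10 / 100) = 2 images replaced
  idx <- attr(out, "perturbedIndex")
  expect_equal(length(idx), 2L)
  changed <- which(vapply(seq_len(10), function(i)
    !identical(images(out)[[i]], images(train)[[i]]), logical(1)))
  expect_equal(changed, idx)
  # fraction 0 is the identity; empty set errors
  expect_identical(buildPerturbedTrainingSet(
    train, trainVariantSpec(0, "none")), train)
  expect_error(buildPerturbedTrainingSet(
    LabeledImageSet(list(), integer(), character()),
    spec), "empty")
})

test_that("fraction 100 replaces every image (noise severity)", {
  train <- makeTestSet(8, size = 9, split = "train", seed = 32)
  out <- buildPerturbedTrainingSet(train, trainVariantSpec(100, "noise", 3))
  expect_equal(attr(out, "perturbedIndex"), 1:8)
  differs <- vapply(1:8, function(i)
    !identical(images(out)[[i]], images(train)[[i]]), logical(1))
  expect_true(all(differs))
})

test_that("rounding of the perturbed count is half-up", {
  # 20% of 624 = 124.8 -> 125; 50% of 5 = 2.5 -> 3
  train <- makeTestSet(5, size = 8, split = "train", seed = 33)
  out <- buildPerturbedTrainingSet(train, trainVariantSpec(50, "noise", 1))
  expect_equal(length(attr(out, "perturbedIndex")), 3L)
  out2 <- resamplePerturbedTestSets(makeTestSet(7, 8, seed = 34),
                                    testResampleSpec(50, "noise", 2, 1))
  expect_equal(length(attr(out2[[1]], "perturbedIndex")), 4L)  # 3.5 -> 4
})

test_that("variant enumeration yields baseline + fraction x kind grid", {
  v <- enumerateVariants()
  expect_equal(length(v), 26L)
  expect_equal(v[[1]]@kind, "none")
  expect_equal(v[[1]]@fractionP, 0)
  keys <- vapply(v[-1], function(s) paste(s@kind, s@fractionP), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(length(enumerateVariants(kinds = character())), 1L)
  expect_equal(length(enumerateVariants(40, "blur")), 2L)
  expect_error(enumerateVariants(c(20, 20), "blur"), "duplicate")
  # distinct deterministic seeds per variant
  seeds <- vapply(v, function(s) s@seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_identical(seeds,
    vapply(enumerateVariants(), function(s) s@seed, integer(1)))
})

test_that("test-set resampling is replicate-exact and deterministic", {
  test <- makeTestSet(20, size = 9, split = "test", seed = 35)
  spec <- testResampleSpec(25, "noise", nReplicates = 6, seed = 9)
  reps <- resamplePerturbedTestSets(test, spec)
  expect_equal(length(reps), 6L)
  for (r in reps) {
    expect_equal(length(attr(r, "perturbedIndex")), 5L)  # 25% of 20
    expect_identical(labels(r), labels(test))
    expect_identical(imageIds(r), imageIds(test))
  }
  # selections differ across replicates with high probability
  sel <- vapply(reps, function(r)
    paste(attr(r, "perturbedIndex"), collapse = ","), character(1))
  expect_gt(length(unique(sel)), 1L)
  # bitwise determinism under the same seed
  reps2 <- resamplePerturbedTestSets(test, spec)
  expect_identical(lapply(reps, images), lapply(reps2, images))
  # fraction 0: every replicate is the clean set
  clean <- resamplePerturbedTestSets(test, testResampleSpec(0, "noise", 3, 1))
  expect_identical(lapply(clean, images), rep(list(images(test)), 3))
})

test_that("per-image perturbation frequency follows the sampling design", {
  # N = 100, fraction 20, 200 replicates: each image perturbed 40/200
  # times on average (exactly, by the fixed per-replicate count), with
  # binomial spread across images
  test <- makeTestSet(100, size = 8, split = "test", seed = 36)
  reps <- resamplePerturbedTestSets(test,
    testResampleSpec(20, "noise", nReplicates = 200, seed = 4))
  counts <- integer(100)
  for (r in reps) {
    idx <- attr(r, "perturbedIndex")
    expect_equal(length(idx), 20L)
    counts[idx] <- counts[idx] + 1L
  }
  expect_equal(sum(counts), 200L * 20L)  # mean is exactly 40 per image
  # binomial(200, 0.2): sd ~ 5.7; all counts within ~5 sigma of 40
  expect_true(all(counts > 12 & counts < 68))
  expect_gt(sd(counts), 2)
})

test_that("multi-perturbation training groups are disjoint with half spared", {
  train <- makeTestSet(100, size = 9, split = "train", seed = 37)
  out <- buildMultiperturbedTrainingSet(train, multiPerturbSpec(seed = 6))
  expect_equal(length(out), 100L)
  expect_identical(labels(out), labels(train))
  groups <- attr(out, "perturbedGroups")
  expect_equal(sort(names(groups)), sort(perturbationKinds()))
  expect_true(all(lengths(groups) == 10L))
  allIdx <- unlist(groups)
  expect_equal(anyDuplicated(allIdx), 0L)  # pairwise disjoint
  expect_equal(length(setdiff(1:100, allIdx)), 50L)  # half untouched
  untouched <- setdiff(1:100, allIdx)
  expect_true(all(vapply(untouched, function(i)
    identical(images(out)[[i]], images(train)[[i]]), logical(1))))
  # all-zero fractions: identity
  z <- multiPerturbSpec(trainFractionPerKind =
                          setNames(rep(0, 5), perturbationKinds()))
  expect_identical(images(buildMultiperturbedTrainingSet(train, z)),
                   images(train))
  # fractions above 1 rejected at construction
  expect_error(multiPerturbSpec(trainFractionPerKind =
                                  setNames(rep(0.3, 5), perturbationKinds())),
               "sum")
})

test_that("multi-perturbation test draws are Bernoulli per image and kind", {
  test <- makeTestSet(200, size = 8, split = "test", seed = 38)
  spec <- multiPerturbSpec(nReplicates = 10, seed = 12)
  reps <- buildMultiperturbedTestSets(test, spec)
  expect_equal(length(reps), 10L)
  zeroFrac <- mean(vapply(reps, function(r)
    mean(rowSums(attr(r, "kindAssignments")) == 0), numeric(1)))
  # P(no kind applied) = 0.5^5 = 0.03125; 2000 draws, sd ~ 0.0039
  expect_lt(abs(zeroFrac - 0.5^5), 4 * sqrt(0.03125 * (1 - 0.03125) / 2000))
  # untouched images are bitwise-identical to the clean set
  r1 <- reps[[1]]
  zero <- which(rowSums(attr(r1, "kindAssignments")) == 0)
  for (i in zero)
    expect_identical(images(r1)[[i]], images(test)[[i]])
  # probability 0: all replicates equal the clean set
  p0 <- multiPerturbSpec(testProbabilityPerKind = 0, nReplicates = 2)
  expect_identical(lapply(buildMultiperturbedTestSets(test, p0), images),
                   rep(list(images(test)), 2))
  # probability 1: every image receives all five kinds
  p1 <- multiPerturbSpec(testProbabilityPerKind = 1, nReplicates = 1)
  expect_true(all(attr(buildMultiperturbedTestSets(test, p1)[[1]],
                       "kindAssignments")))
})

test_that("one master seed fixes the whole pipeline", {
  train <- makeTestSet(30, size = 9, split = "train", seed = 39)
  run <- function() {
    v <- enumerateVariants(c(20, 60), c("noise", "rotation"), masterSeed = 77)
    lapply(v, function(s) images(buildPerturbedTrainingSet(train, s)))
  }
  expect_identical(run(), run())
})
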