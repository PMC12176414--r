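test_that("error rate is the misclassified proportion", {
  y <- rep(c(1L, 0L), 50)
  p <- y; p[1:15] <- 1L - p[1:15]
  expect_equal(errorRate(y, p), 0.15)
  expect_equal(errorRate(y, y), 0)
  expect_equal(errorRate(y, 1L - y), 1)
  expect_error(errorRate(integer(), integer()), "empty")
  expect_error(errorRate(c(1, 0), c(1)), "length")
  # complement of accuracy on random draws
  withr::with_seed(8, {
    yt <- sample(0:1, 40, replace = TRUE)
    yp <- sample(0:1, 40, replace = TRUE)
  })
  expect_equal(errorRate(yt, yp) + mean(yt == yp), 1)
})

test_that("precision/recall follow the contingency counts", {
  expect_equal(precisionRecall(c(1, 0, 1), c(1, 0, 1))[c("precision", "recall")],
               list(precision = 1, recall = 1))
  # all predicted positive, half truly positive
  pr <- precisionRecall(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 1)
  # TP=3 FP=1 FN=2
  yt <- c(1, 1, 1, 1, 1, 0, 0)
  yp <- c(1, 1, 1, 0, 0, 1, 0)
  pr <- precisionRecall(yt, yp)
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.6)
  # undefined precision flagged, not fatal
  expect_warning(pr0 <- precisionRecall(c(1, 0), c(0, 0)), "precision")
  expect_equal(pr0$precision, 0)
  expect_true(pr0$undefinedPrecision)
})

test_that("SSIM matches its closed forms and reference implementation", {
  x <- randomImage(16, seed = 6)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- randomImage(16, seed = 7)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_true(abs(ssim(x, y)) <= 1)
  # zero-variance closed form: (2*100*150 + C1) / (100^2 + 150^2 + C1)
  C1 <- (0.01 * 255)^2
  expect_equal(ssim(matrix(100, 16, 16), matrix(150, 16, 16)),
               (2 * 100 * 150 + C1) / (100^2 + 150^2 + C1),
               tolerance = 1e-12)
  # frozen cross-check against scikit-image structural_similarity
  # (gaussian_weights, sigma 1.5, win 11, data_range 255) on a
  # deterministic 24x24 pair
  i <- 0:23
  a <- outer(i, i, function(r, cc) (r * 7 + cc * 13) %% 256)
  b <- floor(a * 0.9 + 20)
  expect_equal(ssim(a, b), 0.988193783487846, tolerance = 1e-9)
  expect_error(ssim(x, matrix(0, 4, 4)), "dimension")
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("set-level SSIM averages per-image similarities and checks ids", {
  s <- makeTestSet(4, size = 14, seed = 21)
  expect_equal(meanSetSsim(s, list(s, s), winSize = 11), 1)
  one <- s[1:4]  # aligned copy
  expect_equal(meanSetSsim(s, one, winSize = 11), 1)
  perm <- s[c(2, 1, 3, 4)]
  expect_error(meanSetSsim(s, list(perm)), "aligned")
  # single pair degenerates to plain ssim
  a <- makeTestSet(1, size = 14, seed = 1)
  b <- LabeledImageSet(list(applyGaussianNoise(images(a)[[1]], 0.1, seed = 2)),
                       labels(a), imageIds(a), split = "test")
  expect_equal(meanSetSsim(a, list(b), winSize = 11),
               ssim(images(a)[[1]], images(b)[[1]]))
})

test_that("replicate summaries match a direct two-pass computation", {
  expect_error(summarizeReplicates(list()), "no replicate")
  same <- replicate(5, evalResult(c(1, 0), c(1, 1)), simplify = FALSE)
  s <- summarizeReplicates(same)
  expect_equal(s$meanError, 0.5)
  expect_equal(s$sdError, 0)
  two <- list(evalResult(rep(1, 10), c(rep(1, 9), 0)),
              evalResult(rep(1, 10), c(rep(1, 8), 0, 0)))
  expect_equal(summarizeReplicates(two)$meanError, 0.15)
  # 200 simulated replicates against mean()/sd() recomputation, and
  # invariance under permutation of the replicates
  withr::with_seed(13, {
    res <- lapply(1:200, function(i) {
      yt <- sample(0:1, 50, replace = TRUE)
      yp <- ifelse(runif(50) < 0.2, 1 - yt, yt)
      evalResult(yt, yp)
    })
  })
  s <- summarizeReplicates(res)
  errs <- vapply(res, `[[`, numeric(1), "errorRate")
  expect_equal(s$meanError, mean(errs))
  expect_equal(s$sdError, sd(errs))
  expect_equal(summarizeReplicates(rev(res))$meanError, s$meanError)
  expect_equal(summarizeReplicates(rev(res))$sdError, s$sdError)
})
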