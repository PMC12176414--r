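test_that("zero-severity settings are exact identities", {
  img <- randomImage(14, seed = 2)
  intImg <- img; storage.mode(intImg) <- "integer"
  expect_identical(applyGaussianNoise(img, 0), intImg)
  expect_identical(applyContrast(img, 1), intImg)
  expect_identical(applyRotation(img, 0), intImg)
  expect_identical(applyTilt(img, 0), intImg)
  expect_identical(applyBlur(img, 1, 0.1), intImg)
})

test_that("noise matches its sampling model and respects clipping", {
  expect_error(applyGaussianNoise(randomImage(8), -0.1), ">= 0")
  # constant-128 input: output sd ~= 0.08 * 255 = 20.4 over 10^4 pixels
  big <- matrix(128L, 100, 100)
  out <- applyGaussianNoise(big, 0.08, seed = 7)
  expect_equal(sd(as.numeric(out)), 0.08 * 255, tolerance = 0.02)
  expect_equal(mean(out), 128, tolerance = 1)
  # clipping: all-255 input never exceeds the range
  sat <- applyGaussianNoise(matrix(255L, 50, 50), 0.5, seed = 1)
  expect_true(all(sat <= 255L & sat >= 0L))
  # same seed, same draw
  expect_identical(applyGaussianNoise(big, 0.08, seed = 7), out)
})

test_that("contrast extrapolates away from the image mean", {
  # hand evaluation: mu = 125, EF 3.3 -> pre-quantization 42.5 / 207.5
  two <- matrix(c(100L, 150L), 1, 2)
  out <- applyContrast(two, 3.3)
  expect_equal(as.numeric(out), c(43, 208))  # half rounds away from zero
  # constant image is a fixed point for any factor
  const <- matrix(77L, 6, 6)
  expect_identical(applyContrast(const, 3.3), const)
  expect_error(applyContrast(two, 0), "> 0")
  # saturation: extreme factors clip into range
  expect_true(all(applyContrast(randomImage(10), 50) %in% 0:255))
})

test_that("rotation follows the center-rotation coordinate map", {
  # single bright pixel, 9x9, rotated 90 deg counterclockwise: compute the
  # expected landing spot from the forward map derived independently
  img <- matrix(0L, 9, 9)
  img[3, 7] <- 255L  # 0-based (r=2, c=6)
  th <- pi / 2; cy <- cx <- 4
  dxo <- (6 - cx) * cos(th) + (2 - cy) * sin(th)
  dyo <- -(6 - cx) * sin(th) + (2 - cy) * cos(th)
  out <- applyRotation(img, 90)
  expect_equal(out[round(cy + dyo) + 1, round(cx + dxo) + 1], 255L)
  expect_equal(sum(out > 0), 1L)
  # inverse pair on a centered disk is near-identity
  ctr <- 10.5
  disk <- matrix(0L, 22, 22)
  d <- sqrt(outer((1:22 - ctr)^2, (1:22 - ctr)^2, `+`))
  disk[d < 7] <- 200L
  back <- applyRotation(applyRotation(disk, 37), -37)
  inner <- d < 5 | d > 9  # away from the interpolated rim
  expect_lt(mean(abs(back[inner] - disk[inner])), 4)
})

test_that("tilt equals the homography through the four corner points", {
  # independent oracle: DLT homography from the corner correspondences,
  # applied by a naive per-pixel bilinear sampler with zero fill
  img <- randomImage(15, seed = 9)
  theta <- 45
  H <- nrow(img); W <- ncol(img)
  half <- (W - 1) / 2; d <- half * (1 - cos(theta * pi / 180))
  src <- rbind(c(0, 0), c(W - 1, 0), c(0, H - 1), c(W - 1, H - 1))
  dst <- rbind(c(d, 0), c(W - 1 - d, 0), c(0, H - 1), c(W - 1, H - 1))
  A <- NULL; bvec <- NULL
  for (i in 1:4) {  # homography mapping dst -> src
    x <- dst[i, 1]; y <- dst[i, 2]; u <- src[i, 1]; v <- src[i, 2]
    A <- rbind(A,
      c(x, y, 1, 0, 0, 0, -u * x, -u * y),
      c(0, 0, 0, x, y, 1, -v * x, -v * y))
    bvec <- c(bvec, u, v)
  }
  h <- solve(A, bvec)
  Hm <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  oracle <- matrix(0, H, W)
  for (r in 0:(H - 1)) for (cc in 0:(W - 1)) {
    p <- Hm %*% c(cc, r, 1)
    xs <- p[1] / p[3]; ys <- p[2] / p[3]
    x0 <- floor(xs); y0 <- floor(ys); dx <- xs - x0; dy <- ys - y0
    acc <- 0
    for (dr in 0:1) for (dc in 0:1) {
      rr <- y0 + dr; c2 <- x0 + dc
      w <- (if (dc == 0) 1 - dx else dx) * (if (dr == 0) 1 - dy else dy)
      if (rr >= 0 && rr < H && c2 >= 0 && c2 < W)
        acc <- acc + w * img[rr + 1, c2 + 1]
    }
    oracle[r + 1, cc + 1] <- acc
  }
  got <- applyTilt(img, theta)
  expect_lt(max(abs(got - pmin(pmax(round(oracle), 0), 255))), 2)
  # 90 degrees: top corners displaced to the center point
  out90 <- applyTilt(img, 90)
  expect_equal(dim(out90), dim(img))
  expect_error(applyTilt(img, 91), "\\[0, 90\\]")
})

test_that("blur reproduces the normalized kernel impulse response", {
  imp <- matrix(0L, 9, 9); imp[5, 5] <- 255L
  w <- exp(-(-1:1)^2 / (2 * 1^2)); w <- w / sum(w)
  expected <- matrix(0, 9, 9)
  expected[4:6, 4:6] <- 255 * outer(w, w)
  out <- applyBlur(imp, 3, 1)
  expect_lt(max(abs(out[4:6, 4:6] - expected[4:6, 4:6])), 1)
  # the protocol severity (kernel 3, sd 0.1) is numerically near-identity
  img <- randomImage(12, seed = 4)
  intImg <- img; storage.mode(intImg) <- "integer"
  expect_identical(applyBlur(img, 3, 0.1), intImg)
  # constant image unchanged (kernel sums to 1), even at the borders
  const <- matrix(90L, 8, 8)
  expect_identical(applyBlur(const, 5, 2), const)
  expect_error(applyBlur(img, 4, 1), "odd")
})

test_that("severity sampling honours ranges, defaults and determinism", {
  cfg <- perturbationConfig()
  expect_equal(sampleSeverity("noise", cfg), 0.08)
  expect_equal(sampleSeverity("contrast", cfg), 3.3)
  expect_equal(sampleSeverity("blur", cfg), 3L)
  angles <- vapply(1:500, function(i)
    sampleSeverity("rotation", cfg, seed = i), numeric(1))
  expect_true(all(angles >= -90 & angles <= 90))
  expect_true(all(angles == round(angles)))
  expect_gt(length(unique(angles)), 50)
  tilts <- vapply(1:200, function(i)
    sampleSeverity("tilt", cfg, seed = i), numeric(1))
  expect_true(all(tilts >= 0 & tilts <= 90))
  expect_identical(vapply(1:50, function(i)
    sampleSeverity("rotation", cfg, seed = i), numeric(1)), angles[1:50])
  expect_error(sampleSeverity("fog", cfg), "unknown")
})

test_that("the dispatcher preserves shape, range and purity for all kinds", {
  cfg <- perturbationConfig()
  for (seed in 1:3) {
    img <- randomImage(11, seed = seed)
    before <- img
    for (kind in perturbationKinds()) {
      out <- applyPerturbation(img, kind, cfg, seed = seed)
      expect_equal(dim(out), dim(img))
      expect_true(all(out >= 0L & out <= 255L))
      expect_identical(applyPerturbation(img, kind, cfg, seed = seed), out)
    }
    expect_identical(img, before)  # inputs never mutated
  }
  expect_error(applyPerturbation(randomImage(8), "sharpen"), "unknown")
})

test_that("mean SSIM decreases as noise and rotation severity grow", {
  panel <- lapply(1:4, function(i) randomImage(24, seed = 100 + i))
  smoothPanel <- lapply(panel, function(p) applyBlur(p, 7, 3))
  noiseCurve <- vapply(c(0.02, 0.08, 0.2, 0.5), function(sg)
    mean(vapply(seq_along(smoothPanel), function(i)
      ssim(smoothPanel[[i]],
           applyGaussianNoise(smoothPanel[[i]], sg, seed = i),
           winSize = 11), numeric(1))), numeric(1))
  expect_true(all(diff(noiseCurve) <= 0))
  rotCurve <- vapply(c(0, 10, 45, 90), function(a)
    mean(vapply(smoothPanel, function(p)
      ssim(p, applyRotation(p, a), winSize = 11), numeric(1))), numeric(1))
  expect_true(all(diff(rotCurve) <= 1e-6))
})
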