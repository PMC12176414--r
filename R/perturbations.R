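# The five perturbation operators. Each preserves shape and the 0-255
# range, computes in floating point, and quantizes on output. Zero-severity
# settings (sigma = 0, EF = 1, angle = 0, kernel = 1) are exact identities.

#' @include AllClasses.R rng.R
NULL

# Vectorized bilinear sampling of `img` (numeric matrix) at 0-based
# coordinates (x = col, y = row). Coordinates outside the frame contribute
# the fill value 0 unless clampEdges = TRUE (edge replication, used by
# resizing where out-of-frame means half-pixel overshoot only).
.bilinearSample <- function(img, x, y, clampEdges = FALSE) {
  H <- nrow(img); W <- ncol(img)
  if (clampEdges) {
    x <- pmin(pmax(x, 0), W - 1)
    y <- pmin(pmax(y, 0), H - 1)
  }
  x0 <- floor(x); y0 <- floor(y)
  dx <- x - x0; dy <- y - y0
  val <- numeric(length(x))
  for (k in 1:4) {
    cc <- x0 + (k == 2L || k == 4L)
    rr <- y0 + (k >= 3L)
    w <- (if (k %% 2L == 1L) 1 - dx else dx) *
         (if (k <= 2L) 1 - dy else dy)
    inside <- rr >= 0 & rr < H & cc >= 0 & cc < W & w > 0
    if (any(inside))
      val[inside] <- val[inside] +
        w[inside] * img[cbind(rr[inside] + 1, cc[inside] + 1)]
  }
  val
}

#' Additive Gaussian noise
#'
#' Scales the image to [0, 1], adds i.i.d. N(0, sigma^2) noise to every
#' pixel, clips to [0, 1], and rescales to 0--255. The protocol severity is
#' sigma = 0.08, the mildest level of the common-corruption benchmarks.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param sigma Unit-scale standard deviation (>= 0); 0 is the identity.
#' @param seed Optional integer seed for the noise draw; NULL uses the
#'   current RNG stream.
#' @return Perturbed integer matrix, same shape, values in [0, 255].
#' @examples
#' img <- matrix(128L, 8, 8)
#' noisy <- applyGaussianNoise(img, 0.08, seed = 1)
#' @export
applyGaussianNoise <- function(img, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(quantizeIntensity(img))
  draw <- function() matrix(stats::rnorm(length(img), 0, sigma),
                            nrow(img), ncol(img))
  eps <- if (is.null(seed)) draw() else withSeed(seed, draw())
  u <- pmin(pmax(img / 255 + eps, 0), 1)
  quantizeIntensity(u * 255)
}

#' Mean-pivot contrast extrapolation
#'
#' Moves every pixel away from the image's mean intensity by the
#' enhancement factor EF: \code{out = mu + EF * (pixel - mu)}, clipped to
#' [0, 255]. EF = 1 is the identity; EF > 1 pushes values toward the
#' extremes (the classic extrapolate-against-mean-gray contrast
#' enhancement). The protocol severity is EF = 3.3.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param factor Enhancement factor EF (> 0).
#' @return Perturbed integer matrix.
#' @examples
#' applyContrast(matrix(c(100L, 150L), 1, 2), 3.3)  # 43, 208
#' @export
applyContrast <- function(img, factor) {
  if (factor <= 0) stop("contrast factor must be > 0")
  mu <- mean(img)
  quantizeIntensity(mu + factor * (img - mu))
}

#' In-plane rotation about the image center
#'
#' Rotates by an integer angle (positive = counterclockwise, row 0 at the
#' top), bilinear interpolation, same output shape, out-of-frame regions
#' filled with 0. Per-image angles are drawn uniformly from [-90, 90]
#' degrees by the severity sampler.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param angleDeg Rotation angle in degrees.
#' @return Rotated integer matrix, same shape.
#' @export
applyRotation <- function(img, angleDeg) {
  if (angleDeg == 0) return(quantizeIntensity(img))
  H <- nrow(img); W <- ncol(img)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- angleDeg * pi / 180
  g <- expand.grid(r = 0:(H - 1), c = 0:(W - 1))
  dx <- g$c - cx; dy <- g$r - cy
  # inverse map: rotate output coords by -theta (y axis points down)
  xs <- cx + dx * cos(th) - dy * sin(th)
  ys <- cy + dx * sin(th) + dy * cos(th)
  quantizeIntensity(matrix(.bilinearSample(img, xs, ys), H, W))
}

#' Perspective tilt
#'
#' Projective warp emulating the top of the image being pushed away along
#' the z-axis: the two top corners move inward symmetrically by
#' \code{(width/2) * (1 - cos(theta))} while the bottom edge stays fixed
#' (width measured between corner centers). Bilinear interpolation, same
#' shape, fill 0. At 90 degrees the top edge collapses to the center
#' point. Per-image angles are drawn uniformly from [0, 90] degrees.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param angleDeg Tilt angle in degrees, within [0, 90].
#' @return Tilted integer matrix, same shape.
#' @export
applyTilt <- function(img, angleDeg) {
  if (angleDeg < 0 || angleDeg > 90) stop("tilt angle must be in [0, 90]")
  if (angleDeg == 0) return(quantizeIntensity(img))
  H <- nrow(img); W <- ncol(img)
  half <- (W - 1) / 2; cx <- half; Yb <- H - 1
  ct <- cos(angleDeg * pi / 180)
  # symmetric trapezoid homography in centered coords (u = x - cx, v = y):
  # source = a * (u, v) / (q * v + 1), a = half / (half - d), q = (a-1)/Yb.
  # Derived from the four corner correspondences; symmetry forces the form.
  d <- half * (1 - ct)
  a <- if (ct > 1e-12) half / (half - d) else 1e12
  q <- (a - 1) / Yb
  g <- expand.grid(r = 0:(H - 1), c = 0:(W - 1))
  u <- g$c - cx; v <- g$r
  denom <- q * v + 1
  xs <- cx + a * u / denom
  ys <- a * v / denom
  quantizeIntensity(matrix(.bilinearSample(img, xs, ys), H, W))
}

# normalized 1-D Gaussian taps for a window of odd size k
.gaussianTaps <- function(k, sigma) {
  half <- (k - 1) / 2
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian blur
#'
#' Convolution with a normalized Gaussian kernel of odd window size and
#' given sd; borders handled by edge replication. The protocol severity
#' (kernel 3, sd 0.1) is the mildest defocus level of the
#' common-corruption benchmarks and is numerically near-identity.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param kernel Odd window size (>= 1); 1 is the identity.
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @return Blurred integer matrix, same shape.
#' @export
applyBlur <- function(img, kernel, sigma) {
  if (kernel < 1 || kernel %% 2 == 0) stop("kernel size must be odd and >= 1")
  if (sigma <= 0) stop("blur sigma must be > 0")
  if (kernel == 1) return(quantizeIntensity(img))
  w <- .gaussianTaps(kernel, sigma)
  half <- (kernel - 1) / 2
  H <- nrow(img); W <- ncol(img)
  padIdx <- function(n) pmin(pmax(seq(1 - half, n + half), 1), n)
  padded <- img[padIdx(H), padIdx(W)]
  out <- matrix(0, H, W)
  # separable pass done as one 2-D accumulation; kernel is tiny
  tmp <- matrix(0, H, W + 2 * half)
  for (i in seq_len(kernel))
    tmp <- tmp + w[i] * padded[seq_len(H) + i - 1, ]
  for (j in seq_len(kernel))
    out <- out + w[j] * tmp[, seq_len(W) + j - 1]
  quantizeIntensity(out)
}

#' Sample a per-image severity for one perturbation kind
#'
#' Rotation and tilt draw a fresh uniform integer degree from the
#' configured range for every image; noise, contrast and blur severities
#' are fixed by the configuration.
#'
#' @param kind One of \code{perturbationKinds()}.
#' @param cfg A \linkS4class{PerturbationConfig}.
#' @param seed Optional integer seed for the draw.
#' @return A numeric severity (degrees for rotation/tilt; sigma for noise;
#'   EF for contrast; the kernel size for blur).
#' @export
sampleSeverity <- function(kind, cfg = perturbationConfig(), seed = NULL) {
  if (!kind %in% perturbationKinds()) stop("unknown perturbation kind: ", kind)
  drawInt <- function(rng) {
    vals <- rng[1]:rng[2]
    draw <- function() if (length(vals) == 1L) vals else sample(vals, 1L)
    if (is.null(seed)) draw() else withSeed(seed, draw())
  }
  switch(kind,
    noise = cfg@noiseSigma,
    contrast = cfg@contrastFactor,
    rotation = drawInt(cfg@rotationRange),
    tilt = drawInt(cfg@tiltRange),
    blur = cfg@blurKernel)
}

#' Apply one perturbation kind to an image
#'
#' Samples the per-image severity via [sampleSeverity()] and dispatches to
#' the matching operator. Labels are never touched by perturbation; the
#' input image is not modified.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param kind One of \code{perturbationKinds()}.
#' @param cfg A \linkS4class{PerturbationConfig}.
#' @param seed Optional integer seed; fixes both the severity draw and the
#'   noise draw, making the output fully reproducible.
#' @return Perturbed integer matrix, same shape, values in [0, 255].
#' @examples
#' img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
#' applyPerturbation(img, "rotation", seed = 7)
#' @export
applyPerturbation <- function(img, kind, cfg = perturbationConfig(),
                              seed = NULL) {
  if (!kind %in% perturbationKinds()) stop("unknown perturbation kind: ", kind)
  sevSeed <- if (is.null(seed)) NULL else childSeed(seed, "severity", kind)
  sev <- sampleSeverity(kind, cfg, seed = sevSeed)
  switch(kind,
    noise = applyGaussianNoise(img, sev,
      seed = if (is.null(seed)) NULL else childSeed(seed, "noise")),
    contrast = applyContrast(img, sev),
    rotation = applyRotation(img, sev),
    tilt = applyTilt(img, sev),
    blur = applyBlur(img, sev, cfg@blurSigma))
}
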