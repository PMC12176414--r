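# SPSA adversarial attack: the protocol's control condition.
#
# Gradient-free untargeted attack. The loss pushed uphill is the margin
# against the correct class on the classifier's real-valued score; the
# gradient is estimated by central finite differences along random
# Rademacher directions and the iterate is projected back onto the
# L-infinity ball (radius epsilon, unit scale) intersected with [0, 1]
# after every step.

#' @include AllClasses.R classifiers.R rng.R imaging.R
NULL

#' SPSA attack on a single image
#'
#' Maximizes the misclassification loss \code{-(2*label - 1) * score(x)}
#' by simultaneous-perturbation stochastic approximation: at each step,
#' \code{nSamples} Rademacher directions v give the estimate
#' \code{g = mean[(loss(x + delta*v) - loss(x - delta*v)) / (2*delta) * v]},
#' and the iterate moves by \code{stepSize * sign(g)}, clipped to the
#' epsilon ball around the source and to [0, 1]. With \code{epsilon = 0}
#' the output is the input.
#'
#' @param model A classifier with a [predictScores()] method (real-valued
#'   positive-class score).
#' @param img Integer matrix on the 0--255 scale.
#' @param label True binary label of \code{img}.
#' @param cfg A \linkS4class{SpsaConfig}.
#' @param seed Optional seed overriding \code{cfg@seed}.
#' @return Adversarial integer matrix within \code{epsilon * 255} of the
#'   input (after quantization) and within [0, 255].
#' @export
spsaAttack <- function(model, img, label, cfg = spsaConfig(), seed = NULL) {
  if (!hasMethod("predictScores", class(model)))
    stop("model does not expose a real-valued score (predictScores method)")
  if (cfg@epsilon == 0) return(quantizeIntensity(img))
  if (is.null(seed)) seed <- cfg@seed
  H <- nrow(img); W <- ncol(img); d <- H * W
  x0 <- as.numeric(img) / 255
  x <- x0
  sgn <- if (label == 1) 1 else -1  # loss = -sgn * score
  lossOf <- function(mat) {
    # batch all probe images into one scoring call
    -sgn * predictScores(model, lapply(seq_len(ncol(mat)), function(j)
      matrix(mat[, j] * 255, H, W)))
  }
  withSeed(childSeed(seed, "spsa"), {
    for (it in seq_len(cfg@nIters)) {
      V <- matrix(sample(c(-1, 1), d * cfg@nSamples, replace = TRUE),
                  d, cfg@nSamples)
      probes <- cbind(x + cfg@delta * V, x - cfg@delta * V)
      L <- lossOf(probes)
      diffs <- (L[seq_len(cfg@nSamples)] -
                L[cfg@nSamples + seq_len(cfg@nSamples)]) / (2 * cfg@delta)
      g <- as.numeric(V %*% diffs) / cfg@nSamples
      x <- x + cfg@stepSize * sign(g)
      x <- pmin(pmax(x, x0 - cfg@epsilon), x0 + cfg@epsilon)
      x <- pmin(pmax(x, 0), 1)
    }
  })
  fromUnitScale(matrix(x, H, W))
}

#' Replace every training image by its SPSA-attacked version
#'
#' Builds the adversarially trained control variant: each image is
#' attacked against the supplied (clean-trained) classifier once, before
#' re-training; labels and set size are unchanged.
#'
#' @param train A \linkS4class{LabeledImageSet}.
#' @param model The clean-trained classifier to attack against.
#' @param cfg A \linkS4class{SpsaConfig}.
#' @return A \linkS4class{LabeledImageSet} of the same size.
#' @export
buildAdversarialTrainingSet <- function(train, model, cfg = spsaConfig()) {
  imgs <- lapply(seq_along(train@images), function(i)
    spsaAttack(model, train@images[[i]], train@labels[i], cfg,
               seed = childSeed(cfg@seed, "adv", i)))
  new("LabeledImageSet", images = imgs, labels = train@labels,
      ids = train@ids, split = train@split)
}

#' SPSA gradient estimate (exposed for diagnostics)
#'
#' One-step SPSA gradient estimate of the misclassification loss at the
#' image, without taking a step. Useful for validating the estimator
#' against models with a known analytic gradient.
#'
#' @inheritParams spsaAttack
#' @return Numeric vector of length \code{nrow(img) * ncol(img)} (the
#'   estimated loss gradient on the unit scale, column-major).
#' @export
spsaGradient <- function(model, img, label, cfg = spsaConfig(), seed = NULL) {
  if (is.null(seed)) seed <- cfg@seed
  H <- nrow(img); W <- ncol(img); d <- H * W
  x <- as.numeric(img) / 255
  sgn <- if (label == 1) 1 else -1
  lossOf <- function(mat)
    -sgn * predictScores(model, lapply(seq_len(ncol(mat)), function(j)
      matrix(mat[, j] * 255, H, W)))
  withSeed(childSeed(seed, "spsa-grad"), {
    V <- matrix(sample(c(-1, 1), d * cfg@nSamples, replace = TRUE),
                d, cfg@nSamples)
    L <- lossOf(cbind(x + cfg@delta * V, x - cfg@delta * V))
    diffs <- (L[seq_len(cfg@nSamples)] -
              L[cfg@nSamples + seq_len(cfg@nSamples)]) / (2 * cfg@delta)
    as.numeric(V %*% diffs) / cfg@nSamples
  })
}
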