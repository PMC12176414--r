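# Evaluation metrics: error rate, precision/recall, SSIM, replicate
# aggregation.

#' Classification error rate
#'
#' The proportion of misclassified images:
#' \code{1 - (number of correct predictions) / (total predictions)}.
#' An error rate of 0.15 means 15% of the test images were misclassified;
#' 0.5 indicates chance-level prediction for a balanced problem.
#'
#' @param yTrue,yPred Equal-length binary label vectors.
#' @return Proportion in [0, 1].
#' @examples
#' errorRate(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.25
#' @export
errorRate <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty label vector")
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  1 - sum(yTrue == yPred) / length(yTrue)
}

#' Precision and recall for the positive class
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), positive class =
#' label 1. A zero denominator (no positive predictions, or no positive
#' truths) yields 0 with the corresponding \code{undefined*} flag set, so
#' replicate aggregation never aborts.
#'
#' @param yTrue,yPred Equal-length binary label vectors.
#' @return List with \code{precision}, \code{recall},
#'   \code{undefinedPrecision}, \code{undefinedRecall}.
#' @examples
#' precisionRecall(c(1, 1, 1, 0, 0, 1), c(1, 1, 0, 1, 0, 0))
#' @export
precisionRecall <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty label vector")
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  fn <- sum(yTrue == 1 & yPred == 0)
  undefP <- (tp + fp) == 0
  undefR <- (tp + fn) == 0
  if (undefP) warning("no positive predictions; precision reported as 0")
  if (undefR) warning("no positive truths; recall reported as 0")
  list(precision = if (undefP) 0 else tp / (tp + fp),
       recall = if (undefR) 0 else tp / (tp + fn),
       undefinedPrecision = undefP, undefinedRecall = undefR)
}

#' Evaluate hard predictions against truth
#'
#' @param yTrue,yPred Equal-length binary label vectors.
#' @return List with \code{errorRate}, \code{precision}, \code{recall},
#'   \code{nCorrect}, \code{nTotal} and undefined-metric flags.
#' @export
evalResult <- function(yTrue, yPred) {
  pr <- suppressWarnings(precisionRecall(yTrue, yPred))
  list(errorRate = errorRate(yTrue, yPred),
       precision = pr$precision, recall = pr$recall,
       undefinedPrecision = pr$undefinedPrecision,
       undefinedRecall = pr$undefinedRecall,
       nCorrect = sum(yTrue == yPred), nTotal = length(yTrue))
}

#' Structural similarity index (SSIM) between two images
#'
#' Standard mean SSIM with the canonical parameterization: dynamic range
#' 255, stabilizers C1 = (0.01 * 255)^2 and C2 = (0.03 * 255)^2, local
#' statistics under an 11x11 Gaussian window with sd 1.5, averaged over
#' the valid (fully overlapping) window positions.
#'
#' @param a,b Numeric matrices of identical dimension (0--255 scale).
#' @param winSize Odd window size (default 11).
#' @param winSigma Window Gaussian sd (default 1.5).
#' @param dynamicRange Intensity range L (default 255).
#' @param K1,K2 Stabilizer constants (defaults 0.01, 0.03).
#' @return Mean SSIM in [-1, 1]; 1 iff the images are identical.
#' @examples
#' x <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
#' ssim(x, x)  # 1
#' @export
ssim <- function(a, b, winSize = 11L, winSigma = 1.5, dynamicRange = 255,
                 K1 = 0.01, K2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop("images differ in dimension")
  if (min(dim(a)) < winSize)
    stop("image smaller than the SSIM window (", winSize, ")")
  a <- a * 1.0; b <- b * 1.0
  w <- .gaussianTaps(winSize, winSigma)
  # valid-region separable weighted filtering via banded matrices
  band <- function(n) {
    m <- matrix(0, n - winSize + 1L, n)
    for (i in seq_len(n - winSize + 1L)) m[i, i:(i + winSize - 1L)] <- w
    m
  }
  Br <- band(nrow(a)); Bc <- band(ncol(a))
  f <- function(x) Br %*% x %*% t(Bc)
  muA <- f(a); muB <- f(b)
  varA <- f(a * a) - muA^2
  varB <- f(b * b) - muB^2
  covAB <- f(a * b) - muA * muB
  C1 <- (K1 * dynamicRange)^2
  C2 <- (K2 * dynamicRange)^2
  smap <- ((2 * muA * muB + C1) * (2 * covAB + C2)) /
          ((muA^2 + muB^2 + C1) * (varA + varB + C2))
  mean(smap)
}

#' Mean SSIM between a clean set and replicate perturbed sets
#'
#' Measures perturbation intensity as the average structural similarity of
#' every perturbed image to its clean counterpart, over all images and all
#' replicate sets. Sets must carry identically ordered ids.
#'
#' @param clean A \linkS4class{LabeledImageSet}.
#' @param perturbedSets List of \linkS4class{LabeledImageSet} replicates.
#' @param ... Passed to [ssim()].
#' @return Mean similarity across all (image, replicate) pairs.
#' @export
meanSetSsim <- function(clean, perturbedSets, ...) {
  if (is(perturbedSets, "LabeledImageSet"))
    perturbedSets <- list(perturbedSets)
  vals <- vapply(perturbedSets, function(p) {
    if (!identical(imageIds(p), imageIds(clean)))
      stop("replicate ids are not aligned with the clean set")
    mean(vapply(seq_along(clean@images), function(i)
      ssim(clean@images[[i]], p@images[[i]], ...), numeric(1)))
  }, numeric(1))
  mean(vals)
}

#' Aggregate per-replicate evaluation results
#'
#' @param results List of [evalResult()] lists, one per replicate test set.
#' @return List with \code{meanError}, \code{sdError} (sample sd),
#'   \code{meanPrecision}, \code{meanRecall}, \code{nReplicates} and the
#'   retained \code{perReplicate} detail.
#' @export
summarizeReplicates <- function(results) {
  if (length(results) == 0L) stop("no replicate results to summarize")
  errs <- vapply(results, `[[`, numeric(1), "errorRate")
  list(meanError = mean(errs),
       sdError = if (length(errs) > 1L) stats::sd(errs) else 0,
       meanPrecision = mean(vapply(results, `[[`, numeric(1), "precision")),
       meanRecall = mean(vapply(results, `[[`, numeric(1), "recall")),
       nReplicates = length(errs),
       perReplicate = results)
}
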