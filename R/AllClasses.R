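# S4 classes for the perturbation-robustness protocol.

.SPLIT_ROLES <- c("train", "validation", "test")

#' The five common perturbation kinds
#'
#' Closed enumeration of the perturbation operators: additive Gaussian
#' noise, mean-pivot contrast extrapolation, in-plane rotation, perspective
#' tilt, and Gaussian blur. Every dispatcher in the package rejects any
#' other value.
#'
#' @return Character vector of the five kind names, in the canonical
#'   application order used for simultaneous perturbations.
#' @examples
#' perturbationKinds()
#' @export
perturbationKinds <- function() c("noise", "contrast", "rotation", "tilt", "blur")

#' LabeledImageSet: grayscale images with binary labels
#'
#' Container for an ordered collection of single-channel images (integer
#' matrices on the 0--255 scale), aligned binary labels (0 = negative,
#' 1 = positive diagnosis), unique stable identifiers and the split the
#' set belongs to (train / validation / test).
#'
#' @slot images List of integer matrices, each with values in [0, 255].
#' @slot labels Integer vector of 0/1 labels, one per image.
#' @slot ids Character vector of unique identifiers, one per image.
#' @slot split One of \code{"train"}, \code{"validation"}, \code{"test"}.
#' @export
setClass("LabeledImageSet",
  representation(images = "list", labels = "integer", ids = "character",
                 split = "character"))

setValidity("LabeledImageSet", function(object) {
  msg <- NULL
  n <- length(object@images)
  if (length(object@labels) != n || length(object@ids) != n)
    msg <- c(msg, "images, labels and ids must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique")
  if (n > 0 && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(object@split) != 1L || !object@split %in% .SPLIT_ROLES)
    msg <- c(msg, "split must be one of train/validation/test")
  for (im in object@images) {
    if (!is.matrix(im) || !is.numeric(im)) {
      msg <- c(msg, "each image must be a numeric matrix"); break
    }
    if (any(im < 0 | im > 255)) {
      msg <- c(msg, "pixel intensities must lie in [0, 255]"); break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a LabeledImageSet
#'
#' @param images List of integer pixel matrices (0--255).
#' @param labels Binary labels (0/1), one per image.
#' @param ids Unique identifiers; defaults to zero-padded integers.
#' @param split Split role, one of \code{"train"}, \code{"validation"},
#'   \code{"test"}.
#' @return A \linkS4class{LabeledImageSet}.
#' @examples
#' im <- matrix(0L, 8, 8)
#' LabeledImageSet(list(im, im), c(0, 1), split = "train")
#' @export
LabeledImageSet <- function(images, labels, ids = NULL, split = "train") {
  if (is.null(ids))
    ids <- sprintf("img-%04d", seq_along(images))
  images <- lapply(images, function(im) {
    storage.mode(im) <- "integer"
    im
  })
  new("LabeledImageSet", images = images, labels = as.integer(labels),
      ids = as.character(ids), split = split)
}

#' Perturbation severity configuration
#'
#' Holds the severity of each of the five perturbation operators. Defaults
#' are the protocol's fixed severities: noise sd 0.08 on the unit scale,
#' contrast enhancement factor 3.3, rotation angles drawn from [-90, 90]
#' degrees, tilt angles from [0, 90] degrees, and a 3x3 Gaussian blur
#' kernel with sd 0.1.
#'
#' @slot noiseSigma Unit-scale standard deviation of the additive noise.
#' @slot contrastFactor Enhancement factor EF (EF = 1 is the identity).
#' @slot rotationRange Ordered integer degree interval for rotation.
#' @slot tiltRange Ordered integer degree interval for tilt.
#' @slot blurKernel Odd kernel window size.
#' @slot blurSigma Kernel standard deviation (pixels).
#' @export
setClass("PerturbationConfig",
  representation(noiseSigma = "numeric", contrastFactor = "numeric",
                 rotationRange = "integer", tiltRange = "integer",
                 blurKernel = "integer", blurSigma = "numeric"))

setValidity("PerturbationConfig", function(object) {
  msg <- NULL
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@contrastFactor <= 0) msg <- c(msg, "contrastFactor must be > 0")
  if (length(object@rotationRange) != 2L ||
      object@rotationRange[1] > object@rotationRange[2])
    msg <- c(msg, "rotationRange must be an ordered integer interval")
  if (length(object@tiltRange) != 2L ||
      object@tiltRange[1] > object@tiltRange[2] ||
      object@tiltRange[1] < 0L || object@tiltRange[2] > 90L)
    msg <- c(msg, "tiltRange must be an ordered interval within [0, 90]")
  if (object@blurKernel < 1L || object@blurKernel %% 2L == 0L)
    msg <- c(msg, "blurKernel must be odd and >= 1")
  if (object@blurSigma <= 0) msg <- c(msg, "blurSigma must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param noiseSigma,contrastFactor,rotationRange,tiltRange,blurKernel,blurSigma
#'   See the class slots.
#' @return A \linkS4class{PerturbationConfig}.
#' @rdname PerturbationConfig-class
#' @examples
#' perturbationConfig()
#' perturbationConfig(noiseSigma = 0.2, rotationRange = c(-30, 30))
#' @export
perturbationConfig <- function(noiseSigma = 0.08, contrastFactor = 3.3,
                               rotationRange = c(-90L, 90L),
                               tiltRange = c(0L, 90L),
                               blurKernel = 3L, blurSigma = 0.1) {
  new("PerturbationConfig", noiseSigma = noiseSigma,
      contrastFactor = contrastFactor,
      rotationRange = as.integer(rotationRange),
      tiltRange = as.integer(tiltRange),
      blurKernel = as.integer(blurKernel), blurSigma = blurSigma)
}

#' Training-set variant coordinates
#'
#' A variant perturbs a fraction \code{fractionP} (a percentage) of the
#' training images with one perturbation kind, replacing the originals.
#' The baseline variant is \code{kind = "none"} with \code{fractionP = 0}.
#'
#' @slot fractionP Percentage of training images to perturb (0--100).
#' @slot kind One of \code{perturbationKinds()} or \code{"none"}.
#' @slot seed Integer seed controlling image selection and severities.
#' @export
setClass("TrainVariantSpec",
  representation(fractionP = "numeric", kind = "character", seed = "integer"))

setValidity("TrainVariantSpec", function(object) {
  msg <- NULL
  if (object@fractionP < 0 || object@fractionP > 100)
    msg <- c(msg, "fractionP must be in [0, 100]")
  if (!object@kind %in% c("none", perturbationKinds()))
    msg <- c(msg, "unknown perturbation kind")
  if ((object@kind == "none") != (object@fractionP == 0))
    msg <- c(msg, "kind 'none' if and only if fractionP is 0")
  if (is.null(msg)) TRUE else msg
})

#' @param fractionP,kind,seed See the class slots.
#' @return A \linkS4class{TrainVariantSpec}.
#' @rdname TrainVariantSpec-class
#' @export
trainVariantSpec <- function(fractionP, kind, seed = 1L) {
  new("TrainVariantSpec", fractionP = as.numeric(fractionP),
      kind = kind, seed = as.integer(seed))
}

#' Replicated perturbed test-set coordinates
#'
#' For one (test fraction, kind) combination, \code{nReplicates} test sets
#' are resampled, each with a fresh random subset of exactly
#' \code{round(fractionPPrime * N / 100)} images perturbed.
#'
#' @slot fractionPPrime Percentage of test images perturbed (0--100).
#' @slot kind One of \code{perturbationKinds()}.
#' @slot nReplicates Number of replicate test sets (protocol default 200).
#' @slot seed Integer seed; replicate r is fully determined by (seed, r).
#' @export
setClass("TestResampleSpec",
  representation(fractionPPrime = "numeric", kind = "character",
                 nReplicates = "integer", seed = "integer"))

setValidity("TestResampleSpec", function(object) {
  msg <- NULL
  if (object@fractionPPrime < 0 || object@fractionPPrime > 100)
    msg <- c(msg, "fractionPPrime must be in [0, 100]")
  if (!object@kind %in% perturbationKinds())
    msg <- c(msg, "unknown perturbation kind")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param fractionPPrime,kind,nReplicates,seed See the class slots.
#' @return A \linkS4class{TestResampleSpec}.
#' @rdname TestResampleSpec-class
#' @export
testResampleSpec <- function(fractionPPrime, kind, nReplicates = 200L,
                             seed = 1L) {
  new("TestResampleSpec", fractionPPrime = as.numeric(fractionPPrime),
      kind = kind, nReplicates = as.integer(nReplicates),
      seed = as.integer(seed))
}

#' Simultaneous multi-perturbation scheme
#'
#' Training: a disjoint random 10% group of the training images per kind is
#' perturbed by that kind (50% of the set left untouched under defaults).
#' Testing: each test image independently receives each kind with
#' probability \code{testProbabilityPerKind}, applied in
#' \code{applicationOrder}, across \code{nReplicates} replicate sets.
#'
#' @slot trainFractionPerKind Named fractions (of 1) per kind; sum <= 1.
#' @slot testProbabilityPerKind Per-kind application probability in [0, 1].
#' @slot applicationOrder Permutation of the five kinds.
#' @slot nReplicates Number of replicate test sets.
#' @slot seed Integer seed.
#' @export
setClass("MultiPerturbSpec",
  representation(trainFractionPerKind = "numeric",
                 testProbabilityPerKind = "numeric",
                 applicationOrder = "character",
                 nReplicates = "integer", seed = "integer"))

setValidity("MultiPerturbSpec", function(object) {
  msg <- NULL
  if (!setequal(names(object@trainFractionPerKind), perturbationKinds()))
    msg <- c(msg, "trainFractionPerKind must name all five kinds")
  if (any(object@trainFractionPerKind < 0) ||
      sum(object@trainFractionPerKind) > 1 + 1e-12)
    msg <- c(msg, "train fractions must be >= 0 and sum to at most 1")
  if (object@testProbabilityPerKind < 0 || object@testProbabilityPerKind > 1)
    msg <- c(msg, "testProbabilityPerKind must be in [0, 1]")
  if (!identical(sort(object@applicationOrder), sort(perturbationKinds())))
    msg <- c(msg, "applicationOrder must be a permutation of the five kinds")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param trainFractionPerKind,testProbabilityPerKind,applicationOrder,nReplicates,seed
#'   See the class slots.
#' @return A \linkS4class{MultiPerturbSpec}.
#' @rdname MultiPerturbSpec-class
#' @examples
#' multiPerturbSpec(nReplicates = 20)
#' @export
multiPerturbSpec <- function(trainFractionPerKind =
                               stats::setNames(rep(0.10, 5), perturbationKinds()),
                             testProbabilityPerKind = 0.5,
                             applicationOrder = perturbationKinds(),
                             nReplicates = 200L, seed = 1L) {
  if (is.null(names(trainFractionPerKind)) &&
      length(trainFractionPerKind) == 5L)
    names(trainFractionPerKind) <- perturbationKinds()
  new("MultiPerturbSpec", trainFractionPerKind = trainFractionPerKind,
      testProbabilityPerKind = testProbabilityPerKind,
      applicationOrder = applicationOrder,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' SPSA adversarial-attack configuration
#'
#' Gradient-free untargeted attack used as the protocol's control
#' condition. The attack stays within an L-infinity ball of radius
#' \code{epsilon} (unit scale; protocol control intensity 8/255) around the
#' source image.
#'
#' @slot epsilon L-infinity budget on the 0--1 scale.
#' @slot nIters Number of ascent steps.
#' @slot delta Finite-difference probe radius.
#' @slot stepSize Update magnitude per step (unit scale).
#' @slot nSamples Rademacher directions averaged per gradient estimate.
#' @slot seed Integer seed for the probe directions.
#' @export
setClass("SpsaConfig",
  representation(epsilon = "numeric", nIters = "integer", delta = "numeric",
                 stepSize = "numeric", nSamples = "integer", seed = "integer"))

setValidity("SpsaConfig", function(object) {
  msg <- NULL
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
  if (object@nIters < 1L) msg <- c(msg, "nIters must be >= 1")
  if (object@delta <= 0) msg <- c(msg, "delta must be > 0")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param epsilon,nIters,delta,stepSize,nSamples,seed See the class slots.
#' @return A \linkS4class{SpsaConfig}.
#' @rdname SpsaConfig-class
#' @examples
#' spsaConfig()
#' @export
spsaConfig <- function(epsilon = 8 / 255, nIters = 20L, delta = 0.01,
                       stepSize = 0.01, nSamples = 32L, seed = 1L) {
  new("SpsaConfig", epsilon = epsilon, nIters = as.integer(nIters),
      delta = delta, stepSize = stepSize, nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

#' Synthetic labeled-image generator specification
#'
#' Emulates the structure of small grayscale binary-diagnosis datasets:
#' imbalanced classes (default 70% positive), fixed disjoint
#' train/validation/test splits, and a class-defining motif engineered to
#' be sensitive to a specific perturbation family.
#'
#' @slot nTrain,nVal,nTest Split sizes.
#' @slot imageSize Side length in pixels (default 28).
#' @slot positiveFraction Fraction of positive labels in (0, 1).
#' @slot motif One of \code{"corner_marker"} (rotation/tilt-sensitive),
#'   \code{"fine_texture"} (blur-sensitive), \code{"band_intensity"}
#'   (contrast-sensitive), \code{"plain_blob"} (perturbation-neutral).
#' @slot backgroundNoiseSd Background texture sd in intensity units.
#' @slot seed Integer seed.
#' @export
setClass("SyntheticSpec",
  representation(nTrain = "integer", nVal = "integer", nTest = "integer",
                 imageSize = "integer", positiveFraction = "numeric",
                 motif = "character", backgroundNoiseSd = "numeric",
                 seed = "integer"))

.MOTIFS <- c("corner_marker", "fine_texture", "band_intensity", "plain_blob")

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (object@nTrain < 1L || object@nVal < 0L || object@nTest < 1L)
    msg <- c(msg, "split sizes must be positive (validation may be 0)")
  if (object@imageSize < 8L) msg <- c(msg, "imageSize must be >= 8")
  if (object@positiveFraction <= 0 || object@positiveFraction >= 1)
    msg <- c(msg, "positiveFraction must be in (0, 1)")
  if (!object@motif %in% .MOTIFS)
    msg <- c(msg, "unknown motif")
  if (object@backgroundNoiseSd < 0)
    msg <- c(msg, "backgroundNoiseSd must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param nTrain,nVal,nTest,imageSize,positiveFraction,motif,backgroundNoiseSd,seed
#'   See the class slots.
#' @return A \linkS4class{SyntheticSpec}.
#' @rdname SyntheticSpec-class
#' @examples
#' syntheticSpec(nTrain = 100, nTest = 50, motif = "corner_marker")
#' @export
syntheticSpec <- function(nTrain = 600L, nVal = 100L, nTest = 200L,
                          imageSize = 28L, positiveFraction = 0.7,
                          motif = "corner_marker", backgroundNoiseSd = 20,
                          seed = 1L) {
  new("SyntheticSpec", nTrain = as.integer(nTrain), nVal = as.integer(nVal),
      nTest = as.integer(nTest), imageSize = as.integer(imageSize),
      positiveFraction = positiveFraction, motif = motif,
      backgroundNoiseSd = backgroundNoiseSd, seed = as.integer(seed))
}
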