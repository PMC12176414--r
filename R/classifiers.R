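# Reference classifier: a seeded random-feature ridge model.
#
# The protocol treats the classifier as a pluggable contract (fit /
# predict / score). The bundled reference learner maps unit-scale pixels
# through a fixed random tanh projection (drawn from the training seed)
# and fits a ridge-regularized linear read-out in closed form. It is
# deterministic given (data, seed), trains in milliseconds, and the seed
# plays the role the paper's protocol assigns to alternative network
# architectures in ensemble mode.

#' @include AllClasses.R AllGenerics.R rng.R
NULL

#' Seeded random-feature ridge classifier
#'
#' @slot hidden Number of random tanh features.
#' @slot lambda Ridge penalty on the read-out weights.
#' @slot W Projection matrix (pixels x hidden), drawn from the seed.
#' @slot b Feature offsets (hidden).
#' @slot beta Read-out weights (hidden + 1, intercept first).
#' @slot dims Training image dimensions (rows, cols).
#' @slot seed Seed that drew the projection.
#' @slot fingerprint Architecture/hyperparameter fingerprint string;
#'   retrained models must expose the identical fingerprint.
#' @export
setClass("ReferenceClassifier",
  representation(hidden = "integer", lambda = "numeric", W = "matrix",
                 b = "numeric", beta = "numeric", dims = "integer",
                 seed = "integer", fingerprint = "character"))

setMethod("show", "ReferenceClassifier", function(object) {
  cat(sprintf("ReferenceClassifier (%s)\n", object@fingerprint))
  cat(sprintf("  input: %d x %d images; seed %d\n",
              object@dims[1], object@dims[2], object@seed))
})

# LabeledImageSet or list of matrices -> N x d matrix of unit-scale pixels
.designMatrix <- function(newdata, dims = NULL) {
  imgs <- if (is(newdata, "LabeledImageSet")) images(newdata)
          else if (is.matrix(newdata)) list(newdata) else newdata
  if (!is.null(dims) && !all(dim(imgs[[1L]]) == dims))
    stop("image dimensions (", paste(dim(imgs[[1L]]), collapse = "x"),
         ") do not match the classifier's training dimensions (",
         paste(dims, collapse = "x"), ")")
  t(vapply(imgs, function(im) as.numeric(im) / 255,
           numeric(length(imgs[[1L]]))))
}

.featurize <- function(object, X) {
  tanh(sweep(X %*% object@W, 2, object@b, `+`))
}

#' Train the baseline classifier on a clean training set
#'
#' Fits the reference random-feature ridge classifier. Identical (data,
#' seed) always yields identical predictions. Both classes must be
#' present.
#'
#' @param train A \linkS4class{LabeledImageSet} with both classes present.
#' @param seed Integer seed drawing the random projection.
#' @param hidden Number of random tanh features (default 300).
#' @param lambda Ridge penalty (default 1).
#' @return A trained \linkS4class{ReferenceClassifier}.
#' @examples
#' sets <- generateSyntheticData(syntheticSpec(nTrain = 80, nVal = 0,
#'                                             nTest = 40))
#' f <- trainBaseline(sets$train, seed = 1)
#' mean(predictLabels(f, sets$test) != labels(sets$test))
#' @export
trainBaseline <- function(train, seed = 1L, hidden = 300L, lambda = 1) {
  if (length(train) == 0L) stop("empty training set")
  if (length(unique(train@labels)) < 2L)
    stop("training set contains a single class")
  X <- .designMatrix(train)
  d <- ncol(X)
  hidden <- as.integer(hidden)
  proj <- withSeed(childSeed(seed, "init"), {
    list(W = matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden),
         b = stats::runif(hidden, -1, 1))
  })
  obj <- new("ReferenceClassifier", hidden = hidden, lambda = lambda,
             W = proj$W, b = proj$b, beta = numeric(hidden + 1L),
             dims = dim(train@images[[1L]]), seed = as.integer(seed),
             fingerprint = sprintf("rfridge-h%d-l%g", hidden, lambda))
  H <- cbind(1, .featurize(obj, X))
  y <- ifelse(train@labels == 1L, 1, -1)
  pen <- diag(c(0, rep(lambda, hidden)))  # intercept unpenalized
  obj@beta <- as.numeric(solve(crossprod(H) + pen, crossprod(H, y)))
  obj
}

#' @rdname classifier-contract
#' @export
setMethod("predictScores", "ReferenceClassifier", function(object, newdata, ...) {
  X <- .designMatrix(newdata, object@dims)
  as.numeric(cbind(1, .featurize(object, X)) %*% object@beta)
})

#' @rdname classifier-contract
#' @export
setMethod("predictLabels", "ReferenceClassifier", function(object, newdata, ...) {
  as.integer(predictScores(object, newdata) > 0)
})

#' @rdname classifier-contract
#' @details \code{retrain} re-trains a classifier of the identical
#'   architecture (same hidden size and penalty, hence the same
#'   fingerprint) with freshly initialized weights on a new training-set
#'   variant; the reference classifier is not modified. Retraining on the
#'   clean set with the baseline's seed reproduces the baseline exactly.
#' @export
setMethod("retrain", "ReferenceClassifier", function(reference, train, seed, ...) {
  if (length(train) > 0L &&
      !all(dim(train@images[[1L]]) == reference@dims))
    stop("training-set image dimensions do not match the reference classifier")
  trainBaseline(train, seed = seed, hidden = reference@hidden,
                lambda = reference@lambda)
})

#' Evaluate a classifier on a labeled set
#'
#' @param object A classifier implementing [predictLabels()].
#' @param testSet A \linkS4class{LabeledImageSet}.
#' @return An [evalResult()] list.
#' @export
evaluateClassifier <- function(object, testSet) {
  evalResult(labels(testSet), predictLabels(object, testSet))
}
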