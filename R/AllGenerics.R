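#' @include AllClasses.R
NULL

#' Accessors for LabeledImageSet
#'
#' @param x,object A \linkS4class{LabeledImageSet}.
#' @param ... Ignored.
#' @return \code{images} returns the list of integer pixel matrices,
#'   \code{imageIds} the identifier vector, \code{labels} the 0/1 label
#'   vector and \code{splitRole} the split the set belongs to.
#' @name LabeledImageSet-accessors
NULL

#' @rdname LabeledImageSet-accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname LabeledImageSet-accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname LabeledImageSet-accessors
#' @export
setGeneric("splitRole", function(x) standardGeneric("splitRole"))

#' Classifier contract generics
#'
#' Any classifier participating in the robustness protocol implements three
#' methods: \code{predictLabels} (hard 0/1 calls), \code{predictScores}
#' (real-valued positive-class scores, required by the SPSA attack) and
#' \code{retrain} (same architecture, fresh weights, new training data).
#'
#' @param object A trained classifier.
#' @param newdata A \linkS4class{LabeledImageSet} or list of pixel matrices.
#' @param ... Passed to methods.
#' @return \code{predictLabels} an integer vector of 0/1 calls;
#'   \code{predictScores} a numeric vector (positive score = positive call).
#' @name classifier-contract
NULL

#' @rdname classifier-contract
#' @export
setGeneric("predictLabels", function(object, newdata, ...)
  standardGeneric("predictLabels"))

#' @rdname classifier-contract
#' @export
setGeneric("predictScores", function(object, newdata, ...)
  standardGeneric("predictScores"))

#' @param reference A trained classifier whose architecture is reused.
#' @param train A \linkS4class{LabeledImageSet} to retrain on.
#' @param seed Integer seed for the fresh weight initialisation.
#' @rdname classifier-contract
#' @export
setGeneric("retrain", function(reference, train, seed, ...)
  standardGeneric("retrain"))
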