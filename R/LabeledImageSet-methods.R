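#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname LabeledImageSet-accessors
#' @export
setMethod("images", "LabeledImageSet", function(x) x@images)

#' @rdname LabeledImageSet-accessors
#' @export
setMethod("imageIds", "LabeledImageSet", function(x) x@ids)

#' @rdname LabeledImageSet-accessors
#' @export
setMethod("splitRole", "LabeledImageSet", function(x) x@split)

#' @rdname LabeledImageSet-accessors
#' @export
setMethod("labels", "LabeledImageSet", function(object, ...) object@labels)

#' @rdname LabeledImageSet-accessors
#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@images))

#' Image dimensions of a set
#'
#' @param x A \linkS4class{LabeledImageSet}.
#' @return Integer (rows, cols) of the first image, or NULL if empty.
#' @export
imageDim <- function(x) {
  if (length(x@images) == 0L) return(NULL)
  dim(x@images[[1L]])
}

#' @param i Index vector (integer, logical or id character).
#' @param j,drop Ignored.
#' @rdname LabeledImageSet-accessors
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("LabeledImageSet", images = x@images[i], labels = x@labels[i],
      ids = x@ids[i], split = x@split)
})

setMethod("show", "LabeledImageSet", function(object) {
  d <- imageDim(object)
  cat(sprintf("LabeledImageSet: %d images (%s split)\n",
              length(object), object@split))
  if (!is.null(d))
    cat(sprintf("  dimensions: %d x %d\n", d[1], d[2]))
  cat(sprintf("  labels: %d positive / %d negative\n",
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

setMethod("show", "PerturbationConfig", function(object) {
  cat("PerturbationConfig\n",
      sprintf("  noise sigma (unit scale): %g\n", object@noiseSigma),
      sprintf("  contrast factor (EF):     %g\n", object@contrastFactor),
      sprintf("  rotation range (deg):     [%d, %d]\n",
              object@rotationRange[1], object@rotationRange[2]),
      sprintf("  tilt range (deg):         [%d, %d]\n",
              object@tiltRange[1], object@tiltRange[2]),
      sprintf("  blur kernel / sd:         %d / %g\n",
              object@blurKernel, object@blurSigma), sep = "")
})
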