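# Intensity-scale conventions and file I/O for labeled image sets.
#
# Intensities are stored as integers on the 0-255 scale. All operators
# compute internally in floating point and quantize on output by rounding
# half away from zero, then clipping to [0, 255].

roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# float 0-255 -> stored integer representation
quantizeIntensity <- function(x) {
  out <- pmin(pmax(roundHalfAway(x), 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Convert a stored image to the unit scale
#'
#' Divides each 0--255 intensity by 255, giving values in [0, 1]; the
#' scale on which noise severities and the SPSA budget are expressed.
#'
#' @param img Numeric matrix on the 0--255 scale.
#' @return Numeric matrix of the same shape with values in [0, 1].
#' @seealso [fromUnitScale()]
#' @examples
#' toUnitScale(matrix(128L, 2, 2))
#' @export
toUnitScale <- function(img) {
  stopifnot(is.matrix(img))
  img / 255
}

#' Rescale a unit image back to the stored 0--255 representation
#'
#' Multiplies by 255, rounds half away from zero, and clips to [0, 255]
#' (values may fall outside [0, 1] after additive noise).
#'
#' @param u Numeric matrix, nominally on the unit scale.
#' @return Integer matrix with values in [0, 255].
#' @examples
#' fromUnitScale(matrix(c(-0.1, 0.5, 1.2), 1, 3))  # 0, 128, 255
#' @export
fromUnitScale <- function(u) {
  stopifnot(is.matrix(u))
  quantizeIntensity(u * 255)
}

# read one grayscale image file -> integer matrix 0-255; color inputs are
# collapsed to grayscale by the Rec. 601 luma weights
.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage uses (col, row [, channel]); transpose to (row, col)
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    a <- if (nch >= 3L)
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a[, , 1]
  }
  quantizeIntensity(a * 255)
}

#' Load a labeled image set from a directory or packed archive
#'
#' Two layouts are supported. A \emph{class-per-subfolder directory}: each
#' subdirectory holds the PNG/JPG images of one class, and \code{classes}
#' maps subdirectory names to 0/1 labels (the mappings neg/pos,
#' negative/positive and 0/1 are recognised automatically). A \emph{packed
#' archive} written by [saveImageSet()]. Color images are converted to
#' grayscale; ordering is deterministic (sorted by identifier).
#'
#' @param path Directory or archive file path.
#' @param split Split role to assign, one of train/validation/test.
#' @param classes Optional named integer vector mapping subdirectory name
#'   to label, e.g. \code{c(healthy = 0, disease = 1)}.
#' @return A \linkS4class{LabeledImageSet}.
#' @seealso [saveImageSet()]
#' @export
loadImageSet <- function(path, split = "train", classes = NULL) {
  if (!file.exists(path))
    stop("path does not exist: ", path)
  if (!dir.exists(path)) {
    payload <- readRDS(path)
    stopifnot(is.list(payload),
              all(c("images", "labels", "ids") %in% names(payload)))
    return(LabeledImageSet(payload$images, payload$labels, payload$ids,
                           split = split))
  }
  subdirs <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE),
                  method = "radix")
  if (length(subdirs) == 0L)
    stop("no class subdirectories found under ", path)
  if (is.null(classes)) {
    known <- list(c(neg = 0L, pos = 1L),
                  c(negative = 0L, positive = 1L),
                  c(`0` = 0L, `1` = 1L))
    hit <- Filter(function(m) setequal(names(m), subdirs), known)
    if (length(hit) == 0L)
      stop("label mapping absent: supply `classes` naming the ",
           "subdirectories (", paste(subdirs, collapse = ", "), ")")
    classes <- hit[[1L]]
  }
  if (!setequal(names(classes), subdirs))
    stop("`classes` must name exactly the subdirectories of ", path)
  files <- character(); labs <- integer(); ids <- character()
  for (d in subdirs) {
    fs <- sort(list.files(file.path(path, d),
                          pattern = "\\.(png|jpe?g)$", ignore.case = TRUE),
               method = "radix")
    files <- c(files, file.path(path, d, fs))
    labs <- c(labs, rep(classes[[d]], length(fs)))
    ids <- c(ids, paste0(d, "/", tools::file_path_sans_ext(fs)))
  }
  if (length(files) == 0L)
    stop("no PNG/JPG images found under ", path)
  ord <- order(ids, method = "radix")
  imgs <- lapply(files[ord], .readImageFile)
  LabeledImageSet(imgs, labs[ord], ids[ord], split = split)
}

#' Save a labeled image set as a packed archive with manifest
#'
#' Writes a single archive file (image stack, label vector, id list) plus
#' a plain-text manifest CSV (\code{id, label, split}) alongside it.
#'
#' @param x A \linkS4class{LabeledImageSet}.
#' @param path Archive file path (conventionally \code{.rds}).
#' @return \code{path}, invisibly.
#' @export
saveImageSet <- function(x, path) {
  stopifnot(is(x, "LabeledImageSet"))
  saveRDS(list(images = x@images, labels = x@labels, ids = x@ids,
               split = x@split), path)
  manifest <- data.frame(id = x@ids, label = x@labels,
                         split = x@split, stringsAsFactors = FALSE)
  utils::write.csv(manifest,
                   paste0(tools::file_path_sans_ext(path), "_manifest.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Resize a grayscale image
#'
#' Utility for harmonising image dimensions before training. The
#' interpolation method is explicitly configurable because resampling
#' choices are not neutral for downstream classification.
#'
#' @param img Integer matrix on the 0--255 scale.
#' @param rows,cols Target dimensions.
#' @param method \code{"bilinear"} (default) or \code{"nearest"}.
#' @return Integer matrix of dimension \code{rows x cols}.
#' @export
resizeImage <- function(img, rows, cols, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  # map output pixel centers onto the input grid (0-based)
  ys <- (seq_len(rows) - 0.5) * H / rows - 0.5
  xs <- (seq_len(cols) - 0.5) * W / cols - 0.5
  grid <- expand.grid(y = ys, x = xs)
  vals <- if (method == "nearest") {
    r <- pmin(pmax(roundHalfAway(grid$y), 0), H - 1)
    c_ <- pmin(pmax(roundHalfAway(grid$x), 0), W - 1)
    img[cbind(r + 1, c_ + 1)]
  } else {
    .bilinearSample(img, grid$x, grid$y, clampEdges = TRUE)
  }
  quantizeIntensity(matrix(vals, rows, cols))
}
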