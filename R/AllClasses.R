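#' LabeledCloud: a point cloud with optional per-point class labels
#'
#' The unit of all I/O, preprocessing, augmentation and inference in
#' panicle3D. Coordinates are an N x 3 numeric matrix (arbitrary units before
#' normalization, unit-cube units after); labels, when present, are integers
#' in \{0, 1\} with 0 = stem and 1 = panicle (ear).
#'
#' @slot coords N x 3 numeric matrix of finite coordinates.
#' @slot labels Integer vector of length N in \{0,1\}, or length 0 when the
#'   cloud is unlabeled.
#' @slot name Identifier string.
#' @aliases LabeledCloud
#' @exportClass LabeledCloud
setClass("LabeledCloud",
  representation(coords = "matrix", labels = "integer", name = "character"),
  prototype(coords = matrix(numeric(0), 0, 3), labels = integer(0),
            name = "cloud")
)

setValidity("LabeledCloud", function(object) {
  msgs <- character(0)
  if (ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must have 3 columns")
  if (nrow(object@coords) < 1L)
    msgs <- c(msgs, "cloud must contain at least one point")
  if (!all(is.finite(object@coords)))
    msgs <- c(msgs, "all coordinates must be finite")
  if (length(object@labels) > 0L) {
    if (length(object@labels) != nrow(object@coords))
      msgs <- c(msgs, "labels length must equal the number of points")
    if (!all(object@labels %in% c(0L, 1L)))
      msgs <- c(msgs, "labels must be 0 (stem) or 1 (panicle)")
  }
  if (length(object@name) != 1L)
    msgs <- c(msgs, "name must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledCloud
#'
#' @param coords N x 3 numeric matrix (or coercible) of point coordinates.
#' @param labels Optional integer vector of per-point labels in \{0,1\}
#'   (0 = stem, 1 = panicle); `NULL` for an unlabeled cloud.
#' @param name Identifier string.
#' @return A [LabeledCloud-class] object.
#' @examples
#' cl <- LabeledCloud(matrix(runif(30), 10, 3), labels = rep(0:1, 5))
#' nPoints(cl)
#' @export
LabeledCloud <- function(coords, labels = NULL, name = "cloud") {
  coords <- asCoordMatrix(coords)
  dimnames(coords) <- NULL
  if (is.null(labels)) labels <- integer(0)
  new("LabeledCloud", coords = coords, labels = as.integer(labels),
      name = as.character(name))
}

#' CloudDataset: an ordered collection of uniformly sized labeled clouds
#'
#' Every member cloud must be labeled and carry the same point count, so the
#' collection can be fed directly to a fixed-input-size network. Optional
#' split tags assign each cloud to the training or held-out test partition.
#'
#' @slot clouds List of [LabeledCloud-class] objects.
#' @slot splits Character vector ("train"/"test") of the same length as
#'   `clouds`, or length 0 when no split has been assigned.
#' @aliases CloudDataset
#' @exportClass CloudDataset
setClass("CloudDataset",
  representation(clouds = "list", splits = "character"),
  prototype(clouds = list(), splits = character(0))
)

setValidity("CloudDataset", function(object) {
  msgs <- character(0)
  if (length(object@clouds) == 0L)
    msgs <- c(msgs, "dataset must contain at least one cloud")
  if (!all(vapply(object@clouds, is, logical(1), class2 = "LabeledCloud")))
    msgs <- c(msgs, "all members must be LabeledCloud objects")
  else {
    ns <- vapply(object@clouds, function(x) nrow(x@coords), integer(1))
    if (length(unique(ns)) > 1L)
      msgs <- c(msgs, "all clouds must have the same point count")
    if (!all(vapply(object@clouds, function(x) length(x@labels) > 0L,
                    logical(1))))
      msgs <- c(msgs, "every member cloud must be labeled")
  }
  if (length(object@splits) > 0L) {
    if (length(object@splits) != length(object@clouds))
      msgs <- c(msgs, "splits length must match the number of clouds")
    if (!all(object@splits %in% c("train", "test")))
      msgs <- c(msgs, "splits must be 'train' or 'test'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CloudDataset
#'
#' @param clouds List of labeled [LabeledCloud-class] objects with identical
#'   point counts.
#' @param splits Optional character vector of "train"/"test" tags, one per
#'   cloud.
#' @return A [CloudDataset-class] object.
#' @export
CloudDataset <- function(clouds, splits = NULL) {
  if (is.null(splits)) splits <- character(0)
  new("CloudDataset", clouds = clouds, splits = as.character(splits))
}
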