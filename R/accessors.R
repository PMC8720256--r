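#' @rdname LabeledCloud
#' @param object,x A `LabeledCloud` or `CloudDataset`.
#' @export
setGeneric("cloudCoords", function(object) standardGeneric("cloudCoords"))

#' @rdname LabeledCloud
#' @export
setMethod("cloudCoords", "LabeledCloud", function(object) object@coords)

#' @rdname LabeledCloud
#' @export
setGeneric("cloudLabels", function(object) standardGeneric("cloudLabels"))

#' @rdname LabeledCloud
#' @export
setMethod("cloudLabels", "LabeledCloud", function(object) {
  if (length(object@labels)) object@labels else NULL
})

#' @rdname LabeledCloud
#' @export
setGeneric("cloudName", function(object) standardGeneric("cloudName"))

#' @rdname LabeledCloud
#' @export
setMethod("cloudName", "LabeledCloud", function(object) object@name)

#' @rdname LabeledCloud
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname LabeledCloud
#' @export
setMethod("nPoints", "LabeledCloud", function(object) nrow(object@coords))

#' @rdname LabeledCloud
#' @export
setGeneric("isLabeled", function(object) standardGeneric("isLabeled"))

#' @rdname LabeledCloud
#' @export
setMethod("isLabeled", "LabeledCloud",
          function(object) length(object@labels) > 0L)

setMethod("show", "LabeledCloud", function(object) {
  lab <- if (isLabeled(object)) {
    sprintf("labeled (%d stem / %d panicle)",
            sum(object@labels == 0L), sum(object@labels == 1L))
  } else "unlabeled"
  cat(sprintf("LabeledCloud '%s': %d points, %s\n",
              object@name, nPoints(object), lab))
})

#' Replace a cloud's points, carrying a subset of labels along
#'
#' Internal helper used by all filtering/resampling steps so the per-point
#' label association is never broken.
#' @keywords internal
subsetCloud <- function(cloud, idx) {
  labs <- if (isLabeled(cloud)) cloud@labels[idx] else NULL
  LabeledCloud(cloud@coords[idx, , drop = FALSE], labs, cloud@name)
}

replaceCoords <- function(cloud, coords) {
  LabeledCloud(coords, cloudLabels(cloud), cloud@name)
}

#' @rdname CloudDataset
#' @param object A `CloudDataset`.
#' @export
setGeneric("cloudList", function(object) standardGeneric("cloudList"))

#' @rdname CloudDataset
#' @export
setMethod("cloudList", "CloudDataset", function(object) object@clouds)

#' @rdname CloudDataset
#' @export
setGeneric("splitTags", function(object) standardGeneric("splitTags"))

#' @rdname CloudDataset
#' @export
setMethod("splitTags", "CloudDataset", function(object) {
  if (length(object@splits)) object@splits else NULL
})

#' @rdname CloudDataset
#' @export
setMethod("length", "CloudDataset", function(x) length(x@clouds))

#' @rdname CloudDataset
#' @param i Index.
#' @param j,drop,... Ignored (matrix-style extraction is not supported).
#' @export
setMethod("[[", "CloudDataset", function(x, i, j, ...) x@clouds[[i]])

setMethod("show", "CloudDataset", function(object) {
  n <- length(object@clouds)
  np <- if (n) nPoints(object@clouds[[1L]]) else 0L
  sp <- if (length(object@splits)) {
    sprintf(", %d train / %d test", sum(object@splits == "train"),
            sum(object@splits == "test"))
  } else ""
  cat(sprintf("CloudDataset: %d clouds of %d points%s\n", n, np, sp))
})
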