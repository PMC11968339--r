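#' CTVolume: a patient CT voxel grid
#'
#' A 3D grid of Hounsfield-unit (HU) intensities with axis order
#' (slice, row, col) and per-axis spacing in millimetres. Axial in-plane
#' matrices are typically 512 x 512 at a 3 mm slice interval.
#'
#' @slot voxels 3D numeric array, dimensions (slices, rows, cols), HU values.
#' @slot spacing numeric length-3, (slice_mm, row_mm, col_mm), all positive.
#' @slot patientId single character identifier.
#'
#' @seealso [readPatient()], [medianDenoise()], [huWindow()]
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric",
                 patientId = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L || any(d < 1L))
      msg <- c(msg, "voxels must be a 3D array with all dimensions >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite numbers")
    if (any(!is.finite(object@voxels)))
      msg <- c(msg, "voxel intensities must be finite")
    if (length(object@patientId) != 1L)
      msg <- c(msg, "patientId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' ROIMask: a labelled segmentation grid paired with a CTVolume
#'
#' Integer labels on the same grid as the paired volume. Before lymph-node
#' grouping the convention is 0 = background, 1 = tumor, 2 = lymph; after
#' [relabelGroups()] each anatomical node mass carries its own id >= 2.
#'
#' @slot labels 3D integer array, same dimensions as the paired volume.
#' @export
setClass("ROIMask",
  representation(labels = "array"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@labels)
    if (length(d) != 3L || any(d < 1L))
      msg <- c(msg, "labels must be a 3D array with all dimensions >= 1")
    lv <- object@labels
    if (any(!is.finite(lv)) || any(lv < 0) || any(lv != round(lv)))
      msg <- c(msg, "labels must be non-negative integers")
    if (length(msg)) msg else TRUE
  })

#' PlaneImage: a 2D training plane with pixel provenance
#'
#' A square grayscale image with intensities in [0, 1] and a provenance grid
#' recording each pixel's source: 0 background, 1 tumor, >= 2 the lymph-node
#' group id. Pixels are zero wherever provenance is zero (the plane contains
#' only ROI tissue).
#'
#' @slot pixels numeric matrix, values in [0, 1].
#' @slot provenance integer matrix, same shape as `pixels`.
#' @slot variant one of "PJ", "TM", "ZC" (or "ROI" for single-lesion score
#'   tiles).
#' @export
setClass("PlaneImage",
  representation(pixels = "matrix", provenance = "matrix",
                 variant = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@pixels), dim(object@provenance)))
      msg <- c(msg, "pixels and provenance must have identical shapes")
    if (any(object@pixels < -1e-9) || any(object@pixels > 1 + 1e-9))
      msg <- c(msg, "pixels must lie within [0, 1]")
    if (any(object@pixels[object@provenance == 0] != 0))
      msg <- c(msg, "pixels must be 0 wherever provenance is 0")
    if (any(object@provenance < 0) ||
        any(object@provenance != round(object@provenance)))
      msg <- c(msg, "provenance must hold non-negative integers")
    if (length(object@variant) != 1L)
      msg <- c(msg, "variant must be a single string")
    if (length(msg)) msg else TRUE
  })

#' LymphGroup: one anatomical lymph-node mass
#'
#' The 3D-connected set of lymph voxels forming one node mass, its group id
#' (>= 2), and the largest single-slice ROI used for projection.
#'
#' @slot groupId integer-valued scalar >= 2.
#' @slot voxels integer matrix with columns (slice, row, col), 1-based.
#' @slot maxSlice slice index (1-based) of the largest per-slice ROI.
#' @slot maxRoiPixels integer matrix with columns (row, col) on `maxSlice`.
#' @export
setClass("LymphGroup",
  representation(groupId = "numeric", voxels = "matrix",
                 maxSlice = "numeric", maxRoiPixels = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@groupId < 2) msg <- c(msg, "groupId must be >= 2")
    if (nrow(object@voxels) < 1L) msg <- c(msg, "voxels must be non-empty")
    if (ncol(object@voxels) != 3L)
      msg <- c(msg, "voxels must have columns (slice, row, col)")
    if (ncol(object@maxRoiPixels) != 2L)
      msg <- c(msg, "maxRoiPixels must have columns (row, col)")
    on_max <- object@voxels[object@voxels[, 1] == object@maxSlice, , drop = FALSE]
    if (nrow(object@maxRoiPixels) != nrow(on_max))
      msg <- c(msg, "maxRoiPixels must equal the group's pixels on maxSlice")
    if (length(msg)) msg else TRUE
  })

#' @rdname CTVolume-class
#' @param voxels,spacing,patientId see slot descriptions.
#' @export
CTVolume <- function(voxels, spacing = c(3, 1, 1), patientId = "patient") {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      patientId = as.character(patientId))
}

#' @rdname ROIMask-class
#' @param labels see slot description.
#' @export
ROIMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("ROIMask", labels = labels)
}

#' @rdname PlaneImage-class
#' @param pixels,provenance,variant see slot descriptions.
#' @export
PlaneImage <- function(pixels, provenance, variant = "PJ") {
  storage.mode(provenance) <- "integer"
  new("PlaneImage", pixels = pixels, provenance = provenance,
      variant = variant)
}
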