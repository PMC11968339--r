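# Accessor generics and show methods for the core S4 classes.

#' @rdname CTVolume-class
#' @param object,x a LymphPlane S4 object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname CTVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname CTVolume-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname ROIMask-class
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname PlaneImage-class
#' @export
setGeneric("planePixels", function(x) standardGeneric("planePixels"))
#' @rdname PlaneImage-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname PlaneImage-class
#' @export
setGeneric("planeVariant", function(x) standardGeneric("planeVariant"))
#' @rdname LymphGroup-class
#' @export
setGeneric("groupId", function(x) standardGeneric("groupId"))
#' @rdname LymphGroup-class
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname LymphGroup-class
#' @export
setGeneric("maxSlice", function(x) standardGeneric("maxSlice"))
#' @rdname LymphGroup-class
#' @export
setGeneric("maxRoiPixels", function(x) standardGeneric("maxRoiPixels"))

#' @rdname CTVolume-class
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname CTVolume-class
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)
#' @rdname CTVolume-class
#' @export
setMethod("patientId", "CTVolume", function(x) x@patientId)
#' @rdname ROIMask-class
#' @export
setMethod("maskLabels", "ROIMask", function(x) x@labels)
#' @rdname PlaneImage-class
#' @export
setMethod("planePixels", "PlaneImage", function(x) x@pixels)
#' @rdname PlaneImage-class
#' @export
setMethod("provenance", "PlaneImage", function(x) x@provenance)
#' @rdname PlaneImage-class
#' @export
setMethod("planeVariant", "PlaneImage", function(x) x@variant)
#' @rdname LymphGroup-class
#' @export
setMethod("groupId", "LymphGroup", function(x) x@groupId)
#' @rdname LymphGroup-class
#' @export
setMethod("voxelCount", "LymphGroup", function(x) nrow(x@voxels))
#' @rdname LymphGroup-class
#' @export
setMethod("maxSlice", "LymphGroup", function(x) x@maxSlice)
#' @rdname LymphGroup-class
#' @export
setMethod("maxRoiPixels", "LymphGroup", function(x) x@maxRoiPixels)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume '%s': %d slices x %d x %d, spacing %.1f/%.1f/%.1f mm, HU [%d, %d]\n",
              object@patientId, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              round(min(object@voxels)), round(max(object@voxels))))
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@labels)
  tab <- table(object@labels[object@labels > 0])
  cat(sprintf("ROIMask: %d x %d x %d; labels: %s\n", d[1], d[2], d[3],
              if (length(tab)) paste(sprintf("%s (%d vox)", names(tab), tab),
                                     collapse = ", ") else "none"))
})

setMethod("show", "PlaneImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PlaneImage [%s]: %d x %d, %d ROI pixels, %d lymph group(s)\n",
              object@variant, d[1], d[2], sum(object@provenance > 0),
              length(setdiff(unique(as.vector(object@provenance)), c(0, 1)))))
})

setMethod("show", "LymphGroup", function(object) {
  cat(sprintf("LymphGroup %d: %d voxels over %d slice(s); max ROI %d px on slice %d\n",
              object@groupId, nrow(object@voxels),
              length(unique(object@voxels[, 1])),
              nrow(object@maxRoiPixels), object@maxSlice))
})
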