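# Grouping of lymph ROI voxels into anatomical node masses. A node seen on
# several adjacent slices is one 3D connected component of lymph-labelled
# voxels; components are found by breadth-first search, sorted by total voxel
# count, written back into the mask under fresh ids >= 2, and each group
# contributes its largest single-slice ROI to the projection.

.group_from_voxels <- function(id, vox) {
  # vox: integer matrix (slice, row, col), 1-based
  tab <- table(vox[, 1])
  counts <- as.integer(tab)
  slices <- as.integer(names(tab))
  ms <- slices[counts == max(counts)][1]  # tie -> smallest slice index
  on_max <- vox[vox[, 1] == ms, c(2, 3), drop = FALSE]
  new("LymphGroup", groupId = as.numeric(id), voxels = vox,
      maxSlice = as.numeric(ms), maxRoiPixels = on_max)
}

#' Identify lymph-node groups as 3D connected components
#'
#' Breadth-first search over the lymph voxels (any mask label >= 2) under the
#' chosen 3D connectivity partitions them into maximal connected components,
#' one per anatomical node mass. Group ids are assigned 2, 3, ... in
#' lexicographic (slice, row, col) seed order; [sortGroups()] remaps them by
#' size.
#'
#' @param mask a [ROIMask-class] (pre-grouping convention, lymph = 2; a
#'   relabelled mask regroups to the identical partition).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners,
#'   the default: it merges the same node seen on adjacent slices even under
#'   slight in-plane drift).
#' @return list of [LymphGroup-class]; empty list when no lymph voxels exist.
#' @export
groupComponents <- function(mask, connectivity = 26L) {
  lab <- maskLabels(mask)
  lymph <- array(0L, dim(lab))
  lymph[lab >= 2L] <- 1L
  if (!any(lymph == 1L)) return(list())
  comp <- cpp_label_components3d(lymph, dim(lymph), 1L,
                                 as.integer(connectivity), 2L)
  ids <- sort(unique(comp[comp > 0L]))
  lapply(ids, function(id) {
    vox <- which(comp == id, arr.ind = TRUE)
    colnames(vox) <- c("slice", "row", "col")
    # which() returns indices ordered column-major = (slice fastest); reorder
    # lexicographically by (slice, row, col) for a deterministic seed voxel
    vox <- vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
    .group_from_voxels(id, vox)
  })
}

#' Sort lymph-node groups by size
#'
#' Descending by total voxel count; ties broken by the lexicographically
#' smallest (slice, row, col) voxel of each group, so the order is
#' deterministic. Group ids are remapped to 2, 3, ... in sorted order.
#'
#' @param groups list of [LymphGroup-class].
#' @return the sorted, re-identified list.
#' @export
sortGroups <- function(groups) {
  if (length(groups) == 0L) return(groups)
  counts <- vapply(groups, voxelCount, numeric(1))
  seeds <- t(vapply(groups, function(g) g@voxels[1, ], numeric(3)))
  ord <- order(-counts, seeds[, 1], seeds[, 2], seeds[, 3])
  out <- groups[ord]
  for (i in seq_along(out)) out[[i]]@groupId <- i + 1
  out
}

#' Overwrite lymph labels with group ids
#'
#' Writes each group's id into the mask so that no voxel with the generic
#' lymph label 2 remains un-attributed; tumor (1) and background (0) are
#' untouched. Groups must partition the mask's lymph voxels.
#'
#' @param mask a [ROIMask-class].
#' @param groups list of [LymphGroup-class] (typically from [sortGroups()]).
#' @return a relabelled [ROIMask-class].
#' @export
relabelGroups <- function(mask, groups) {
  lab <- maskLabels(mask)
  out <- lab
  out[lab >= 2L] <- NA_integer_
  d <- dim(lab)
  for (g in groups) {
    idx <- g@voxels[, 1] + d[1] * (g@voxels[, 2] - 1L) +
      d[1] * d[2] * (g@voxels[, 3] - 1L)
    if (any(!is.na(out[idx])))
      stop("internal consistency error: groups overlap or cover non-lymph voxels")
    out[idx] <- as.integer(groupId(g))
  }
  if (anyNA(out))
    stop("internal consistency error: ", sum(is.na(out)),
         " lymph voxel(s) not covered by any group")
  ROIMask(out)
}

#' Largest single-slice ROI of a group
#'
#' @param group a [LymphGroup-class].
#' @return list with `maxSlice` (1-based index) and `maxRoiPixels`
#'   ((row, col) matrix); ties resolved to the smallest slice index.
#' @export
extractMaxRoi <- function(group) {
  list(maxSlice = maxSlice(group), maxRoiPixels = maxRoiPixels(group))
}

#' Per-group summary table
#'
#' @param groups list of [LymphGroup-class].
#' @return data.frame with group_id, voxel_count, n_slices, max_slice,
#'   max_roi_area.
#' @export
groupTable <- function(groups) {
  data.frame(
    group_id = vapply(groups, groupId, numeric(1)),
    voxel_count = vapply(groups, voxelCount, numeric(1)),
    n_slices = vapply(groups, function(g) length(unique(g@voxels[, 1])), numeric(1)),
    max_slice = vapply(groups, maxSlice, numeric(1)),
    max_roi_area = vapply(groups, function(g) nrow(maxRoiPixels(g)), numeric(1)))
}
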