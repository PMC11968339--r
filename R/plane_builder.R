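# Construction of the three training-plane variants.
#
# PJ  - the tumor-lymph projection plane: the datum slice (largest tumor ROI)
#       keeps its tumor pixels, then each node group's largest ROI is stamped
#       at its ORIGINAL in-plane coordinates onto still-blank positions, so
#       relative position and relative size survive the flattening.
# TM  - tumor-only control: the datum slice masked to the tumor ROI.
# ZC  - zoom-center concatenation control: every lesion is cropped to its
#       bounding box, rescaled to one fixed tile side and stitched onto a
#       blank canvas row-major, deliberately destroying position and size.

#' Select the datum plane
#'
#' The axial slice with the largest per-slice tumor ROI pixel count; ties go
#' to the smallest slice index.
#'
#' @param mask a [ROIMask-class] with tumor label 1 present.
#' @return 1-based slice index.
#' @export
selectDatumPlane <- function(mask) {
  lab <- maskLabels(mask)
  areas <- apply(lab == 1L, 1, sum)
  if (all(areas == 0)) stop("no tumor ROI in mask")
  which.max(areas)  # first maximum = smallest index
}

# Normalized [0,1] intensity image of one slice restricted to maskSel pixels.
.masked_slice <- function(volume, slice, sel, window) {
  img <- .normalizeHu(voxels(volume)[slice, , , drop = TRUE],
                      window[1], window[2])
  img[!sel] <- 0
  img
}

.finish_plane <- function(pix, prov, variant, targetSide, resample) {
  if (resample) {
    pix <- resamplePlane(pix, targetSide)
    prov <- resampleLabels(prov, targetSide)
    pix[prov == 0L] <- 0      # the plane contains only ROI tissue
    pix <- pmin(pmax(pix, 0), 1)
  }
  PlaneImage(pix, prov, variant = variant)
}

#' Build the tumor-only (TM) plane
#'
#' @param volume a [CTVolume-class].
#' @param mask a [ROIMask-class] (windowed; tumor = 1).
#' @param targetSide output side (default 224).
#' @param window HU window used for intensity normalization.
#' @param resample if `FALSE`, return the native-resolution plane (used by
#'   conservation checks).
#' @return a [PlaneImage-class] with provenance in {0, 1}.
#' @export
buildTmPlane <- function(volume, mask, targetSide = 224L,
                         window = c(-50, 300), resample = TRUE) {
  s0 <- selectDatumPlane(mask)
  sel <- maskLabels(mask)[s0, , , drop = TRUE] == 1L
  pix <- .masked_slice(volume, s0, sel, window)
  prov <- matrix(0L, nrow(pix), ncol(pix))
  prov[sel] <- 1L
  .finish_plane(pix, prov, "TM", targetSide, resample)
}

#' Build the tumor-lymph projection (PJ) plane
#'
#' Starts from the datum slice masked to the tumor ROI, then for each sorted
#' group stamps its largest single-slice ROI at the original (row, col)
#' coordinates onto positions still blank, copying the source-slice
#' intensities. Tumor pixels are never overwritten and stamping is
#' append-only, so larger groups win contested pixels.
#'
#' @param volume a [CTVolume-class].
#' @param mask a [ROIMask-class] (windowed).
#' @param groups sorted list of [LymphGroup-class] (see [sortGroups()]).
#' @inheritParams buildTmPlane
#' @return a [PlaneImage-class]; provenance 1 = tumor, >= 2 = group id.
#' @export
buildPjPlane <- function(volume, mask, groups, targetSide = 224L,
                         window = c(-50, 300), resample = TRUE) {
  s0 <- selectDatumPlane(mask)
  sel <- maskLabels(mask)[s0, , , drop = TRUE] == 1L
  pix <- .masked_slice(volume, s0, sel, window)
  prov <- matrix(0L, nrow(pix), ncol(pix))
  prov[sel] <- 1L
  for (g in groups) {
    px <- maxRoiPixels(g)
    idx <- px[, 1] + nrow(prov) * (px[, 2] - 1L)
    blank <- prov[idx] == 0L
    if (!any(blank)) next
    src <- .normalizeHu(voxels(volume)[maxSlice(g), , , drop = TRUE],
                        window[1], window[2])
    pix[idx[blank]] <- src[idx[blank]]
    prov[idx[blank]] <- as.integer(groupId(g))
  }
  .finish_plane(pix, prov, "PJ", targetSide, resample)
}

# Crop a pixel set to its bounding box on one slice, masked and normalized,
# and rescale to a square tile. Rescaling is nearest-neighbour for both
# intensity and provenance: interpolation would imprint the zoom factor on
# the tile (edge softness, noise granularity), leaking the lesion's original
# size through a transform whose purpose is to discard it.
.lesion_tile <- function(volume, slice, px, provValue, tileSide, window) {
  r0 <- range(px[, 1]); c0 <- range(px[, 2])
  sel <- matrix(FALSE, r0[2] - r0[1] + 1L, c0[2] - c0[1] + 1L)
  sel[cbind(px[, 1] - r0[1] + 1L, px[, 2] - c0[1] + 1L)] <- TRUE
  img <- .normalizeHu(voxels(volume)[slice, r0[1]:r0[2], c0[1]:c0[2], drop = TRUE],
                      window[1], window[2])
  img <- matrix(img, nrow(sel), ncol(sel))
  img[!sel] <- 0
  ri <- pmin(floor((seq_len(tileSide) - 0.5) * nrow(sel) / tileSide), nrow(sel) - 1L) + 1L
  ci <- pmin(floor((seq_len(tileSide) - 0.5) * ncol(sel) / tileSide), ncol(sel) - 1L) + 1L
  tile <- img[ri, ci, drop = FALSE]
  prov <- matrix(as.integer(sel[ri, ci]) * as.integer(provValue),
                 tileSide, tileSide)
  # antialias with a fixed-size box blur: contour staircases and noise blocks
  # produced by rescaling have a spatial period proportional to the zoom
  # factor, i.e. they re-encode the lesion's original size; a uniform blur
  # erases that artifact scale without favouring any tile
  tile <- .box_blur(tile, 5L)
  tile[prov == 0L] <- 0
  list(pix = pmin(pmax(tile, 0), 1), prov = prov)
}

# separable box blur via padded cumulative sums
.box_blur <- function(x, k) {
  r <- (k - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  xp <- x[pad_idx(H), pad_idx(W), drop = FALSE]
  cs <- apply(xp, 2, cumsum)
  vert <- (cs[(k):(H + 2L * r), , drop = FALSE] -
             rbind(0, cs[seq_len(H + 2L * r - k), , drop = FALSE])) / k
  cs2 <- t(apply(vert, 1, cumsum))
  (cs2[, (k):(W + 2L * r), drop = FALSE] -
      cbind(0, cs2[, seq_len(W + 2L * r - k), drop = FALSE])) / k
}

#' Build the zoom-center concatenation (ZC) plane
#'
#' The tumor's datum-slice ROI and each group's largest ROI are individually
#' cropped to their bounding boxes, rescaled to a fixed uniform tile side and
#' placed row-major (tumor first, then groups in sorted order) on a blank
#' canvas. Position and relative size are deliberately destroyed: the output
#' is invariant to rigid translation of the nodes in the source volume.
#'
#' @inheritParams buildPjPlane
#' @param tileSide side of each lesion tile (default 56; a 4 x 4 grid fills
#'   the 224 canvas, tumor + up to 15 groups, surplus groups dropped).
#' @param grid (rows, cols) of the tile layout.
#' @return a [PlaneImage-class].
#' @export
buildZcPlane <- function(volume, mask, groups, targetSide = 224L,
                         tileSide = 56L, grid = c(4L, 4L),
                         window = c(-50, 300)) {
  s0 <- selectDatumPlane(mask)
  tsel <- which(maskLabels(mask)[s0, , , drop = TRUE] == 1L, arr.ind = TRUE)
  capacity <- prod(grid)
  tiles <- list(.lesion_tile(volume, s0, tsel, 1L, tileSide, window))
  for (g in head(groups, capacity - 1L))
    tiles <- c(tiles, list(.lesion_tile(volume, maxSlice(g), maxRoiPixels(g),
                                        as.integer(groupId(g)), tileSide, window)))
  canvasSide <- max(grid) * tileSide
  pix <- matrix(0, canvasSide, canvasSide)
  prov <- matrix(0L, canvasSide, canvasSide)
  for (i in seq_along(tiles)) {
    ri <- (i - 1L) %/% grid[2]
    ci <- (i - 1L) %% grid[2]
    rows <- (ri * tileSide + 1L):((ri + 1L) * tileSide)
    cols <- (ci * tileSide + 1L):((ci + 1L) * tileSide)
    pix[rows, cols] <- tiles[[i]]$pix
    prov[rows, cols] <- tiles[[i]]$prov
  }
  if (canvasSide != targetSide) {
    pix <- resamplePlane(pix, targetSide)
    prov <- resampleLabels(prov, targetSide)
    pix[prov == 0L] <- 0
    pix <- pmin(pmax(pix, 0), 1)
  }
  PlaneImage(pix, prov, variant = "ZC")
}

#' Build a centered single-lesion plane for feature scoring
#'
#' Reuses the ZC tile pipeline: crop one lesion to its bounding box, rescale
#' to `tileSide`, and center it on a blank `side` x `side` canvas. A `NULL`
#' pixel set yields the all-blank plane used to pad missing nodes.
#'
#' @param volume a [CTVolume-class] (ignored for blank planes).
#' @param slice source slice index.
#' @param px (row, col) pixel matrix of the lesion ROI, or `NULL`.
#' @param side canvas side (default 224).
#' @param tileSide lesion tile side (default 112).
#' @param window HU window.
#' @return a [PlaneImage-class] with variant "ROI".
#' @export
singleRoiPlane <- function(volume, slice, px, side = 224L, tileSide = 112L,
                           window = c(-50, 300)) {
  pix <- matrix(0, side, side)
  prov <- matrix(0L, side, side)
  if (!is.null(px) && nrow(px) > 0) {
    tile <- .lesion_tile(volume, slice, px, 1L, tileSide, window)
    off <- (side - tileSide) %/% 2L
    rows <- (off + 1L):(off + tileSide)
    pix[rows, rows] <- tile$pix
    prov[rows, rows] <- tile$prov
  }
  PlaneImage(pix, prov, variant = "ROI")
}

#' Preprocess a patient and build one training plane
#'
#' Convenience wrapper running the full preprocessing chain: median
#' denoising, HU windowing of the mask, node grouping and sorting, then the
#' requested plane variant.
#'
#' @param volume a [CTVolume-class].
#' @param mask a raw [ROIMask-class] (labels {0,1,2}).
#' @param variant "PJ", "TM" or "ZC".
#' @param connectivity 3D connectivity for grouping.
#' @param medianKernel odd side for [medianDenoise()] (default 3).
#' @param window HU window (default c(-50, 300)).
#' @param targetSide output side (default 224).
#' @return a [PlaneImage-class].
#' @export
buildPlane <- function(volume, mask, variant = c("PJ", "TM", "ZC"),
                       connectivity = 26L, medianKernel = 3L,
                       window = c(-50, 300), targetSide = 224L) {
  variant <- match.arg(variant)
  volume <- medianDenoise(volume, medianKernel)
  mask <- huWindow(volume, mask, window[1], window[2])
  groups <- sortGroups(groupComponents(mask, connectivity))
  switch(variant,
    PJ = buildPjPlane(volume, mask, groups, targetSide, window),
    TM = buildTmPlane(volume, mask, targetSide, window),
    ZC = buildZcPlane(volume, mask, groups, targetSide, window = window))
}
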