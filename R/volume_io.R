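# Volume/mask input-output and the CT preprocessing primitives:
# median denoising, Hounsfield-unit windowing of the mask, and plane
# resampling. File format is NRRD (text header + ascii or little-endian raw
# payload in one file), the de-facto exchange format for hand-delineated CT
# segmentations.

.nrrd_types <- c(double = "double", int = "int32", integer = "int32")

#' Write a 3D array as an NRRD file
#'
#' Minimal NRRD0004 writer: attached header, `ascii` (default) or `raw`
#' little-endian encoding, axis sizes fastest-first matching R's column-major
#' (slice, row, col) layout, and per-axis spacings.
#'
#' @param x 3D numeric or integer array.
#' @param path output file path.
#' @param spacing numeric length-3 per-axis spacing (mm).
#' @param encoding "ascii" or "raw".
#' @return `path`, invisibly.
#' @export
writeNrrd <- function(x, path, spacing = c(3, 1, 1), encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  stopifnot(length(dim(x)) == 3L)
  type <- if (is.integer(x) || all(x == round(x))) "int32" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by LymphPlane",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(x), collapse = " ")),
           sprintf("spacings: %s", paste(format(spacing, trim = TRUE), collapse = " ")),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(x), trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  } else {
    if (type == "int32") writeBin(as.integer(x), con, size = 4L, endian = "little")
    else writeBin(as.double(x), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD file written by [writeNrrd()] (attached header)
#'
#' @param path NRRD file path.
#' @return 3D array with attribute `spacing`.
#' @export
readNrrd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated NRRD header in ", path)
    if (ln == "") break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  if (enc == "ascii") {
    txt <- readLines(con)
    vals <- scan(text = paste(txt, collapse = " "), quiet = TRUE)
  } else if (enc == "raw") {
    if (type %in% c("int32", "int", "signed int"))
      vals <- readBin(con, "integer", n = n, size = 4L, endian = "little")
    else vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD payload has ", length(vals),
                              " values, expected ", n)
  arr <- array(vals, dim = sizes)
  if (!is.null(fields$spacings))
    attr(arr, "spacing") <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  arr
}

#' Read a co-registered patient volume and ROI mask
#'
#' Validates that the two grids share a shape and that the mask uses the
#' pre-grouping label convention {0 background, 1 tumor, 2 lymph}.
#'
#' @param volumePath,maskPath NRRD paths for intensities and labels.
#' @return a list with elements `volume` ([CTVolume-class]) and `mask`
#'   ([ROIMask-class]).
#' @export
readPatient <- function(volumePath, maskPath) {
  vox <- readNrrd(volumePath)
  lab <- readNrrd(maskPath)
  if (!identical(dim(vox), dim(lab)))
    stop(sprintf("shape mismatch: volume is (%s) but mask is (%s)",
                 paste(dim(vox), collapse = ","),
                 paste(dim(lab), collapse = ",")))
  bad <- setdiff(unique(as.vector(lab)), c(0L, 1L, 2L))
  if (length(bad))
    stop("unknown mask label value(s): ", paste(sort(bad), collapse = ", "),
         " (expected 0 background, 1 tumor, 2 lymph)")
  sp <- attr(vox, "spacing")
  if (is.null(sp)) sp <- c(3, 1, 1)
  pid <- sub("\\.nrrd$", "", basename(volumePath))
  pid <- sub("_volume$", "", pid)
  list(volume = CTVolume(array(as.double(vox), dim(vox)), spacing = sp,
                         patientId = pid),
       mask = ROIMask(array(as.integer(lab), dim(lab))))
}

#' Write a patient volume and mask as NRRD
#'
#' @param volume a [CTVolume-class].
#' @param mask a [ROIMask-class].
#' @param volumePath,maskPath output paths.
#' @param encoding "ascii" or "raw".
#' @export
writePatient <- function(volume, mask, volumePath, maskPath,
                         encoding = "ascii") {
  writeNrrd(voxels(volume), volumePath, spacing = spacing(volume),
            encoding = encoding)
  writeNrrd(maskLabels(mask), maskPath, spacing = spacing(volume),
            encoding = encoding)
  invisible(c(volumePath, maskPath))
}

#' Per-slice median denoising
#'
#' Applies a 2D median filter of side `kernel` to every axial slice, with
#' reflected edges. Values never leave the input's per-slice min/max range and
#' constant slices are unchanged.
#'
#' @param volume a [CTVolume-class].
#' @param kernel odd integer filter side (default 3).
#' @return a denoised [CTVolume-class].
#' @export
medianDenoise <- function(volume, kernel = 3L) {
  if (kernel %% 2 == 0 || kernel < 1)
    stop("kernel side must be an odd integer >= 1")
  v <- voxels(volume)
  out <- v
  for (s in seq_len(dim(v)[1]))
    out[s, , ] <- cpp_median_filter2d(v[s, , , drop = TRUE], as.integer(kernel))
  CTVolume(out, spacing = spacing(volume), patientId = patientId(volume))
}

#' Hounsfield-unit windowing of the ROI mask
#'
#' Drops ROI voxels whose paired HU intensity falls strictly outside
#' [`low`, `high`] (default [-50, +300], the soft-tissue band that excludes
#' fat, air and contrast-enhanced vessels). Boundary values are retained.
#' The mask support can only shrink.
#'
#' @param volume a [CTVolume-class].
#' @param mask a [ROIMask-class].
#' @param low,high window bounds in HU.
#' @return a new windowed [ROIMask-class].
#' @export
huWindow <- function(volume, mask, low = -50, high = 300) {
  if (low >= high) stop("low must be < high")
  v <- voxels(volume)
  lab <- maskLabels(mask)
  if (!identical(dim(v), dim(lab)))
    stop(sprintf("shape mismatch: volume is (%s) but mask is (%s)",
                 paste(dim(v), collapse = ","),
                 paste(dim(lab), collapse = ",")))
  lab[v < low | v > high] <- 0L
  ROIMask(lab)
}

#' Resample a 2D plane to a target side
#'
#' Bilinear interpolation for intensities; use [resampleLabels()] for label /
#' provenance grids (nearest neighbour, so no new label values appear).
#'
#' @param image numeric matrix.
#' @param targetSide output side in pixels (default 224).
#' @return `targetSide` x `targetSide` numeric matrix.
#' @export
resamplePlane <- function(image, targetSide = 224L) {
  stopifnot(nrow(image) >= 1, ncol(image) >= 1)
  cpp_resize_bilinear(image, as.integer(targetSide), as.integer(targetSide))
}

#' @rdname resamplePlane
#' @export
resampleLabels <- function(image, targetSide = 224L) {
  storage.mode(image) <- "integer"
  cpp_resize_nearest(image, as.integer(targetSide), as.integer(targetSide))
}

# Map windowed HU values linearly onto [0,1]; callers zero the background.
.normalizeHu <- function(x, low = -50, high = 300) {
  pmin(pmax((x - low) / (high - low), 0), 1)
}
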