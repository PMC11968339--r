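# Survival-derived binary labels, patient-level stratified splitting, and
# training-set augmentation/balancing.
#
# Censoring policy (stated, not silent): the cohort table holds one pooled
# time column (survival time for deaths, follow-up time for the censored).
# A label is assigned only when determinable — a patient censored before the
# cut-off (median or horizon) may or may not survive past it, and is
# excluded from that task.

#' Median-split survival labels
#'
#' The cut-off m is the median of the pooled time column over ALL records
#' (deaths and censored follow-ups alike). Label 1 when time > m (survival
#' beyond the median is already observed, dead or not); label 0 for deaths at
#' time <= m; `NA` (excluded) for patients censored at time <= m.
#'
#' @param records data.frame with columns `patient_id`, `time_months`,
#'   `event` (1 = dead, 0 = alive/censored).
#' @return data.frame (`patient_id`, `label`) with attribute
#'   `"median"`; indeterminate patients carry `NA` labels.
#' @export
medianSplitLabels <- function(records) {
  stopifnot(nrow(records) >= 2L)
  m <- median(records$time_months)
  lab <- ifelse(records$time_months > m, 1L,
                ifelse(records$event == 1L, 0L, NA_integer_))
  if (all(is.na(lab))) stop("all records indeterminate under the median split")
  out <- data.frame(patient_id = records$patient_id, label = lab)
  attr(out, "median") <- m
  out
}

#' Fixed-horizon survival labels
#'
#' Dead at time <= horizon: 0. Time > horizon (dead or censored): 1.
#' Censored at time <= horizon: `NA` (indeterminate, excluded).
#'
#' @inheritParams medianSplitLabels
#' @param horizonMonths horizon in months, conventionally 12, 36 or 60.
#' @return data.frame (`patient_id`, `label`).
#' @export
horizonLabels <- function(records, horizonMonths) {
  lab <- ifelse(records$time_months > horizonMonths, 1L,
                ifelse(records$event == 1L, 0L, NA_integer_))
  data.frame(patient_id = records$patient_id, label = lab)
}

#' Patient-level stratified train/test split
#'
#' Splits patient ids 7:3 (by default) within each label stratum, so class
#' proportions match across sides and no patient appears on both.
#'
#' @param labels data.frame (`patient_id`, `label`), `NA` labels dropped.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed; the split is reproducible for a fixed seed.
#' @return list with character vectors `train` and `test` of patient ids.
#' @export
splitDataset <- function(labels, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- labels[!is.na(labels$label), , drop = FALSE]
  if (length(unique(labels$label)) < 2L)
    stop("both classes must be present to split")
  set.seed(as.integer(seed))
  train <- character()
  for (cl in sort(unique(labels$label))) {
    ids <- labels$patient_id[labels$label == cl]
    ntr <- round(length(ids) * ratio)
    train <- c(train, sample(as.character(ids), ntr))
  }
  list(train = train,
       test = setdiff(as.character(labels$patient_id), train))
}

#' Augment one training plane
#'
#' Horizontal flip plus rigid rotation about the image center (bilinear for
#' intensities, nearest for provenance, zero fill outside the support).
#'
#' @param plane a [PlaneImage-class].
#' @param flip logical, mirror columns first.
#' @param angle rotation angle in degrees.
#' @return the transformed [PlaneImage-class].
#' @export
augmentPlane <- function(plane, flip = FALSE, angle = 0) {
  pix <- cpp_warp_rotate(planePixels(plane), angle, flip, FALSE)
  prov <- cpp_warp_rotate(planePixels(plane) * 0 + provenance(plane),
                          angle, flip, TRUE)
  storage.mode(prov) <- "integer"
  pix[prov == 0L] <- 0
  pix <- pmin(pmax(pix, 0), 1)
  PlaneImage(pix, prov, variant = planeVariant(plane))
}

#' Augment and class-balance a training set
#'
#' Every positive sample gains one augmented copy (flip with probability 0.5,
#' rotation angle uniform on [-60, 60] degrees), doubling the positives;
#' negatives are then randomly oversampled (augmented copies) or subsampled
#' until both classes have equal counts. Test data must never pass through
#' here.
#'
#' @param planes list of [PlaneImage-class].
#' @param labels integer vector in {0, 1}, one per plane.
#' @param seed integer seed.
#' @return list with `planes` (list) and `labels` (vector), class-balanced.
#' @export
augmentBalance <- function(planes, labels, seed = 1L) {
  stopifnot(length(planes) == length(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  set.seed(as.integer(seed))
  rand_aug <- function(p)
    augmentPlane(p, flip = runif(1) < 0.5, angle = runif(1, -60, 60))
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  out_planes <- planes
  out_labels <- labels
  for (i in pos) {                      # double the positives
    out_planes <- c(out_planes, list(rand_aug(planes[[i]])))
    out_labels <- c(out_labels, 1L)
  }
  target <- 2L * length(pos)
  if (length(neg) > target) {           # subsample surplus negatives
    drop <- sample(neg, length(neg) - target)
    keep <- setdiff(seq_along(out_labels), drop)
    out_planes <- out_planes[keep]
    out_labels <- out_labels[keep]
  } else if (length(neg) < target) {    # oversample with augmentation
    extra <- sample(neg, target - length(neg), replace = TRUE)
    for (i in extra) {
      out_planes <- c(out_planes, list(rand_aug(planes[[i]])))
      out_labels <- c(out_labels, 0L)
    }
  }
  list(planes = out_planes, labels = out_labels)
}
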