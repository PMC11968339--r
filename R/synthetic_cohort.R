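# Synthetic phantom cohorts. Each patient is a voxel grid with one
# ellipsoidal tumor near the vertical axis and 0-5 ellipsoidal lymph-node
# lesions at sampled displacements (some sharing slices with the tumor, some
# overlapping its in-plane footprint, so projection occlusion is exercised).
# Survival is exponential with a log-linear hazard in the tumor-lymph
# geometry: node count, minimum tumor-node centroid distance (closer ->
# higher hazard) and the largest-node/tumor volume ratio. The dominant terms
# are size and proximity — exactly the features the projection plane
# preserves and the zoom-center control destroys (node COUNT survives both
# transforms, so a count-dominated hazard could not separate the arms).

#' Phantom cohort parameters
#'
#' Defaults emulate a contrast-CT esophageal cohort at desk scale: 3 mm
#' slices, soft-tissue HU levels, node counts Poisson(2) capped at 5, a wide
#' node-size range, and a strongly geometry-coupled hazard dominated by node
#' size and tumor-node proximity, under ~46% random censoring plus a
#' 120-month follow-up window.
#'
#' @param nPatients cohort size.
#' @param shape volume dimensions (slices, rows, cols).
#' @param voxSpacing (slice, row, col) spacing in mm.
#' @param tumorRadius in-plane tumor semi-axis range (voxels).
#' @param tumorVertRadius tumor vertical semi-axis range (slices).
#' @param lymphLambda,lymphMax Poisson mean and cap for node count.
#' @param lymphRadius,lymphVertRadius node semi-axis ranges; the in-plane
#'   base radius is drawn once per patient and individual nodes vary by
#'   0.8-1.25x around it.
#' @param lymphDist radial displacement range of node centers from the tumor
#'   center, in-plane voxels.
#' @param lymphSliceOffset maximum |slice offset| of node centers.
#' @param huTumor,huLymph,huBackground,huSoft (mean, sd) HU of each tissue;
#'   for lesions the level is drawn per lesion and voxel texture is
#'   low-amplitude i.i.d. noise around it (see `textureSd`).
#' @param textureSd within-lesion voxel texture standard deviation (HU).
#' @param softRadius radius of the soft-tissue column (voxels).
#' @param h0 baseline hazard per month.
#' @param betaN per-node log-hazard increment.
#' @param betaD log-hazard per unit normalized distance (negative: closer
#'   nodes mean higher hazard); distance is normalized by `distScale` mm and
#'   node-free patients sit at `distFree`.
#' @param betaV log-hazard per unit largest-node/tumor volume ratio.
#' @param distScale,distFree distance normalization constants (mm, unitless).
#' @param censorRate probability of independent uniform censoring.
#' @param maxFollowup administrative censoring horizon (months).
#' @param seed cohort seed.
#' @return a `phantomParams` list.
#' @export
phantomParams <- function(nPatients = 300L, shape = c(24L, 128L, 128L),
                          voxSpacing = c(3, 1, 1),
                          tumorRadius = c(8, 14), tumorVertRadius = c(2, 4),
                          lymphLambda = 2, lymphMax = 5L,
                          lymphRadius = c(2, 10), lymphVertRadius = c(1, 2),
                          lymphDist = c(8, 45), lymphSliceOffset = 6L,
                          huTumor = c(60, 10), huLymph = c(40, 10),
                          huBackground = c(-700, 30), huSoft = c(30, 20),
                          textureSd = 3, softRadius = 48,
                          h0 = 0.02, betaN = 0.1, betaD = -2, betaV = 8,
                          distScale = 40, distFree = 1.5,
                          censorRate = 0.46, maxFollowup = 120,
                          seed = 1L) {
  stopifnot(all(shape >= 1), all(tumorRadius >= 1), all(lymphRadius >= 1),
            censorRate >= 0, censorRate < 1, h0 > 0)
  structure(as.list(environment()), class = "phantomParams")
}

# Stamp an ellipsoid into label/intensity grids. The lesion's mean HU level
# is drawn once from N(hu[1], hu[2]); voxel texture around it is i.i.d.
# N(0, textureSd). Low-amplitude texture is deliberate: zoom-resampled i.i.d.
# noise changes its granularity with the zoom factor, which would leak
# lesion size through the uniform-scale control's resampling statistics.
.stamp_ellipsoid <- function(vox, lab, center, semi, label, hu,
                             textureSd = 3) {
  d <- dim(lab)
  sl <- max(1L, floor(center[1] - semi[1])):min(d[1], ceiling(center[1] + semi[1]))
  rw <- max(1L, floor(center[2] - semi[2])):min(d[2], ceiling(center[2] + semi[2]))
  cl <- max(1L, floor(center[3] - semi[3])):min(d[3], ceiling(center[3] + semi[3]))
  sub <- expand.grid(s = sl, r = rw, c = cl)
  inside <- ((sub$s - center[1]) / semi[1])^2 +
    ((sub$r - center[2]) / semi[2])^2 +
    ((sub$c - center[3]) / semi[3])^2 <= 1
  sub <- sub[inside, , drop = FALSE]
  if (nrow(sub) == 0) return(list(vox = vox, lab = lab, n = 0L))
  idx <- sub$s + d[1] * (sub$r - 1L) + d[1] * d[2] * (sub$c - 1L)
  free <- lab[idx] == 0L | lab[idx] == label   # tumor takes precedence
  idx <- idx[free]
  lab[idx] <- label
  level <- rnorm(1, hu[1], hu[2])
  vox[idx] <- rnorm(length(idx), level, textureSd)
  list(vox = vox, lab = lab, n = length(idx))
}

#' Generate one phantom patient
#'
#' Uses the current RNG state (seed the stream yourself or via
#' [generateCohort()]).
#'
#' @param params a [phantomParams()] list.
#' @return list with `volume` ([CTVolume-class]), `mask` ([ROIMask-class],
#'   labels {0, 1, 2}) and `geometry` (node count `k`, minimum tumor-node
#'   centroid distance `dminMm`, largest-node/tumor `volRatio`, total
#'   `volRatioTotal`).
#' @export
generatePatient <- function(params) {
  d <- params$shape
  vox <- array(rnorm(prod(d), params$huBackground[1], params$huBackground[2]), d)
  # soft-tissue column around the vertical axis
  rc <- (d[2] + 1) / 2; cc <- (d[3] + 1) / 2
  dist2 <- outer((seq_len(d[2]) - rc)^2, (seq_len(d[3]) - cc)^2, "+")
  soft <- dist2 <= params$softRadius^2
  nsoft <- sum(soft)
  for (s in seq_len(d[1]))
    vox[s, , ][soft] <- rnorm(nsoft, params$huSoft[1], params$huSoft[2])
  lab <- array(0L, d)
  # tumor near the volume's vertical axis, middle slices
  tctr <- c(runif(1, d[1] * 0.35, d[1] * 0.65),
            rc + runif(1, -8, 8), cc + runif(1, -8, 8))
  tsemi <- c(runif(1, params$tumorVertRadius[1], params$tumorVertRadius[2]),
             runif(1, params$tumorRadius[1], params$tumorRadius[2]),
             runif(1, params$tumorRadius[1], params$tumorRadius[2]))
  st <- .stamp_ellipsoid(vox, lab, tctr, tsemi, 1L, params$huTumor,
                         params$textureSd)
  vox <- st$vox; lab <- st$lab
  tumor_n <- st$n
  # lymph nodes
  k <- min(rpois(1, params$lymphLambda), params$lymphMax)
  dmin <- Inf
  lymph_n <- 0L
  max_node <- 0L
  placed <- 0L
  # node sizes share a per-patient base radius (a patient's metastatic burden
  # grows the nodes jointly); individual nodes vary mildly around it. This
  # keeps node size — the hazard's dominant term — decoupled from node count.
  base_r <- runif(1, params$lymphRadius[1], params$lymphRadius[2])
  for (j in seq_len(k)) {
    semi <- c(runif(1, params$lymphVertRadius[1], params$lymphVertRadius[2]),
              base_r * runif(1, 0.8, 1.25), base_r * runif(1, 0.8, 1.25))
    ok <- FALSE
    for (try in 1:20) {
      dd <- runif(1, params$lymphDist[1], params$lymphDist[2])
      th <- runif(1, 0, 2 * pi)
      ctr <- c(tctr[1] + sample(seq(-params$lymphSliceOffset,
                                    params$lymphSliceOffset), 1),
               tctr[2] + dd * sin(th), tctr[3] + dd * cos(th))
      if (ctr[1] - semi[1] >= 1 && ctr[1] + semi[1] <= d[1] &&
          ctr[2] - semi[2] >= 1 && ctr[2] + semi[2] <= d[2] &&
          ctr[3] - semi[3] >= 1 && ctr[3] + semi[3] <= d[3]) { ok <- TRUE; break }
    }
    if (!ok) next
    st <- .stamp_ellipsoid(vox, lab, ctr, semi, 2L, params$huLymph,
                           params$textureSd)
    if (st$n == 0L) next
    vox <- st$vox; lab <- st$lab
    lymph_n <- lymph_n + st$n
    max_node <- max(max_node, st$n)
    placed <- placed + 1L
    dphys <- sqrt(sum(((ctr - tctr) * params$voxSpacing)^2))
    dmin <- min(dmin, dphys)
  }
  list(volume = CTVolume(vox, spacing = params$voxSpacing),
       mask = ROIMask(lab),
       geometry = list(k = placed, dminMm = dmin,
                       volRatio = max_node / max(tumor_n, 1L),
                       volRatioTotal = lymph_n / max(tumor_n, 1L)))
}

#' Geometry-coupled survival record
#'
#' Exponential survival at rate
#' `h0 * exp(betaN * k + betaD * dmin/distScale + betaV * volRatio)` where
#' `volRatio` is the largest-node/tumor volume ratio (node-free patients use
#' `distFree` in place of the normalized distance), with
#' independent uniform censoring at `censorRate` and administrative censoring
#' at `maxFollowup` months.
#'
#' @param geometry the `geometry` element of [generatePatient()].
#' @param params a [phantomParams()] list.
#' @param patientId identifier for the record.
#' @return one-row data.frame (`patient_id`, `time_months`, `event`).
#' @export
assignSurvival <- function(geometry, params, patientId = "patient") {
  dnorm_ <- if (is.finite(geometry$dminMm))
    geometry$dminMm / params$distScale else params$distFree
  h <- params$h0 * exp(params$betaN * geometry$k + params$betaD * dnorm_ +
                         params$betaV * geometry$volRatio)
  t_true <- rexp(1, rate = h)
  if (t_true > params$maxFollowup) {
    time <- params$maxFollowup; event <- 0L
  } else if (runif(1) < params$censorRate) {
    time <- runif(1, 0, t_true); event <- 0L
  } else {
    time <- t_true; event <- 1L
  }
  data.frame(patient_id = patientId, time_months = time, event = event)
}

#' Generate a phantom cohort
#'
#' Seeds the RNG from `params$seed`, generates `nPatients` patients with
#' survival records, and optionally persists them as NRRD volumes/masks plus
#' a records and manifest table in `dir`.
#'
#' @param params a [phantomParams()] list.
#' @param dir optional output directory; `NULL` keeps the cohort in memory.
#' @param encoding NRRD payload encoding when writing ("raw" or "ascii").
#' @return list with `patients` (list of volume/mask/geometry), `records`
#'   (data.frame) and `manifest` (data.frame).
#' @export
generateCohort <- function(params, dir = NULL, encoding = "raw") {
  set.seed(as.integer(params$seed))
  patients <- vector("list", params$nPatients)
  records <- vector("list", params$nPatients)
  manifest <- vector("list", params$nPatients)
  for (i in seq_len(params$nPatients)) {
    pid <- sprintf("P%04d", i)
    p <- generatePatient(params)
    p$volume@patientId <- pid
    rec <- assignSurvival(p$geometry, params, pid)
    patients[[i]] <- p
    records[[i]] <- rec
    manifest[[i]] <- data.frame(patient_id = pid, k = p$geometry$k,
                                dmin_mm = ifelse(is.finite(p$geometry$dminMm),
                                                 p$geometry$dminMm, NA_real_),
                                vol_ratio = p$geometry$volRatio,
                                time_months = rec$time_months,
                                event = rec$event)
  }
  records <- do.call(rbind, records)
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(params$nPatients)) {
      pid <- manifest$patient_id[i]
      writePatient(patients[[i]]$volume, patients[[i]]$mask,
                   file.path(dir, paste0(pid, "_volume.nrrd")),
                   file.path(dir, paste0(pid, "_mask.nrrd")),
                   encoding = encoding)
    }
    write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(patients = patients, records = records, manifest = manifest)
}
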