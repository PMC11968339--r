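small_params <- function(nPatients = 4L, ...) {
  phantomParams(nPatients = nPatients, shape = c(12L, 64L, 64L),
                softRadius = 24, tumorRadius = c(4, 7), lymphDist = c(6, 22),
                lymphSliceOffset = 3L, ...)
}

test_that("phantom patients are valid, seeded, and carry geometry", {
  p <- small_params(seed = 5)
  set.seed(p$seed)
  pt <- generatePatient(p)
  expect_s4_class(pt$volume, "CTVolume")
  expect_s4_class(pt$mask, "ROIMask")
  expect_true(all(unique(as.vector(maskLabels(pt$mask))) %in% 0:2))
  expect_gt(sum(maskLabels(pt$mask) == 1L), 0)
  expect_true(pt$geometry$k >= 0)
  # fixed seed -> bit-identical rerun
  set.seed(p$seed)
  pt2 <- generatePatient(p)
  expect_identical(voxels(pt$volume), voxels(pt2$volume))
  expect_identical(maskLabels(pt$mask), maskLabels(pt2$mask))
  # lambda = 0 -> tumor only
  p0 <- small_params(lymphLambda = 0, seed = 6)
  set.seed(p0$seed)
  expect_true(all(maskLabels(generatePatient(p0)$mask) %in% 0:1))
})

test_that("every phantom passes IO validation and yields all three planes", {
  p <- small_params(seed = 11)
  co <- generateCohort(p)
  for (pt in co$patients) {
    fv <- tempfile(fileext = ".nrrd"); fm <- tempfile(fileext = ".nrrd")
    writePatient(pt$volume, pt$mask, fv, fm, encoding = "raw")
    back <- readPatient(fv, fm)     # validates shapes and labels
    expect_identical(maskLabels(back$mask), maskLabels(pt$mask))
    for (v in c("PJ", "TM", "ZC"))
      expect_s4_class(buildPlane(pt$volume, pt$mask, v), "PlaneImage")
    file.remove(fv, fm)
  }
})

test_that("cohort generation is reproducible and writes readable output", {
  p <- small_params(seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  co1 <- generateCohort(p, dir = d1, encoding = "ascii")
  co2 <- generateCohort(p, dir = d2, encoding = "ascii")
  expect_identical(co1$records, co2$records)
  expect_identical(co1$manifest, co2$manifest)
  expect_true(file.exists(file.path(d1, "records.csv")))
  f1 <- file.path(d1, paste0(co1$manifest$patient_id[1], "_volume.nrrd"))
  m1 <- file.path(d1, paste0(co1$manifest$patient_id[1], "_mask.nrrd"))
  back <- readPatient(f1, m1)
  expect_equal(voxels(back$volume), voxels(co1$patients[[1]]$volume),
               tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("node counts follow the capped Poisson and survival the hazard", {
  # moment check on k (fast: geometry only needs small volumes)
  p <- small_params(nPatients = 150L, lymphLambda = 2, seed = 31)
  co <- generateCohort(p)
  kbar <- mean(co$manifest$k)
  lam_capped <- sum(dpois(0:50, 2) * pmin(0:50, 5))
  expect_lt(abs(kbar - lam_capped), 3 * sqrt(2 / 150) + 0.25)
  # censoring rate 0 and infinite follow-up -> all deaths
  p0 <- small_params(censorRate = 0, maxFollowup = Inf, seed = 32)
  co0 <- generateCohort(p0)
  expect_true(all(co0$records$event == 1L))
})

test_that("spatial hazard coupling orders survival as documented", {
  # beta all zero: survival exchangeable across geometries
  set.seed(41)
  pz <- phantomParams(betaN = 0, betaD = 0, betaV = 0, censorRate = 0,
                      maxFollowup = Inf)
  g_near <- list(k = 3, dminMm = 10, volRatio = 0.6)
  g_far <- list(k = 0, dminMm = Inf, volRatio = 0)
  t_near <- replicate(300, assignSurvival(g_near, pz)$time_months)
  t_far <- replicate(300, assignSurvival(g_far, pz)$time_months)
  expect_gt(wilcox.test(t_near, t_far)$p.value, 0.01)
  # strong coupling: near/large-node geometry dies sooner (Monte Carlo)
  set.seed(42)
  ps <- phantomParams(censorRate = 0, maxFollowup = Inf)
  t_near2 <- replicate(300, assignSurvival(g_near, ps)$time_months)
  t_far2 <- replicate(300, assignSurvival(g_far, ps)$time_months)
  expect_lt(median(t_near2), median(t_far2))
  expect_lt(wilcox.test(t_near2, t_far2, alternative = "less")$p.value, 1e-6)
  # closest-node tertile dies sooner than the farthest tertile
  set.seed(43)
  dgrid <- runif(450, 8, 60)
  times <- vapply(dgrid, function(d)
    assignSurvival(list(k = 2, dminMm = d, volRatio = 0.3), ps)$time_months,
    numeric(1))
  ter <- cut(dgrid, quantile(dgrid, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  med <- tapply(times, ter, median)
  expect_lt(med[[1]], med[[3]])
  # death prevalence is tunable through the baseline hazard
  set.seed(44)
  deaths_at <- function(h0) {
    # moderate coupling so the hazard is not saturated by the volume term
    p <- small_params(nPatients = 60L, h0 = h0, betaN = 0.2, betaD = -1,
                      betaV = 1, seed = 45)
    mean(generateCohort(p)$records$event)
  }
  expect_lt(deaths_at(0.002), deaths_at(0.08))
})

test_that("a node at zero displacement is fully occluded in the projection", {
  dims <- c(10L, 48L, 48L)
  # lymph blob centred exactly under the tumor footprint on another slice
  blob <- blob_cuboid(8, 22:26, 22:26)
  pt <- tiny_patient(dims = dims, tumor_slices = 3:5, tumor_center = c(24, 24),
                     tumor_radius = 6, lymph_blobs = list(blob))
  gr <- sortGroups(groupComponents(pt$mask))
  pj <- buildPjPlane(pt$volume, pt$mask, gr, resample = FALSE)
  expect_false(any(provenance(pj) >= 2L))
})
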