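make_grouped <- function(...) {
  pt <- tiny_patient(...)
  groups <- sortGroups(groupComponents(pt$mask))
  c(pt, list(groups = groups))
}

test_that("datum plane is the slice with the largest tumor ROI", {
  lab <- array(0L, c(4L, 10L, 10L))
  lab[cbind(2, rep(1:7, 2), rep(1:2, each = 7))] <- 1L  # 14 px
  lab[cbind(3, rep(1:6, 5), rep(1:5, each = 6))] <- 1L  # 30 px
  lab[cbind(4, rep(1:2, 11), rep(1:11 %% 10 + 1, each = 2))] <- 1L
  m <- ROIMask(lab)
  expect_equal(selectDatumPlane(m), 3L)
  # oracle: exhaustive argmax
  expect_equal(selectDatumPlane(m), which.max(apply(lab == 1L, 1, sum)))
  expect_error(selectDatumPlane(ROIMask(array(0L, c(2L, 4L, 4L)))), "no tumor")
})

test_that("PJ conserves disjoint ROI areas and provenance coordinates", {
  blob <- blob_cuboid(5, 26:29, 26:29)  # disjoint from the central tumor
  pt <- make_grouped(lymph_blobs = list(blob))
  pj <- buildPjPlane(pt$volume, pt$mask, pt$groups, resample = FALSE)
  prov <- provenance(pj)
  s0 <- selectDatumPlane(pt$mask)
  tumor_area <- sum(maskLabels(pt$mask)[s0, , ] == 1L)
  expect_identical(sum(prov == 1L), tumor_area)
  expect_identical(sum(prov > 0L), tumor_area + nrow(blob))
  # every lymph pixel sits at its original (row, col)
  lpix <- which(prov >= 2L, arr.ind = TRUE)
  expect_setequal(paste(lpix[, 1], lpix[, 2]), paste(blob[, 2], blob[, 3]))
  # and carries the source-slice intensity (normalized)
  expect_true(all(abs(planePixels(pj)[lpix] - (40 + 50) / 350) < 1e-9))
})

test_that("full occlusion reduces PJ to the tumor-only plane", {
  # lymph node exactly under the tumor footprint in (row, col)
  blob <- blob_cuboid(5, 14:18, 14:18)
  blob <- blob[(blob[, 2] - 16)^2 + (blob[, 3] - 16)^2 <= 25, , drop = FALSE]
  pt <- make_grouped(lymph_blobs = list(blob))
  pj <- buildPjPlane(pt$volume, pt$mask, pt$groups, resample = FALSE)
  tm <- buildTmPlane(pt$volume, pt$mask, resample = FALSE)
  expect_identical(provenance(pj), provenance(tm))
  expect_equal(planePixels(pj), planePixels(tm))
})

test_that("sequential stamping matches a pixelwise oracle under overlap", {
  b1 <- blob_cuboid(5, 24:29, 24:29)   # 36 vox, wins the contested pixels
  b2 <- blob_cuboid(7, 27:30, 27:30)   # 16 vox, 3D-disjoint, occluded in-plane
  pt <- make_grouped(dims = c(8L, 32L, 32L), lymph_blobs = list(b1, b2))
  expect_length(pt$groups, 2L)
  pj <- buildPjPlane(pt$volume, pt$mask, pt$groups, resample = FALSE)
  prov <- provenance(pj)
  # oracle: stamp by hand in sorted order on a blank sheet
  dims <- dim(maskLabels(pt$mask))[2:3]
  want <- matrix(0L, dims[1], dims[2])
  s0 <- selectDatumPlane(pt$mask)
  want[maskLabels(pt$mask)[s0, , ] == 1L] <- 1L
  for (g in pt$groups) {
    px <- maxRoiPixels(g)
    for (i in seq_len(nrow(px)))
      if (want[px[i, 1], px[i, 2]] == 0L)
        want[px[i, 1], px[i, 2]] <- as.integer(groupId(g))
  }
  expect_identical(prov, want)
  # monotone occlusion: the smaller group never overwrote the larger
  expect_identical(sum(prov == 2L), nrow(b1))
  expect_lt(sum(prov == 3L), nrow(b2))
})

test_that("TM planes never contain lymph provenance and PJ covers TM", {
  pt <- make_grouped(lymph_blobs = list(blob_cuboid(3, 25:27, 4:6)))
  tm <- buildTmPlane(pt$volume, pt$mask)
  pj <- buildPjPlane(pt$volume, pt$mask, pt$groups)
  expect_true(all(provenance(tm) %in% c(0L, 1L)))
  expect_identical(dim(planePixels(tm)), c(224L, 224L))
  # TM support is a subset of PJ support (same resampling grid)
  expect_true(all(provenance(pj)[provenance(tm) > 0L] > 0L))
  # node-free patient: PJ equals TM
  nf <- make_grouped()
  pj0 <- buildPjPlane(nf$volume, nf$mask, nf$groups)
  tm0 <- buildTmPlane(nf$volume, nf$mask)
  expect_equal(planePixels(pj0), planePixels(tm0))
  expect_identical(provenance(pj0), provenance(tm0))
})

test_that("ZC tiles are uniform, ordered row-major, and capacity-limited", {
  b1 <- blob_cuboid(5, 2:11, 2:11)     # large node
  b2 <- blob_cuboid(6, 28:29, 28:29)   # small node
  pt <- make_grouped(lymph_blobs = list(b1, b2))
  zc <- buildZcPlane(pt$volume, pt$mask, pt$groups, tileSide = 56L)
  prov <- provenance(zc)
  # tumor tile top-left, then groups in sorted order; uniform 56x56 cells
  expect_true(all(prov[1:56, 1:56] %in% c(0L, 1L)))
  expect_true(any(prov[1:56, 1:56] == 1L))
  expect_true(any(prov[1:56, 57:112] == 2L))
  expect_true(any(prov[1:56, 113:168] == 3L))
  # both node tiles fill a comparable share of their cell despite the
  # 25x true size difference (uniform scale)
  f2 <- mean(prov[1:56, 57:112] == 2L)
  f3 <- mean(prov[1:56, 113:168] == 3L)
  expect_lt(abs(f2 - f3), 0.25)
  # node-free patient: only the tumor tile
  nf <- make_grouped()
  zc0 <- buildZcPlane(nf$volume, nf$mask, nf$groups)
  expect_setequal(unique(as.vector(provenance(zc0))), c(0L, 1L))
})

test_that("ZC is invariant to rigid node translation; PJ is not", {
  dims <- c(8L, 48L, 48L)
  mk <- function(shift) {
    blob <- blob_cuboid(6, (10:14) + shift, (30:34) + shift)
    tiny_patient(dims = dims, tumor_slices = 3:5, tumor_center = c(24, 24),
                 lymph_blobs = list(blob))
  }
  a <- mk(0L); b <- mk(6L)
  ga <- sortGroups(groupComponents(a$mask))
  gb <- sortGroups(groupComponents(b$mask))
  zca <- buildZcPlane(a$volume, a$mask, ga)
  zcb <- buildZcPlane(b$volume, b$mask, gb)
  expect_identical(planePixels(zca), planePixels(zcb))
  expect_identical(provenance(zca), provenance(zcb))
  pja <- buildPjPlane(a$volume, a$mask, ga, resample = FALSE)
  pjb <- buildPjPlane(b$volume, b$mask, gb, resample = FALSE)
  expect_false(identical(provenance(pja), provenance(pjb)))
})

test_that("plane invariants hold on random phantoms", {
  set.seed(5)
  p <- phantomParams(nPatients = 6L, shape = c(12L, 64L, 64L), seed = 77)
  co <- generateCohort(p)
  for (pt in co$patients) {
    msk <- huWindow(pt$volume, pt$mask)
    groups <- sortGroups(groupComponents(msk))
    pj <- buildPjPlane(pt$volume, msk, groups, resample = FALSE)
    s0 <- selectDatumPlane(msk)
    expect_identical(sum(provenance(pj) == 1L),
                     sum(maskLabels(msk)[s0, , ] == 1L))
    # each lymph-provenance pixel matches its source voxel's (row, col)
    for (g in groups) {
      got <- which(provenance(pj) == groupId(g), arr.ind = TRUE)
      src <- maxRoiPixels(g)
      expect_true(all(paste(got[, 1], got[, 2]) %in% paste(src[, 1], src[, 2])))
    }
    # resampled planes are valid PlaneImages by construction (validity ran)
    expect_s4_class(buildPlane(pt$volume, pt$mask, "PJ"), "PlaneImage")
  }
})
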