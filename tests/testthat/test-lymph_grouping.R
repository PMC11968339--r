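test_that("component grouping matches hand-enumerated adjacency cases", {
  dims <- c(3L, 10L, 10L)
  lab <- array(0L, dims)
  lab[1, 6, 6] <- 2L
  lab[2, 7, 7] <- 2L   # diagonal in all three axes from the first voxel
  g26 <- groupComponents(ROIMask(lab), 26L)
  g6 <- groupComponents(ROIMask(lab), 6L)
  expect_length(g26, 1L)
  expect_length(g6, 2L)
  expect_equal(voxelCount(g26[[1]]), 2)

  # no lymph voxels -> empty list; single voxel -> singleton group
  expect_identical(groupComponents(ROIMask(array(0L, dims))), list())
  solo <- array(0L, dims); solo[2, 3, 3] <- 2L
  gs <- groupComponents(ROIMask(solo))
  expect_length(gs, 1L)
  expect_equal(voxelCount(gs[[1]]), 1)
  expect_equal(nrow(maxRoiPixels(gs[[1]])), 1L)
})

test_that("grouping equals brute-force union-find on random masks", {
  for (seed in 1:6) {
    for (conn in c(6L, 26L)) {
      lab <- random_lymph_mask(c(6L, 12L, 12L), density = 0.08, seed = seed * 10 + conn)
      got <- groupComponents(ROIMask(lab), conn)
      want <- oracle_components(array(as.integer(lab == 2L), dim(lab)), conn)
      expect_identical(partition_key(lapply(got, function(g) unname(g@voxels))),
                       partition_key(lapply(want, unname)),
                       info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("partition property: disjoint groups cover exactly the lymph set", {
  lab <- random_lymph_mask(c(8L, 16L, 16L), density = 0.1, seed = 99)
  groups <- groupComponents(ROIMask(lab), 26L)
  all_vox <- do.call(rbind, lapply(groups, function(g) g@voxels))
  expect_identical(nrow(all_vox), sum(lab == 2L))          # coverage
  expect_identical(anyDuplicated(as.data.frame(all_vox)), 0L)  # disjoint
})

test_that("sorting is by descending size with deterministic tie-break", {
  mk <- function(id, n, seed_vox) {
    vox <- cbind(seed_vox[1], seed_vox[2], seed_vox[3] + 0:(n - 1))
    new("LymphGroup", groupId = id, voxels = vox, maxSlice = seed_vox[1],
        maxRoiPixels = vox[, 2:3, drop = FALSE])
  }
  gs <- list(mk(2, 3, c(1, 1, 1)), mk(3, 10, c(2, 1, 1)), mk(4, 7, c(1, 5, 1)))
  srt <- sortGroups(gs)
  expect_equal(vapply(srt, voxelCount, numeric(1)), c(10, 7, 3))
  expect_equal(vapply(srt, groupId, numeric(1)), c(2, 3, 4))
  # ties: ordered by lexicographic seed voxel
  t1 <- mk(2, 4, c(2, 3, 3)); t2 <- mk(3, 4, c(1, 9, 9))
  srt2 <- sortGroups(list(t1, t2))
  expect_equal(srt2[[1]]@voxels[1, 1], 1)  # smaller slice seed first
  # random sizes match an order() oracle
  set.seed(7)
  sizes <- sample(1:30, 20, replace = TRUE)
  gs3 <- lapply(seq_along(sizes), function(i) mk(i + 1, sizes[i], c(i, 1, 1)))
  srt3 <- sortGroups(gs3)
  expect_equal(vapply(srt3, voxelCount, numeric(1)),
               sizes[order(-sizes, seq_along(sizes))])
})

test_that("relabelling exhausts the generic lymph label and is a fixpoint", {
  lab <- array(0L, c(4L, 12L, 12L))
  lab[1, 2, 2] <- 1L                       # tumor stays 1
  lab[cbind(1, 4:6, 4)] <- 2L
  lab[cbind(3, 9:10, 9)] <- 2L
  mask <- ROIMask(lab)
  groups <- sortGroups(groupComponents(mask))
  rl <- relabelGroups(mask, groups)
  lv <- maskLabels(rl)
  expect_setequal(unique(as.vector(lv[lv > 0L])), c(1L, 2L, 3L))
  expect_identical(sum(lv >= 2L), sum(lab == 2L))
  # regrouping the relabelled mask reproduces the identical partition
  re <- groupComponents(rl)
  expect_identical(partition_key(lapply(re, function(g) unname(g@voxels))),
                   partition_key(lapply(groups, function(g) unname(g@voxels))))
})

test_that("max-ROI extraction picks the largest slice, ties to the smallest", {
  lab <- array(0L, c(8L, 12L, 12L))
  lab[cbind(4, rep(1:3, 4), rep(1:4, each = 3))] <- 2L   # 12 px on slice 4
  lab[cbind(5, rep(1:4, 5), rep(1:5, each = 4))] <- 2L   # 20 px on slice 5
  lab[cbind(6, rep(1:3, 3), rep(1:3, each = 3))] <- 2L   # 9 px on slice 6
  g <- groupComponents(ROIMask(lab))[[1]]
  mr <- extractMaxRoi(g)
  expect_equal(mr$maxSlice, 5)
  expect_equal(nrow(mr$maxRoiPixels), 20L)
  # oracle: exhaustive per-slice count
  per_slice <- table(g@voxels[, 1])
  expect_equal(unname(per_slice[as.character(mr$maxSlice)]),
               max(per_slice), ignore_attr = TRUE)
  # tie case
  lab2 <- array(0L, c(4L, 6L, 6L))
  lab2[cbind(2, 1:2, 1)] <- 2L
  lab2[cbind(3, 1:2, 1)] <- 2L
  g2 <- groupComponents(ROIMask(lab2))[[1]]
  expect_equal(maxSlice(g2), 2)
})

test_that("partition is invariant to traversal order (mask permutation probe)", {
  # flipping the volume along rows relabels seeds in a different order but
  # must produce the same partition up to the coordinate flip
  lab <- random_lymph_mask(c(5L, 14L, 14L), density = 0.09, seed = 123)
  fl <- lab[, rev(seq_len(dim(lab)[2])), , drop = FALSE]
  g1 <- groupComponents(ROIMask(lab), 26L)
  g2 <- groupComponents(ROIMask(fl), 26L)
  unflip <- lapply(g2, function(g) {
    v <- g@voxels
    v[, 2] <- dim(lab)[2] + 1L - v[, 2]
    v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  })
  expect_identical(partition_key(lapply(g1, function(g) unname(g@voxels))),
                   partition_key(lapply(unflip, unname)))
})
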