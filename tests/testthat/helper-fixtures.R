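# Shared fixtures: tiny hand-built volumes/masks and brute-force oracles.

# a small co-registered volume/mask pair with one tumor and optional lymph
# blobs given as a list of (slice, row, col) matrices
tiny_patient <- function(dims = c(6L, 32L, 32L), tumor_slices = 2:4,
                         tumor_center = c(16, 16), tumor_radius = 5,
                         lymph_blobs = list(), hu_tumor = 60, hu_lymph = 40,
                         hu_bg = -700) {
  vox <- array(hu_bg, dims)
  lab <- array(0L, dims)
  d2 <- outer((seq_len(dims[2]) - tumor_center[1])^2,
              (seq_len(dims[3]) - tumor_center[2])^2, "+")
  for (s in tumor_slices) {
    sel <- d2 <= tumor_radius^2
    lab[s, , ][sel] <- 1L
    vox[s, , ][sel] <- hu_tumor
  }
  for (blob in lymph_blobs) {
    for (i in seq_len(nrow(blob))) {
      lab[blob[i, 1], blob[i, 2], blob[i, 3]] <- 2L
      vox[blob[i, 1], blob[i, 2], blob[i, 3]] <- hu_lymph
    }
  }
  list(volume = CTVolume(vox), mask = ROIMask(lab))
}

# a square lymph blob (all voxels of a cuboid), rows are (slice,row,col)
blob_cuboid <- function(slices, rows, cols) {
  as.matrix(expand.grid(slice = slices, row = rows, col = cols))
}

# brute-force 2D median filter with reflected edges
oracle_median2d <- function(x, k) {
  r <- (k - 1) / 2
  H <- nrow(x); W <- ncol(x)
  refl <- function(i, n) {
    while (any(bad <- i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  out <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    nb <- x[refl(i + (-r:r), H), refl(j + (-r:r), W)]
    out[i, j] <- median(nb)
  }
  out
}

# brute-force union-find over all voxel pairs for 3D connected components
oracle_components <- function(lymph, connectivity) {
  idx <- which(lymph == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  adjacent <- function(a, b) {
    d <- abs(a - b)
    if (any(d > 1)) return(FALSE)
    nz <- sum(d)
    switch(as.character(connectivity),
           "6" = nz == 1, "18" = nz >= 1 && nz <= 2, "26" = nz >= 1)
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (adjacent(idx[a, ], idx[b, ])) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(members) {
    vox <- idx[members, , drop = FALSE]
    vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
  })
}

# canonical string for a partition (order-independent comparison)
partition_key <- function(voxel_sets) {
  keys <- vapply(voxel_sets, function(v)
    paste(apply(v, 1, paste, collapse = ","), collapse = ";"), character(1))
  paste(sort(keys), collapse = "|")
}

# random pre-grouping mask: sprinkle lymph voxels at given density
random_lymph_mask <- function(dims, density, seed) {
  set.seed(seed)
  lab <- array(0L, dims)
  lab[runif(prod(dims)) < density] <- 2L
  lab
}

# bright/dark disk planes: a linearly separable toy task
disk_plane <- function(bright, side = 224L) {
  pix <- matrix(0, side, side)
  prov <- matrix(0L, side, side)
  r <- runif(1, 30, 60)
  cy <- runif(1, side * 0.35, side * 0.65)
  cx <- runif(1, side * 0.35, side * 0.65)
  d2 <- outer((seq_len(side) - cy)^2, (seq_len(side) - cx)^2, "+")
  sel <- d2 <= r^2
  prov[sel] <- 1L
  pix[sel] <- pmin(pmax(rnorm(sum(sel), if (bright) 0.75 else 0.3, 0.05), 0), 1)
  PlaneImage(pix, prov, "TM")
}
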