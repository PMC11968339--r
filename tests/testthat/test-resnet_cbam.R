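# naive single-sample CBAM oracles, written independently of the layer code
oracle_channel_attention <- function(x, par) {
  C <- dim(x)[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(x[, , c])
    mx[c] <- max(x[, , c])
  }
  mlp <- function(v) {
    h <- as.vector(par$W1 %*% v + par$b1)
    h[h < 0] <- 0
    as.vector(par$W2 %*% h + par$b2)
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

oracle_spatial_attention <- function(x, par) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(par$Wsp)[1]; r <- (k - 1) / 2
  mn <- apply(x, c(1, 2), mean)
  mx <- apply(x, c(1, 2), max)
  two <- array(c(mn, mx), c(H, W, 2))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- par$bsp
    for (di in -r:r) for (dj in -r:r) for (ch in 1:2) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + two[ii, jj, ch] * par$Wsp[di + r + 1, dj + r + 1, ch, 1]
    }
    out[i, j] <- 1 / (1 + exp(-acc))
  }
  out
}

test_that("channel and spatial attention match naive-loop oracles", {
  set.seed(61)
  for (i in 1:4) {
    x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    par <- cbamParams(8, reductionRatio = 2, spatialKernel = 3)
    expect_equal(channelAttention(x, par), oracle_channel_attention(x, par),
                 tolerance = 1e-10)
    expect_equal(spatialAttention(x, par), oracle_spatial_attention(x, par),
                 tolerance = 1e-10)
    cw <- channelAttention(x, par)
    expect_true(all(cw > 0 & cw < 1))
  }
})

test_that("attention identities: constant inputs, zero parameters", {
  set.seed(62)
  par0 <- cbamParams(4, init = "zero")
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  expect_equal(unname(channelAttention(x, par0)), rep(0.5, 4))
  expect_equal(spatialAttention(x, par0), matrix(0.5, 5, 5))
  # constant per channel: avgpool == maxpool, so w = sigmoid(2 MLP(pooled))
  parr <- cbamParams(4, reductionRatio = 2)
  xc <- array(rep(1:4, each = 25), c(5, 5, 4))
  mlp <- function(v) as.vector(parr$W2 %*% pmax(parr$W1 %*% v + parr$b1, 0) + parr$b2)
  expect_equal(unname(channelAttention(xc, parr)),
               1 / (1 + exp(-2 * mlp(1:4))), tolerance = 1e-10)
  # constant everywhere: spatial map constant
  xk <- array(2.5, c(6, 6, 3))
  park <- cbamParams(3, spatialKernel = 3)
  sm <- spatialAttention(xk, park)
  expect_lt(diff(range(sm[2:5, 2:5])), 1e-12)  # interior (away from padding)
})

test_that("cbamRefine applies the two broadcasts and preserves shape", {
  set.seed(63)
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  par <- cbamParams(6, reductionRatio = 2, spatialKernel = 3)
  got <- cbamRefine(x, par)
  expect_identical(dim(got), dim(x))
  # elementwise oracle
  cw <- oracle_channel_attention(x, par)
  x1 <- x
  for (c in 1:6) x1[, , c] <- x[, , c] * cw[c]
  sm <- oracle_spatial_attention(x1, par)
  want <- x1
  for (c in 1:6) want[, , c] <- x1[, , c] * sm
  expect_equal(got, want, tolerance = 1e-10)
  # limit cases via the oracle identity: zero params -> uniform 0.25 scaling
  par0 <- cbamParams(6, init = "zero")
  expect_equal(cbamRefine(x, par0), x * 0.25, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences through a CBAM block", {
  set.seed(64)
  ns <- asNamespace("LymphPlane")
  blk <- ns$nnBottleneck(3L, 2L, 8L, stride = 2L, reductionRatio = 2,
                         spatialKernel = 3)
  blk$bn3$par$gamma <- rnorm(8)   # avoid the zero-init degenerate point
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  y <- blk$forward(x, TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  f <- function() sum(blk$forward(x, TRUE) * dy)
  invisible(blk$forward(x, TRUE))
  dx <- blk$backward(dy)
  eps <- 1e-5
  idx <- sample(length(x), 6)
  num <- vapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (sum(blk$forward(xp, TRUE) * dy) - sum(blk$forward(xm, TRUE) * dy)) / (2 * eps)
  }, numeric(1))
  expect_equal(dx[idx], num, tolerance = 1e-5)
  for (probe in list(c("cbam", "W1"), c("cbam", "Wsp"), c("conv2", "W"),
                     c("bn1", "gamma"))) {
    layer <- blk[[probe[1]]]; nm <- probe[2]
    invisible(blk$forward(x, TRUE)); invisible(blk$backward(dy))
    g <- layer$grad[[nm]]
    pick <- sample(length(layer$par[[nm]]), min(3, length(layer$par[[nm]])))
    nv <- vapply(pick, function(i) {
      old <- layer$par[[nm]]
      layer$par[[nm]][i] <- old[i] + eps; fp <- f()
      layer$par[[nm]][i] <- old[i] - eps; fm <- f()
      layer$par[[nm]] <- old
      (fp - fm) / (2 * eps)
    }, numeric(1))
    expect_equal(g[pick], nv, tolerance = 1e-5,
                 info = paste(probe, collapse = "$"))
  }
})

test_that("forward pass yields normalized, reproducible probabilities", {
  m1 <- resnetCbam("reduced", inputSide = 64L, seed = 7)
  m2 <- resnetCbam("reduced", inputSide = 64L, seed = 7)
  set.seed(70)
  plane <- matrix(runif(64 * 64), 64, 64)
  p1 <- predictProb(m1, list(plane, plane))
  p2 <- predictProb(m2, list(plane))
  expect_equal(rowSums(p1), c(1, 1), tolerance = 1e-6)
  expect_identical(p1[1, ], p1[2, ])       # identical inputs, identical outputs
  expect_equal(p1[1, ], p2[1, ], tolerance = 1e-12)  # seeded rebuild agrees
  expect_error(m1$forward(array(0, c(32, 32, 1, 1))), "input must be")
})

test_that("the full 50-layer variant runs and normalizes", {
  mf <- resnetCbam("full", seed = 3)
  set.seed(71)
  p <- predictProb(mf, list(matrix(runif(224 * 224), 224, 224)))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
})

test_that("training: epoch-0 no-op, seeded determinism, learnable toy task", {
  set.seed(72)
  planes <- lapply(rep(c(TRUE, FALSE), each = 12), disk_plane, side = 64L)
  labels <- rep(c(1L, 0L), each = 12)
  m <- resnetCbam("reduced", inputSide = 64L, seed = 8)
  out0 <- trainModel(m, planes, labels, trainConfig(epochs = 0))
  expect_identical(nrow(out0$history), 0L)
  cfg <- trainConfig(lr = 1e-3, epochs = 3, seed = 5)
  f1 <- trainModel(resnetCbam("reduced", inputSide = 64L, seed = 8),
                   planes, labels, cfg)
  f2 <- trainModel(resnetCbam("reduced", inputSide = 64L, seed = 8),
                   planes, labels, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 3L)
  # bright-vs-dark disks are separable: loss drops and accuracy rises
  f3 <- trainModel(resnetCbam("reduced", inputSide = 64L, seed = 9),
                   planes, labels,
                   trainConfig(lr = 2e-3, epochs = 6, seed = 5))
  expect_lt(tail(f3$history$loss, 1), f3$history$loss[1])
  expect_gt(tail(f3$history$train_acc, 1), 0.9)
})
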