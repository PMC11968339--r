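# The residual attention classifier: a bottleneck ResNet (stage layout
# 3-4-6-3 for the full 50-layer network, 1-1-1-1 at base width 16 for the
# reduced desk-scale variant) with a Convolutional Block Attention Module
# (CBAM) inside every residual block, applied to the block output before the
# skip addition. Channel attention: sigmoid(MLP(avgpool) + MLP(maxpool)) with
# a shared two-layer MLP (hidden C / reduction_ratio, ReLU). Spatial
# attention: channel-wise mean and max stacked into a 2-channel map,
# convolved (odd kernel, same padding) to one channel, sigmoid.

#' Create CBAM parameters
#'
#' @param C number of channels of the feature map the module attends to.
#' @param reductionRatio channel-MLP bottleneck ratio (hidden size
#'   `max(1, C / reductionRatio)`).
#' @param spatialKernel odd side of the spatial-attention convolution.
#' @param init "random" (He-normal weights, zero biases) or "zero" (all
#'   parameters zero, so every attention weight is sigmoid(0) = 0.5).
#' @return list with `W1`, `b1`, `W2`, `b2` (shared channel MLP) and
#'   `Wsp`, `bsp` (spatial convolution).
#' @export
cbamParams <- function(C, reductionRatio = 16, spatialKernel = 7,
                       init = c("random", "zero")) {
  init <- match.arg(init)
  if (spatialKernel %% 2 == 0) stop("spatialKernel must be odd")
  Cr <- max(1L, as.integer(C %/% reductionRatio))
  k <- as.integer(spatialKernel)
  if (init == "zero") {
    list(W1 = matrix(0, Cr, C), b1 = numeric(Cr),
         W2 = matrix(0, C, Cr), b2 = numeric(C),
         Wsp = array(0, c(k, k, 2, 1)), bsp = 0)
  } else {
    list(W1 = matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C), b1 = numeric(Cr),
         W2 = matrix(rnorm(C * Cr, sd = sqrt(2 / Cr)), C, Cr), b2 = numeric(C),
         Wsp = .he_init(c(k, k, 2, 1), k * k * 2), bsp = 0)
  }
}

.as_hwcn <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Channel attention weights
#'
#' Global average pooling and global max pooling over the spatial extent feed
#' a shared two-layer MLP; the two outputs are summed and passed through a
#' sigmoid, giving one weight in (0, 1) per channel.
#'
#' @param x feature map array (H, W, C) or (H, W, C, N).
#' @param params a [cbamParams()] list.
#' @return numeric vector of length C (or C x N matrix for batched input).
#' @export
channelAttention <- function(x, params) {
  x <- .as_hwcn(x)
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, HW, C * N)
  avg <- matrix(colMeans(xm), C, N)
  mx <- matrix(apply(xm, 2, max), C, N)
  mlp <- function(v) params$W2 %*% pmax(params$W1 %*% v + params$b1, 0) + params$b2
  w <- .sigmoid(mlp(avg) + mlp(mx))
  if (N == 1L) as.vector(w) else w
}

#' Spatial attention map
#'
#' Channel-wise mean and max at every position are stacked into a two-channel
#' map, convolved with an odd-sized kernel under same padding, and squashed
#' by a sigmoid into an (0, 1) map over positions.
#'
#' @inheritParams channelAttention
#' @return H x W matrix (or H x W x N array for batched input).
#' @export
spatialAttention <- function(x, params) {
  x <- .as_hwcn(x)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  sp <- array(0, c(H, W, 2, N))
  for (n in seq_len(N)) {
    M <- matrix(x[, , , n], HW, C)
    mn <- rowMeans(M)
    mx <- M[, 1]
    if (C > 1) for (c2 in 2:C) mx <- pmax(mx, M[, c2])
    sp[, , 1, n] <- mn
    sp[, , 2, n] <- mx
  }
  k <- dim(params$Wsp)[1]
  t4 <- cpp_conv2d_fwd(sp, params$Wsp, params$bsp, 1L, (k - 1L) %/% 2L)
  out <- .sigmoid(array(t4, c(H, W, N)))
  if (N == 1L) matrix(out, H, W) else out
}

#' Sequential CBAM refinement
#'
#' Multiplies the feature map by its channel weights (broadcast over
#' positions) and then by its spatial map (broadcast over channels). Shape is
#' preserved; with all weights forced to one this is the identity.
#'
#' @inheritParams channelAttention
#' @return array of the same shape as `x`.
#' @export
cbamRefine <- function(x, params) {
  din <- dim(x)
  x <- .as_hwcn(x)
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  cw <- matrix(channelAttention(x, params), C, N)
  xm <- matrix(x, HW, C * N) * rep(as.vector(cw), each = HW)
  x1 <- array(xm, d)
  sm <- array(spatialAttention(x1, params), c(d[1], d[2], N))
  ym <- matrix(x1, HW, C * N) *
    matrix(sm, HW, N)[, rep(seq_len(N), each = C), drop = FALSE]
  array(ym, din)
}

# ---- CBAM as a trainable layer (with full gradients through both paths) ----

nnCBAM <- function(C, reductionRatio = 16, spatialKernel = 7) {
  e <- new.env(parent = emptyenv())
  e$type <- "cbam"
  e$par <- cbamParams(C, reductionRatio, spatialKernel, init = "random")
  e$grad <- list()
  k <- dim(e$par$Wsp)[1]
  pad <- (k - 1L) %/% 2L
  e$forward <- function(x, train = TRUE) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]; HW <- H * W
    ph <- cpp_pool_hw(x)
    avg <- ph$avg
    mx <- ph$max
    ha <- pmax(e$par$W1 %*% avg + e$par$b1, 0)
    hm <- pmax(e$par$W1 %*% mx + e$par$b1, 0)
    s <- e$par$W2 %*% ha + e$par$W2 %*% hm + 2 * e$par$b2
    cw <- .sigmoid(matrix(s, C, N))
    x1 <- cpp_scale_channels(x, cw)
    pc <- cpp_pool_c(x1)
    t4 <- cpp_conv2d_fwd(pc$spin, e$par$Wsp, e$par$bsp, 1L, pad)
    sm <- .sigmoid(array(t4, c(H, W, N)))
    y <- cpp_scale_spatial(x1, sm)
    if (train) {
      e$c <- list(d = d, x = x, avg = avg, mx = mx, mxidx = ph$arg,
                  ha = ha, hm = hm, cw = cw, x1 = x1, spin = pc$spin,
                  sm = sm, amax = pc$arg)
    }
    y
  }
  e$backward <- function(dy) {
    cc <- e$c
    d <- cc$d; H <- d[1]; W <- d[2]; N <- d[4]; HW <- H * W
    dx1 <- cpp_scale_spatial(dy, cc$sm)
    # spatial-attention path
    dsm <- cpp_sum_channels_prod(dy, cc$x1)
    dt <- dsm * cc$sm * (1 - cc$sm)
    dt4 <- array(dt, c(H, W, 1, N))
    r <- cpp_conv2d_bwd(cc$spin, e$par$Wsp, dt4, 1L, pad)
    e$grad$Wsp <- r$dw
    e$grad$bsp <- r$db
    dmean <- matrix(r$dx[, , 1, ], HW, N)
    dmaxc <- matrix(r$dx[, , 2, ], HW, N)
    dxm1 <- matrix(dx1, HW, C * N) +
      dmean[, rep(seq_len(N), each = C), drop = FALSE] / C
    idx <- rep(seq_len(HW), times = N) +
      HW * ((rep(seq_len(N), each = HW) - 1) * C + as.vector(cc$amax) - 1)
    dxm1[idx] <- dxm1[idx] + as.vector(dmaxc)
    dim(dxm1) <- d
    # channel-attention path
    dxm <- matrix(cpp_scale_channels(dxm1, cc$cw), HW, C * N)
    dcw <- cpp_sum_hw_prod(dxm1, cc$x)
    ds <- dcw * cc$cw * (1 - cc$cw)
    dW2 <- ds %*% t(cc$ha) + ds %*% t(cc$hm)
    db2 <- 2 * rowSums(ds)
    dha <- (t(e$par$W2) %*% ds) * (cc$ha > 0)
    dhm <- (t(e$par$W2) %*% ds) * (cc$hm > 0)
    dW1 <- dha %*% t(cc$avg) + dhm %*% t(cc$mx)
    db1 <- rowSums(dha) + rowSums(dhm)
    e$grad$W1 <- dW1; e$grad$b1 <- db1
    e$grad$W2 <- dW2; e$grad$b2 <- db2
    davg <- t(e$par$W1) %*% dha
    dmx <- t(e$par$W1) %*% dhm
    dxm <- dxm + rep(as.vector(davg) / HW, each = HW)
    idx2 <- as.vector(cc$mxidx) + HW * (seq_len(C * N) - 1)
    dxm[idx2] <- dxm[idx2] + as.vector(dmx)
    e$c <- NULL
    array(dxm, d)
  }
  e
}

# ---- bottleneck residual block with CBAM before the skip addition ----

nnBottleneck <- function(inC, width, outC, stride = 1L,
                         reductionRatio = 16, spatialKernel = 7) {
  e <- new.env(parent = emptyenv())
  e$type <- "bottleneck"
  e$par <- list(); e$grad <- list()
  e$conv1 <- nnConv(inC, width, 1L, 1L, 0L)
  e$bn1 <- nnBatchNorm(width)
  e$relu1 <- nnReLU()
  e$conv2 <- nnConv(width, width, 3L, stride, 1L)
  e$bn2 <- nnBatchNorm(width)
  e$relu2 <- nnReLU()
  e$conv3 <- nnConv(width, outC, 1L, 1L, 0L)
  # zero-init gamma: the block starts as (a scaled) identity, which keeps
  # early training stable without a warm-up schedule
  e$bn3 <- nnBatchNorm(outC, zero_gamma = TRUE)
  e$cbam <- nnCBAM(outC, reductionRatio, spatialKernel)
  e$relu_out <- nnReLU()
  e$has_down <- (inC != outC) || (stride != 1L)
  if (e$has_down) {
    e$down_conv <- nnConv(inC, outC, 1L, stride, 0L)
    e$down_bn <- nnBatchNorm(outC)
  }
  e$children <- Filter(Negate(is.null),
                       list(e$conv1, e$bn1, e$conv2, e$bn2, e$conv3, e$bn3,
                            e$cbam,
                            if (e$has_down) e$down_conv,
                            if (e$has_down) e$down_bn))
  e$forward <- function(x, train = TRUE) {
    out <- e$relu1$forward(e$bn1$forward(e$conv1$forward(x, train), train), train)
    out <- e$relu2$forward(e$bn2$forward(e$conv2$forward(out, train), train), train)
    out <- e$cbam$forward(e$bn3$forward(e$conv3$forward(out, train), train), train)
    skip <- if (e$has_down)
      e$down_bn$forward(e$down_conv$forward(x, train), train) else x
    e$relu_out$forward(out + skip, train)
  }
  e$backward <- function(dy) {
    dsum <- e$relu_out$backward(dy)
    dmain <- e$conv1$backward(e$bn1$backward(e$relu1$backward(
      e$conv2$backward(e$bn2$backward(e$relu2$backward(
        e$conv3$backward(e$bn3$backward(e$cbam$backward(dsum)))))))))
    dskip <- if (e$has_down)
      e$down_conv$backward(e$down_bn$backward(dsum)) else dsum
    dmain + dskip
  }
  e
}

#' Construct the residual CBAM classifier
#'
#' The full variant is the standard 50-layer bottleneck network (stage layout
#' 3-4-6-3, base width 64, expansion 4) with a CBAM module in every residual
#' block, a single grayscale input channel, and a two-layer fully connected
#' head with ReLU between. The reduced variant (stage layout 1-1-1-1, base
#' width 16) keeps the identical architecture family at desk scale.
#'
#' @param variant "full" or "reduced".
#' @param inputChannels input image channels (default 1, grayscale CT).
#' @param numClasses output classes (default 2).
#' @param reductionRatio,spatialKernel CBAM hyperparameters (defaults 16, 7).
#' @param inputSide expected square input side (default 224).
#' @param seed optional integer; when given, parameter initialization is
#'   seeded and therefore reproducible.
#' @return a model object usable with [trainModel()] and [predictProb()].
#' @export
resnetCbam <- function(variant = c("full", "reduced"), inputChannels = 1L,
                       numClasses = 2L, reductionRatio = 16, spatialKernel = 7,
                       inputSide = 224L, seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(as.integer(seed))
  # the reduced variant adds a second stem pool: phantom texture carries no
  # cross-patient information, so a coarser front end regularizes and costs
  # a quarter of the compute
  cfg <- if (variant == "full")
    list(stem = 64L, widths = c(64L, 128L, 256L, 512L),
         blocks = c(3L, 4L, 6L, 3L), extraPool = FALSE)
  else
    list(stem = 16L, widths = c(16L, 32L, 64L, 128L),
         blocks = c(1L, 1L, 1L, 1L), extraPool = TRUE)
  e <- new.env(parent = emptyenv())
  e$type <- "resnet_cbam"
  e$par <- list(); e$grad <- list()
  e$variant <- variant
  e$inputSide <- as.integer(inputSide)
  e$stem_conv <- nnConv(inputChannels, cfg$stem, 7L, 2L, 3L)
  e$stem_bn <- nnBatchNorm(cfg$stem)
  e$stem_relu <- nnReLU()
  e$pool <- nnMaxPool(3L, 2L, 1L)
  e$pool2 <- if (cfg$extraPool) nnMaxPool(3L, 2L, 1L) else NULL
  blocks <- list()
  inC <- cfg$stem
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      outC <- cfg$widths[s] * 4L
      blocks <- c(blocks, list(nnBottleneck(inC, cfg$widths[s], outC, stride,
                                            reductionRatio, spatialKernel)))
      inC <- outC
    }
  }
  e$blocks <- blocks
  e$gap <- nnGlobalAvgPool()
  hidden <- 64L
  e$fc1 <- nnLinear(inC, hidden)
  e$fc_relu <- nnReLU()
  e$fc2 <- nnLinear(hidden, numClasses)
  e$children <- c(list(e$stem_conv, e$stem_bn), blocks,
                  list(e$fc1, e$fc2))
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (d[1] != e$inputSide || d[2] != e$inputSide)
      stop("input must be ", e$inputSide, " x ", e$inputSide,
           " (got ", d[1], " x ", d[2], ")")
    h <- e$pool$forward(e$stem_relu$forward(
      e$stem_bn$forward(e$stem_conv$forward(x, train), train), train), train)
    if (!is.null(e$pool2)) h <- e$pool2$forward(h, train)
    for (blk in e$blocks) h <- blk$forward(h, train)
    f <- e$gap$forward(h, train)
    e$fc2$forward(e$fc_relu$forward(e$fc1$forward(f, train), train), train)
  }
  e$backward <- function(dlogits) {
    dh <- e$fc1$backward(e$fc_relu$backward(e$fc2$backward(dlogits)))
    dh <- e$gap$backward(dh)
    for (blk in rev(e$blocks)) dh <- blk$backward(dh)
    if (!is.null(e$pool2)) dh <- e$pool2$backward(dh)
    e$stem_conv$backward(e$stem_bn$backward(
      e$stem_relu$backward(e$pool$backward(dh))))
  }
  e
}

# stack a list of PlaneImage (or matrices) into an [side, side, 1, N] batch
.plane_batch <- function(planes) {
  mats <- lapply(planes, function(p)
    if (methods::is(p, "PlaneImage")) planePixels(p) else p)
  side <- nrow(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(side, side, 1L, length(mats)))
}

#' Class probabilities for a set of planes
#'
#' Deterministic inference (batch-norm running statistics, no augmentation).
#'
#' @param model a [resnetCbam()] model.
#' @param planes list of [PlaneImage-class] (or bare matrices).
#' @param batchSize inference batch size.
#' @return N x 2 matrix of softmax probabilities (columns: class 0, class 1).
#' @export
predictProb <- function(model, planes, batchSize = 8L) {
  if (methods::is(planes, "PlaneImage")) planes <- list(planes)
  n <- length(planes)
  out <- matrix(NA_real_, n, 2)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    x <- .plane_batch(planes[i:j])
    logits <- model$forward(x, train = FALSE)
    z <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                         byrow = TRUE)
    ez <- exp(z)
    out[i:j, ] <- t(ez) / colSums(ez)
    i <- j + 1L
  }
  colnames(out) <- c("p0", "p1")
  out
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 5e-5 with an
#' L2 penalty of 1e-4, batch size 4, 50 epochs.
#'
#' @param lr learning rate (initial value when `cosineDecay` is on).
#' @param weightDecay L2 penalty coefficient (ridge-style; added to the
#'   gradient, i.e. classic L2 regularization under Adam).
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed controlling shuffling.
#' @param cosineDecay anneal the learning rate to ~0 over the epochs with a
#'   half-cosine schedule (off by default; recommended for short desk-scale
#'   schedules).
#' @param emaDecay exponential-moving-average decay for a Polyak-averaged
#'   copy of the weights used at inference; 0 disables.
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(lr = 5e-5, weightDecay = 1e-4, batchSize = 4L,
                        epochs = 50L, seed = 1L, cosineDecay = FALSE,
                        emaDecay = 0) {
  stopifnot(lr > 0, weightDecay >= 0, batchSize >= 1, epochs >= 0,
            emaDecay >= 0, emaDecay < 1)
  structure(list(lr = lr, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 cosineDecay = isTRUE(cosineDecay), emaDecay = emaDecay),
            class = "trainConfig")
}

#' Train the classifier
#'
#' Minimizes softmax cross-entropy plus the L2 penalty with Adam. Shuffling
#' is seeded, so a fixed (seed, data) pair reproduces the loss history
#' exactly. `epochs = 0` returns the model untouched with an empty history.
#'
#' @param model a [resnetCbam()] model (modified in place and returned).
#' @param planes list of training [PlaneImage-class].
#' @param labels integer vector in {0, 1}.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch loss.
#' @return list with `model` and `history` (data.frame epoch, loss, train_acc).
#' @export
trainModel <- function(model, planes, labels, config = trainConfig(),
                       verbose = FALSE) {
  stopifnot(length(planes) == length(labels))
  if (config$epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(), loss = numeric(),
                                     train_acc = numeric())))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  layers <- .collect_layers(model)
  set.seed(config$seed)
  n <- length(planes)
  t_step <- 0L
  n_steps <- config$epochs * ceiling(n / config$batchSize)
  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     train_acc = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    correct <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batchSize - 1L, n)
      sel <- ord[i:j]
      x <- .plane_batch(planes[sel])
      y <- as.integer(labels[sel])
      logits <- model$forward(x, train = TRUE)
      ce <- softmaxCrossEntropy(logits, y)
      if (!is.finite(ce$loss))
        stop("training aborted: non-finite loss at epoch ", ep,
             " (step ", t_step + 1L, ")")
      losses <- c(losses, ce$loss)
      correct <- correct + sum(max.col(t(ce$prob)) - 1L == y)
      model$backward(ce$dlogits)
      t_step <- t_step + 1L
      lr_t <- if (config$cosineDecay)
        config$lr * 0.5 * (1 + cos(pi * t_step / n_steps)) else config$lr
      adamStep(layers, lr_t, config$weightDecay, t_step,
               emaDecay = config$emaDecay)
      i <- j + 1L
    }
    hist$loss[ep] <- mean(losses)
    hist$train_acc[ep] <- correct / n
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  acc %.3f", ep, config$epochs,
                      hist$loss[ep], hist$train_acc[ep]))
  }
  if (config$emaDecay > 0) swapEmaWeights(layers)  # predict with averages
  list(model = model, history = hist)
}
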