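# A small reverse-mode layer framework for the residual attention network.
# Activations are column-major arrays [H, W, C, N]; each layer is an
# environment holding parameters (`par`), their gradients (`grad`), Adam
# state (`opt`) and closures forward(x, train) / backward(dy). A layer's
# backward must be called exactly once per forward (CBAM accumulates its
# shared-MLP gradients internally).

.he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

nnConv <- function(inC, outC, k, stride = 1L, pad = (k - 1L) %/% 2L,
                   bias = FALSE, zero_init = FALSE) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  W <- if (zero_init) array(0, c(k, k, inC, outC))
       else .he_init(c(k, k, inC, outC), k * k * inC)
  e$par <- list(W = W)
  if (bias) e$par$b <- numeric(outC)
  e$grad <- list()
  e$forward <- function(x, train = TRUE) {
    if (train) e$x <- x
    cpp_conv2d_fwd(x, e$par$W,
                   if (is.null(e$par$b)) NULL else e$par$b,
                   as.integer(stride), as.integer(pad))
  }
  e$backward <- function(dy) {
    r <- cpp_conv2d_bwd(e$x, e$par$W, dy, as.integer(stride), as.integer(pad))
    e$grad$W <- r$dw
    if (!is.null(e$par$b)) e$grad$b <- r$db
    e$x <- NULL
    r$dx
  }
  e
}

nnBatchNorm <- function(C, eps = 1e-5, momentum = 0.1, zero_gamma = FALSE) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$par <- list(gamma = if (zero_gamma) numeric(C) else rep(1, C),
                beta = numeric(C))
  e$grad <- list()
  e$rm <- numeric(C)
  e$rv <- rep(1, C)
  e$forward <- function(x, train = TRUE) {
    r <- cpp_bn_fwd(x, e$par$gamma, e$par$beta, e$rm, e$rv, eps, momentum,
                    train)
    if (train) {
      e$rm <- r$rmean
      e$rv <- r$rvar
      e$xhat <- r$xhat
      e$istd <- r$istd
    }
    r$y
  }
  e$backward <- function(dy) {
    r <- cpp_bn_bwd(dy, e$xhat, e$istd, e$par$gamma)
    e$grad$gamma <- r$dgamma
    e$grad$beta <- r$dbeta
    e$xhat <- NULL
    r$dx
  }
  e
}

nnReLU <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "relu"
  e$par <- list(); e$grad <- list()
  e$forward <- function(x, train = TRUE) {
    if (is.matrix(x)) {                 # dense head activations
      y <- pmax(x, 0)
    } else {
      y <- cpp_relu_fwd(x)
    }
    if (train) e$y <- y
    y
  }
  e$backward <- function(dy) {
    dx <- if (is.matrix(dy)) dy * (e$y > 0) else cpp_relu_bwd(dy, e$y)
    e$y <- NULL
    dx
  }
  e
}

nnMaxPool <- function(k = 3L, stride = 2L, pad = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"
  e$par <- list(); e$grad <- list()
  e$forward <- function(x, train = TRUE) {
    r <- cpp_maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
    if (train) { e$arg <- r$arg; e$in_dim <- dim(x) }
    r$y
  }
  e$backward <- function(dy) {
    dx <- cpp_maxpool_bwd(dy, e$arg, as.integer(e$in_dim))
    e$arg <- NULL
    dx
  }
  e
}

# global average pool: [H,W,C,N] -> C x N feature matrix
nnGlobalAvgPool <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "gap"
  e$par <- list(); e$grad <- list()
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (train) e$dims <- d
    matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  }
  e$backward <- function(dy) {
    d <- e$dims
    hw <- d[1] * d[2]
    array(rep(as.vector(dy) / hw, each = hw), d)
  }
  e
}

nnLinear <- function(inF, outF) {
  e <- new.env(parent = emptyenv())
  e$type <- "linear"
  e$par <- list(W = .he_init(c(outF, inF), inF), b = numeric(outF))
  e$grad <- list()
  e$forward <- function(x, train = TRUE) {   # x: inF x N
    if (train) e$x <- x
    e$par$W %*% x + e$par$b
  }
  e$backward <- function(dy) {
    e$grad$W <- dy %*% t(e$x)
    e$grad$b <- rowSums(dy)
    dx <- t(e$par$W) %*% dy
    e$x <- NULL
    dx
  }
  e
}

# softmax cross-entropy on logits (K x N); returns loss and dlogits
softmaxCrossEntropy <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  z <- logits - matrix(apply(logits, 2, max), K, N, byrow = TRUE)
  ez <- exp(z)
  p <- ez / matrix(colSums(ez), K, N, byrow = TRUE)
  idx <- cbind(y + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, prob = p, dlogits = dlog / N)
}

# ---- Adam ----

.collect_layers <- function(module) {
  if (is.environment(module)) {
    kids <- if (!is.null(module$children)) module$children else list()
    c(if (length(module$par)) list(module) else list(),
      unlist(lapply(kids, .collect_layers), recursive = FALSE))
  } else unlist(lapply(module, .collect_layers), recursive = FALSE)
}

adamStep <- function(layers, lr, weightDecay = 0, t = 1,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     emaDecay = 0) {
  for (ly in layers) {
    if (is.null(ly$opt)) ly$opt <- list()
    for (nm in names(ly$par)) {
      g <- ly$grad[[nm]]
      if (is.null(g)) next
      g <- g + weightDecay * ly$par[[nm]]   # L2 penalty
      st <- ly$opt[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      ly$par[[nm]] <- ly$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      ly$opt[[nm]] <- st
      if (emaDecay > 0) {
        if (is.null(ly$ema)) ly$ema <- list()
        pe <- ly$ema[[nm]]
        ly$ema[[nm]] <- if (is.null(pe)) ly$par[[nm]]
                        else emaDecay * pe + (1 - emaDecay) * ly$par[[nm]]
      }
    }
    ly$grad <- list()
  }
  invisible(NULL)
}

# swap in (or back out) the Polyak-averaged weights for inference
swapEmaWeights <- function(layers) {
  for (ly in layers) {
    if (is.null(ly$ema)) next
    for (nm in names(ly$ema)) {
      tmp <- ly$par[[nm]]
      ly$par[[nm]] <- ly$ema[[nm]]
      ly$ema[[nm]] <- tmp
    }
  }
  invisible(NULL)
}
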