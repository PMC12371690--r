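# Compact convolutional network, implemented directly on BLAS matrix
# products (im2col convolutions). Feature maps live in "spatial-major"
# matrices of shape (H*W*C, N): row index runs fastest within column within
# channel, one column per sample. All layers use 3x3 kernels, stride 1,
# zero padding 1; every block except the last is followed by 2x2 max
# pooling, the last by global average pooling, then a dense softmax head.

# ---- layer plans (precomputed index maps) ----------------------------------

make_conv_plan <- function(H, W, C, k = 3L) {
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W * C)
  j <- rep(rep(seq_len(W), each = H), times = C)
  ch <- rep(seq_len(C), each = H * W)
  pos_pad <- (ch - 1L) * Hp * Wp + j * Hp + (i + 1L)
  off_r <- rep(0L:(k - 1L), times = k)
  off_c <- rep(0L:(k - 1L), each = k)
  delta <- as.vector(vapply(seq_len(C), function(cc)
    (cc - 1L) * Hp * Wp + off_c * Hp + off_r, integer(k * k)))
  base <- as.vector(vapply(seq_len(W), function(jj)
    (jj - 1L) * Hp + seq_len(H), integer(H)))
  idx <- as.vector(outer(delta, base, "+"))
  list(H = H, W = W, C = C, k = k, P = H * W, k2C = k * k * C,
       n_pad = Hp * Wp * C, pos_pad = pos_pad, idx = idx)
}

make_pool_plan <- function(H, W, C) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), times = Wo * C)
  jo <- rep(rep(seq_len(Wo), each = Ho), times = C)
  co <- rep(seq_len(C), each = Ho * Wo)
  i1 <- (co - 1L) * H * W + (2L * jo - 2L) * H + (2L * io - 1L)
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo,
       i1 = i1, i2 = i1 + 1L, i3 = i1 + H, i4 = i1 + H + 1L)
}

# ---- layer forward/backward ------------------------------------------------

# convolution + per-channel batch normalization + ReLU. Channel-first
# layout (F x (P*N)) makes the BN statistics plain row means; length-F
# vectors recycle down the first dimension, so `Z - mu` etc. act per channel.
conv_forward <- function(X, ly, train = FALSE, bn_eps = 1e-5) {
  plan <- ly$plan
  N <- ncol(X)
  Xp <- matrix(0, plan$n_pad, N)
  Xp[plan$pos_pad, ] <- X
  M <- Xp[plan$idx, , drop = FALSE]
  dim(M) <- c(plan$k2C, plan$P * N)
  Z <- crossprod(ly$W, M)              # F x (P*N)
  if (train) {
    mu <- rowMeans(Z)
    v <- rowMeans(Z * Z) - mu * mu
  } else {
    mu <- ly$run_mu
    v <- ly$run_var
  }
  sigma <- sqrt(v + bn_eps)
  xhat <- (Z - mu) / sigma
  A <- ly$gamma * xhat + ly$beta
  pos <- A > 0
  A[!pos] <- 0
  Fn <- length(ly$gamma)
  out <- aperm(array(A, c(Fn, plan$P, N)), c(2, 1, 3))
  dim(out) <- c(plan$P * Fn, N)
  list(out = out,
       cache = if (train) list(M = M, xhat = xhat, sigma = sigma,
                               pos = pos, N = N, Fn = Fn),
       batch_mu = if (train) mu, batch_var = if (train) v)
}

conv_backward <- function(dOut, ly, cache, need_dx = TRUE) {
  plan <- ly$plan
  N <- cache$N; Fn <- cache$Fn
  dim(dOut) <- c(plan$P, Fn, N)
  dA <- aperm(dOut, c(2, 1, 3))
  dim(dA) <- c(Fn, plan$P * N)
  dA <- dA * cache$pos
  dgamma <- rowSums(dA * cache$xhat)
  dbeta <- rowSums(dA)
  m <- ncol(dA)
  dZ <- (ly$gamma / cache$sigma) *
    (dA - dbeta / m - cache$xhat * (dgamma / m))
  dW <- tcrossprod(cache$M, dZ)        # k2C x F
  dX <- NULL
  if (need_dx) {
    dM <- ly$W %*% dZ                  # k2C x (P*N)
    dim(dM) <- c(plan$k2C * plan$P, N)
    rs <- rowsum(dM, plan$idx)
    dXp <- matrix(0, plan$n_pad, N)
    dXp[as.integer(rownames(rs)), ] <- rs
    dX <- dXp[plan$pos_pad, , drop = FALSE]
  }
  list(dW = dW, dgamma = dgamma, dbeta = dbeta, dX = dX)
}

pool_forward <- function(X, plan) {
  x1 <- X[plan$i1, , drop = FALSE]; x2 <- X[plan$i2, , drop = FALSE]
  x3 <- X[plan$i3, , drop = FALSE]; x4 <- X[plan$i4, , drop = FALSE]
  out <- pmax(x1, x2, x3, x4)
  list(out = out, cache = list(x = list(x1, x2, x3, x4), out = out))
}

pool_backward <- function(dOut, plan, cache) {
  dX <- matrix(0, plan$H * plan$W * plan$C, ncol(dOut))
  rem <- matrix(TRUE, nrow(dOut), ncol(dOut))
  ii <- list(plan$i1, plan$i2, plan$i3, plan$i4)
  for (q in 1:4) {
    m <- rem & (cache$x[[q]] == cache$out)
    dX[ii[[q]], ] <- dOut * m
    rem <- rem & !m
  }
  dX
}

gap_forward <- function(X, HW, C) {
  rowsum(X, rep(seq_len(C), each = HW)) / HW
}

# global max pool per channel: X is (HW*C, N) -> (C, N) plus argmax cache
gmp_forward <- function(X, HW, C) {
  N <- ncol(X)
  Xm <- X; dim(Xm) <- c(HW, C * N)
  am <- max.col(t(Xm), ties.method = "first")
  vals <- Xm[cbind(am, seq_len(C * N))]
  list(out = matrix(vals, C, N), am = am)
}

gmp_backward <- function(dOut, am, HW, C) {
  N <- ncol(dOut)
  dXm <- matrix(0, HW, C * N)
  dXm[cbind(am, seq_len(C * N))] <- as.vector(dOut)
  dim(dXm) <- c(HW * C, N)
  dXm
}

# ---- model -----------------------------------------------------------------

#' Configure the compact patch CNN
#'
#' Four 3x3 convolution blocks (ReLU, 2x2 max pooling after all but the
#' last), each convolution followed by per-channel batch normalization and
#' ReLU; the classification head concatenates global average and global max
#' pooled features from every block (multi-scale texture pooling) into a
#' dense softmax layer.
#' Patches are block-averaged down to `input_size` x `input_size` before
#' entering the network; widths and textures of interest survive this
#' reduction while training stays desk-scale.
#'
#' @param n_classes number of output classes (>= 2).
#' @param input_size side of the network input in px; must divide the patch
#'   size and be divisible by 8 (default 56, i.e. 224/4).
#' @param channels filters per block (default `c(8, 16, 32, 32)`).
#' @param epochs maximum training epochs (default 10).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param patience early-stop after this many epochs without validation
#'   improvement (default 3).
#' @param standardize standardize each patch to zero mean / unit sd before
#'   input (default FALSE: absolute intensity is itself class information).
#' @param seed RNG seed for weight initialization and batch order.
#' @return a `cnn_config` list.
#' @export
small_cnn_config <- function(n_classes, input_size = 56L,
                             channels = c(8L, 16L, 32L, 32L),
                             epochs = 10L, lr = 1e-3, batch_size = 32L,
                             patience = 3L, standardize = FALSE, seed = 1L) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (input_size %% 2^(length(channels) - 1L) != 0L)
    stop("input_size must be divisible by ", 2^(length(channels) - 1L))
  structure(list(architecture = "small-cnn", n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size), channels = as.integer(channels),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), patience = as.integer(patience),
                 standardize = standardize, seed = as.integer(seed)),
            class = "cnn_config")
}

init_cnn <- function(config) {
  set.seed(config$seed)
  S <- config$input_size
  ch <- c(1L, config$channels)
  B <- length(config$channels)
  layers <- list(); H <- S; W <- S
  for (b in seq_len(B)) {
    k2C <- 9L * ch[b]
    Fn <- ch[b + 1L]
    layers[[b]] <- list(
      plan = make_conv_plan(H, W, ch[b]),
      W = matrix(rnorm(k2C * Fn, 0, sqrt(2 / k2C)), k2C, Fn),
      gamma = rep(1, Fn), beta = rep(0, Fn),
      run_mu = rep(0, Fn), run_var = rep(1, Fn),
      pool = if (b < B) make_pool_plan(H, W, Fn) else NULL)
    if (b < B) { H <- H %/% 2L; W <- W %/% 2L }
  }
  # multi-scale head: global average + max pooling of every block's output
  # (block-1 pooled ReLU features are soft quantile statistics of intensity,
  # deeper blocks summarize texture and width structure)
  head_hw <- integer(B); head_c <- config$channels
  Hh <- S; Wh <- S
  for (b in seq_len(B)) {
    if (b < B) { Hh <- Hh %/% 2L; Wh <- Wh %/% 2L }
    head_hw[b] <- Hh * Wh
  }
  Dh <- sum(2L * head_c)
  list(layers = layers, head_hw = head_hw, head_c = head_c,
       Wd = matrix(rnorm(Dh * config$n_classes, 0, sqrt(2 / Dh)),
                   Dh, config$n_classes),
       bd = rep(0, config$n_classes))
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

cnn_forward <- function(net, X, train = FALSE) {
  caches <- if (train) list() else NULL
  A <- X
  B <- length(net$layers)
  Gs <- vector("list", B); ams <- vector("list", B)
  for (b in seq_len(B)) {
    ly <- net$layers[[b]]
    cf <- conv_forward(A, ly, train = train)
    A <- cf$out
    if (train) {
      # exponential running statistics for inference-time normalization
      net$layers[[b]]$run_mu <- 0.9 * ly$run_mu + 0.1 * cf$batch_mu
      net$layers[[b]]$run_var <- 0.9 * ly$run_var + 0.1 * cf$batch_var
    }
    if (!is.null(ly$pool)) {
      pf <- pool_forward(A, ly$pool)
      if (train) caches[[b]] <- list(conv = cf$cache, pool = pf$cache)
      A <- pf$out
    } else {
      if (train) caches[[b]] <- list(conv = cf$cache)
    }
    gm <- gmp_forward(A, net$head_hw[b], net$head_c[b])
    Gs[[b]] <- rbind(gap_forward(A, net$head_hw[b], net$head_c[b]), gm$out)
    ams[[b]] <- gm$am
  }
  G <- do.call(rbind, Gs)                         # sum(2 C_b) x N
  Z <- crossprod(net$Wd, G) + net$bd              # K x N
  probs <- softmax_cols(Z)
  list(probs = probs, G = G, gmp_am = ams, caches = caches,
       net = if (train) net)
}

cnn_backward <- function(net, fwd, X, onehot) {
  N <- ncol(onehot)
  grads <- list()
  dZ <- (fwd$probs - onehot) / N                  # K x N
  grads$Wd <- tcrossprod(fwd$G, dZ)               # C x K
  grads$bd <- rowSums(dZ)
  dG <- net$Wd %*% dZ                             # sum(2 C_b) x N
  B <- length(net$layers)
  row0 <- c(0L, cumsum(2L * net$head_c))          # row offsets per block
  dA <- NULL
  for (b in rev(seq_len(B))) {
    ly <- net$layers[[b]]
    cache <- fwd$caches[[b]]
    Cb <- net$head_c[b]; hw <- net$head_hw[b]
    dGb <- dG[row0[b] + seq_len(2L * Cb), , drop = FALSE]
    head_grad <- dGb[seq_len(Cb), , drop = FALSE][rep(seq_len(Cb), each = hw), ,
                                                  drop = FALSE] / hw +
      gmp_backward(dGb[Cb + seq_len(Cb), , drop = FALSE], fwd$gmp_am[[b]], hw, Cb)
    dA <- if (is.null(dA)) head_grad else dA + head_grad
    if (!is.null(ly$pool)) dA <- pool_backward(dA, ly$pool, cache$pool)
    cb <- conv_backward(dA, ly, cache$conv, need_dx = b > 1L)
    grads[[paste0("W", b)]] <- cb$dW
    grads[[paste0("gamma", b)]] <- cb$dgamma
    grads[[paste0("beta", b)]] <- cb$dbeta
    dA <- cb$dX
  }
  grads
}

# flatten parameters for the optimizer
cnn_params <- function(net) {
  p <- list(Wd = net$Wd, bd = net$bd)
  for (b in seq_along(net$layers)) {
    p[[paste0("W", b)]] <- net$layers[[b]]$W
    p[[paste0("gamma", b)]] <- net$layers[[b]]$gamma
    p[[paste0("beta", b)]] <- net$layers[[b]]$beta
  }
  p
}

cnn_set_params <- function(net, p) {
  net$Wd <- p$Wd; net$bd <- p$bd
  for (b in seq_along(net$layers)) {
    net$layers[[b]]$W <- p[[paste0("W", b)]]
    net$layers[[b]]$gamma <- p[[paste0("gamma", b)]]
    net$layers[[b]]$beta <- p[[paste0("beta", b)]]
  }
  net
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# block-average a square matrix by integer factor f
downsample_block <- function(m, f) {
  if (f == 1L) return(m)
  a <- rowsum(m, rep(seq_len(nrow(m) %/% f), each = f))
  t(rowsum(t(a), rep(seq_len(ncol(m) %/% f), each = f))) / (f * f)
}

# patch_set -> input matrix (S*S x N), block-averaged and optionally
# per-patch standardized
prepare_cnn_inputs <- function(patches, config) {
  S <- config$input_size
  P <- patches$patch_size
  n <- nrow(patches$info)
  f <- P %/% S
  if (f * S != P)
    stop("input_size ", S, " must divide patch_size ", P)
  X <- matrix(0, S * S, n)
  for (i in seq_len(n)) {
    m <- downsample_block(patches$pixels[, , i], f)
    if (config$standardize) {
      s <- sd(m); m <- (m - mean(m)) / if (s > 0) s else 1
    }
    X[, i] <- m
  }
  X
}
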