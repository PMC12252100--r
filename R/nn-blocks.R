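# Composite blocks. Each layer owns `params` (its direct arrays) and
# optionally `sub` (named sublayers); collect_params()/set_params() walk that
# structure so the optimizer sees one parameter tree.

collect_params <- function(layer) {
  out <- layer$params %||% list()
  if (!is.null(layer$sub)) {
    out$sub <- lapply(layer$sub, collect_params)
  }
  out
}

set_layer_params <- function(layer, p) {
  sub <- p$sub
  p$sub <- NULL
  layer$params <- p
  if (!is.null(sub)) {
    for (nm in names(sub)) {
      layer$sub[[nm]] <- set_layer_params(layer$sub[[nm]], sub[[nm]])
    }
  }
  layer
}

# run a named list of sublayers sequentially
seq_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], x, training)
    x <- res$out
    caches[[i]] <- res$cache
    if (!is.null(res$layer)) layers[[i]] <- res$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  names(grads) <- names(layers)
  for (i in rev(seq_along(layers))) {
    res <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- res$dx
    grads[[i]] <- res$grads
  }
  list(dx = dout, grads = grads)
}

# ---- ConvBlock: conv -> BN -> ReLU -> MaxPool(2,1,1); length L -> L + 1 ----

conv_block_layer <- function(in_channels, out_channels, kernel = 3) {
  new_layer("conv_block", list(),
            sub = list(conv = conv1d_layer(in_channels, out_channels, kernel),
                       bn = batchnorm_layer(out_channels),
                       relu = relu_layer(),
                       pool = maxpool211_layer()))
}

#' @export
layer_forward.conv_block <- function(layer, x, training = FALSE) {
  res <- seq_forward(layer$sub, x, training)
  layer$sub <- res$layers
  list(out = res$out, cache = res$caches, layer = layer)
}

#' @export
layer_backward.conv_block <- function(layer, dout, cache) {
  res <- seq_backward(layer$sub, dout, cache)
  list(dx = res$dx, grads = list(sub = res$grads))
}

# ---- multi-scale fusion block ----------------------------------------------
# Four parallel convolutions (odd kernels), learnable softmax-normalized
# fusion weights, BN -> ReLU -> dropout -> MaxPool(2,1,1); a parallel
# ConvBlock2 branch; and a 1x1-conv residual skip from the block input. The
# three paths (each of length L + 1) are fused by element-wise addition.

multiscale_layer <- function(in_channels, out_channels, kernels = c(3, 11, 21, 31),
                             dropout = 0.3) {
  if (any(kernels %% 2 == 0)) stopf("multi-scale kernels must all be odd")
  convs <- lapply(kernels, function(k) conv1d_layer(in_channels, out_channels, k))
  names(convs) <- make.unique(paste0("k", kernels))
  new_layer("multiscale", list(logits = numeric(length(kernels))),
            sub = c(convs,
                    list(bn = batchnorm_layer(out_channels),
                         conv2 = conv_block_layer(in_channels, out_channels, 3),
                         skip = conv1d_layer(in_channels, out_channels, 1, pad = 0))),
            kernels = kernels,
            drop = dropout_layer(dropout),
            relu = relu_layer(),
            pool = maxpool211_layer(),
            skip_pool = maxpool211_layer())
}

#' @export
layer_forward.multiscale <- function(layer, x, training = FALSE) {
  nk <- length(layer$kernels)
  wts <- softmax_vec(layer$params$logits)
  branch <- vector("list", nk)
  bcache <- vector("list", nk)
  ybar <- NULL
  for (i in seq_len(nk)) {
    res <- layer_forward(layer$sub[[i]], x, training)
    branch[[i]] <- res$out
    bcache[[i]] <- res$cache
    ybar <- if (is.null(ybar)) wts[i] * res$out else ybar + wts[i] * res$out
  }
  bn <- layer_forward(layer$sub$bn, ybar, training)
  layer$sub$bn <- bn$layer
  rl <- layer_forward(layer$relu, bn$out, training)
  dp <- layer_forward(layer$drop, rl$out, training)
  pl <- layer_forward(layer$pool, dp$out, training)
  cb <- layer_forward(layer$sub$conv2, x, training)
  layer$sub$conv2 <- cb$layer
  sk <- layer_forward(layer$sub$skip, x, training)
  sp <- layer_forward(layer$skip_pool, sk$out, training)
  out <- pl$out + cb$out + sp$out
  list(out = out,
       cache = list(bcache = bcache, branch = branch, wts = wts, bn = bn$cache,
                    rl = rl$cache, dp = dp$cache, pl = pl$cache, cb = cb$cache,
                    sk = sk$cache, sp = sp$cache),
       layer = layer)
}

#' @export
layer_backward.multiscale <- function(layer, dout, cache) {
  nk <- length(layer$kernels)
  grads <- list(sub = stats::setNames(vector("list", length(layer$sub)),
                                      names(layer$sub)))
  # ConvBlock2 path
  g_cb <- layer_backward(layer$sub$conv2, dout, cache$cb)
  grads$sub$conv2 <- g_cb$grads
  dx <- g_cb$dx
  # skip path
  g_sp <- layer_backward(layer$skip_pool, dout, cache$sp)
  g_sk <- layer_backward(layer$sub$skip, g_sp$dx, cache$sk)
  grads$sub$skip <- g_sk$grads
  dx <- dx + g_sk$dx
  # fused multi-scale path
  g_pl <- layer_backward(layer$pool, dout, cache$pl)
  g_dp <- layer_backward(layer$drop, g_pl$dx, cache$dp)
  g_rl <- layer_backward(layer$relu, g_dp$dx, cache$rl)
  g_bn <- layer_backward(layer$sub$bn, g_rl$dx, cache$bn)
  grads$sub$bn <- g_bn$grads
  dybar <- g_bn$dx
  wts <- cache$wts
  dwts <- numeric(nk)
  for (i in seq_len(nk)) {
    dwts[i] <- sum(dybar * cache$branch[[i]])
    g_b <- layer_backward(layer$sub[[i]], wts[i] * dybar, cache$bcache[[i]])
    grads$sub[[i]] <- g_b$grads
    dx <- dx + g_b$dx
  }
  # softmax Jacobian for the fusion logits
  grads$logits <- wts * (dwts - sum(dwts * wts))
  list(dx = dx, grads = grads)
}

# ---- MLPBlock: dual branch with partial convolution ------------------------
# Main branch: conv -> BN -> ReLU -> conv (all "same", channels preserved).
# Partial branch: convolve the first ceil(partial_ratio * C) channels,
# identity on the rest. Branches fused by element-wise addition.

mlp_block_layer <- function(channels, kernel = 3, partial_ratio = 0.25) {
  if (partial_ratio <= 0 || partial_ratio > 1) stopf("partial_ratio must be in (0, 1]")
  cp <- as.integer(ceiling(partial_ratio * channels))
  new_layer("mlp_block", list(),
            sub = list(conv1 = conv1d_layer(channels, channels, kernel),
                       bn = batchnorm_layer(channels),
                       conv2 = conv1d_layer(channels, channels, kernel),
                       pconv = conv1d_layer(cp, cp, kernel)),
            channels = channels, cp = cp,
            relu = relu_layer())
}

#' @export
layer_forward.mlp_block <- function(layer, x, training = FALSE) {
  c1 <- layer_forward(layer$sub$conv1, x, training)
  bn <- layer_forward(layer$sub$bn, c1$out, training)
  layer$sub$bn <- bn$layer
  rl <- layer_forward(layer$relu, bn$out, training)
  c2 <- layer_forward(layer$sub$conv2, rl$out, training)
  cp <- layer$cp
  pc <- layer_forward(layer$sub$pconv, x[seq_len(cp), , , drop = FALSE], training)
  partial <- x
  partial[seq_len(cp), , ] <- pc$out
  list(out = c2$out + partial,
       cache = list(c1 = c1$cache, bn = bn$cache, rl = rl$cache, c2 = c2$cache,
                    pc = pc$cache),
       layer = layer)
}

#' @export
layer_backward.mlp_block <- function(layer, dout, cache) {
  cp <- layer$cp
  g_c2 <- layer_backward(layer$sub$conv2, dout, cache$c2)
  g_rl <- layer_backward(layer$relu, g_c2$dx, cache$rl)
  g_bn <- layer_backward(layer$sub$bn, g_rl$dx, cache$bn)
  g_c1 <- layer_backward(layer$sub$conv1, g_bn$dx, cache$c1)
  dx <- g_c1$dx
  # partial branch: convolved head channels + identity tail
  g_pc <- layer_backward(layer$sub$pconv, dout[seq_len(cp), , , drop = FALSE],
                         cache$pc)
  dx[seq_len(cp), , ] <- dx[seq_len(cp), , , drop = FALSE] + g_pc$dx
  tail_idx <- setdiff(seq_len(layer$channels), seq_len(cp))
  if (length(tail_idx)) {
    dx[tail_idx, , ] <- dx[tail_idx, , , drop = FALSE] +
      dout[tail_idx, , , drop = FALSE]
  }
  list(dx = dx,
       grads = list(sub = list(conv1 = g_c1$grads, bn = g_bn$grads,
                               conv2 = g_c2$grads, pconv = g_pc$grads)))
}

# ---- Efficient Channel Attention -------------------------------------------

#' Adaptive ECA kernel size
#'
#' `k` is the nearest odd integer to `|log2(C) / gamma + b / gamma|`
#' (ties broken downward), floored at 1.
#'
#' @param channels channel count `C`.
#' @param gamma,b adaptive-kernel constants (defaults 2 and 1).
#' @return odd integer kernel size.
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  t <- abs(log2(channels) / gamma + b / gamma)
  lo <- 2 * floor((t - 1) / 2) + 1 # largest odd <= t (or t-1 < odd <= t)
  cands <- c(lo, lo + 2)
  k <- cands[which.min(abs(cands - t))] # ties -> first (lower)
  max(1L, as.integer(k))
}

eca_layer <- function(channels, gamma = 2, b = 1) {
  k <- eca_kernel_size(channels, gamma, b)
  new_layer("eca", list(w = stats::rnorm(k, 0, 0.1)),
            channels = channels, k = k, pad = (k - 1L) %/% 2L)
}

#' @export
layer_forward.eca <- function(layer, x, training = FALSE) {
  d <- dim(x) # (C, L, n)
  C <- d[1]; L <- d[2]; n <- d[3]
  xm <- aperm(x, c(1, 3, 2)); dim(xm) <- c(C * n, L)
  s <- rowMeans(xm); dim(s) <- c(C, n) # channel-wise global average pool
  k <- layer$k; p <- layer$pad
  sp <- matrix(0, C + 2 * p, n)
  sp[p + seq_len(C), ] <- s
  z <- matrix(0, C, n)
  for (j in seq_len(k)) {
    z <- z + layer$params$w[j] * sp[(j - 1) + seq_len(C), , drop = FALSE]
  }
  a <- sigmoid(z) # per-channel weights in (0, 1)
  out <- x * aperm(array(a, c(C, n, L)), c(1, 3, 2))
  list(out = out, cache = list(x = x, s = s, sp = sp, a = a, d = d))
}

#' @export
layer_backward.eca <- function(layer, dout, cache) {
  d <- cache$d
  C <- d[1]; L <- d[2]; n <- d[3]
  a_full <- aperm(array(cache$a, c(C, n, L)), c(1, 3, 2))
  dx <- dout * a_full
  # gradient into the channel weights
  da_full <- dout * cache$x
  dm <- aperm(da_full, c(1, 3, 2)); dim(dm) <- c(C * n, L)
  da <- rowSums(dm); dim(da) <- c(C, n)
  dz <- da * cache$a * (1 - cache$a)
  k <- layer$k; p <- layer$pad
  dw <- numeric(k)
  dsp <- matrix(0, C + 2 * p, n)
  for (j in seq_len(k)) {
    rows <- (j - 1) + seq_len(C)
    dw[j] <- sum(dz * cache$sp[rows, , drop = FALSE])
    dsp[rows, ] <- dsp[rows, , drop = FALSE] + layer$params$w[j] * dz
  }
  ds <- dsp[p + seq_len(C), , drop = FALSE]
  # s was a mean over L: spread back uniformly
  dx <- dx + aperm(array(ds / L, c(C, n, L)), c(1, 3, 2))
  list(dx = dx, grads = list(w = dw))
}
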