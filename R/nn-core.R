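# Minimal neural-network kernel: primitive 1-D layers with hand-derived
# backward passes, operating on arrays of shape (channels, length, batch).
# Everything is double precision and seeded; matrix products go through BLAS.

# dot-prefixed formals so fields passed through ... can never partially
# match them
new_layer <- function(.kind, .params = list(), ...) {
  structure(c(list(kind = .kind, params = .params), list(...)),
            class = c(.kind, "nn_layer"))
}

layer_forward <- function(layer, x, training = FALSE) UseMethod("layer_forward")
layer_backward <- function(layer, dout, cache) UseMethod("layer_backward")

# ---- parameter trees -------------------------------------------------------

# flatten a nested list of numeric arrays into a flat named list
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], key))
    } else {
      out[[key]] <- p[[nm]]
    }
  }
  out
}

# apply f(leaf_a, leaf_b) over two parallel parameter trees
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- map2_params(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

map_params <- function(a, f) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- map_params(a[[nm]], f)
    a
  } else {
    f(a)
  }
}

zeros_like <- function(a) map_params(a, function(x) x * 0)

n_param_scalars <- function(p) sum(vapply(flatten_params(p), length, integer(1)))

# ---- initializers ----------------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

uniform_init <- function(dims, bound) {
  array(stats::runif(prod(dims), -bound, bound), dims)
}

# ---- conv1d ----------------------------------------------------------------

# "same"-style padding for odd kernels is pad = (k - 1) / 2
conv1d_layer <- function(in_channels, out_channels, kernel, pad = (kernel - 1) %/% 2,
                         bias = TRUE) {
  W <- he_init(out_channels, in_channels * kernel, in_channels * kernel)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_channels)
  new_layer("conv1d", params, in_channels = in_channels,
            out_channels = out_channels, kernel = kernel, pad = pad,
            bias = bias)
}

#' @export
layer_forward.conv1d <- function(layer, x, training = FALSE) {
  if (dim(x)[1] != layer$in_channels) {
    stopf("conv1d: expected %d input channels, got %d (layer kernel %d)",
          layer$in_channels, dim(x)[1], layer$kernel)
  }
  if (dim(x)[2] + 2L * layer$pad < layer$kernel) {
    stopf("input length %d too short for kernel %d", dim(x)[2], layer$kernel)
  }
  b <- if (layer$bias) layer$params$b else numeric(layer$out_channels)
  out <- conv1d_fwd_cpp(x, layer$params$W, b, layer$pad, layer$bias)
  list(out = out, cache = list(x = x))
}

#' @export
layer_backward.conv1d <- function(layer, dout, cache) {
  res <- conv1d_bwd_cpp(dout, cache$x, layer$params$W, layer$pad, layer$bias)
  grads <- list(W = res$dW)
  if (layer$bias) grads$b <- as.numeric(res$db)
  list(dx = res$dx, grads = grads)
}

# ---- batchnorm1d -----------------------------------------------------------

batchnorm_layer <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("batchnorm", list(gamma = rep(1, channels), beta = numeric(channels)),
            channels = channels, momentum = momentum, eps = eps,
            running_mean = numeric(channels), running_var = rep(1, channels))
}

#' @export
layer_forward.batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  m <- prod(d[-1])
  xm <- x; dim(xm) <- c(d[1], m)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2 # biased variance, as used for normalization
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * inv
  out <- layer$params$gamma * xhat + layer$params$beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv = inv, dims = d, m = m,
                               training = training),
       layer = layer)
}

#' @export
layer_backward.batchnorm <- function(layer, dout, cache) {
  d <- cache$dims
  dm <- dout; dim(dm) <- c(d[1], cache$m)
  grads <- list(gamma = rowSums(dm * cache$xhat), beta = rowSums(dm))
  dxhat <- dm * layer$params$gamma
  if (cache$training) {
    m <- cache$m
    dx <- cache$inv / m *
      (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$inv
  }
  dim(dx) <- d
  list(dx = dx, grads = grads)
}

# ---- relu ------------------------------------------------------------------

relu_layer <- function() new_layer("relu")

#' @export
layer_forward.relu <- function(layer, x, training = FALSE) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

#' @export
layer_backward.relu <- function(layer, dout, cache) {
  list(dx = dout * cache, grads = list())
}

# ---- max pool (kernel 2, stride 1, padding 1): output length L + 1 ---------

maxpool211_layer <- function() new_layer("maxpool211")

#' @export
layer_forward.maxpool211 <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- d[1]; L <- d[2]; n <- d[3]
  # window t covers padded positions (t-1, t): out[1] = x[1], out[L+1] = x[L]
  a <- x[, c(1L, seq_len(L)), , drop = FALSE]       # left element (pad = -Inf -> x[1] dominates at t = 1)
  b <- x[, c(seq_len(L), L), , drop = FALSE]        # right element
  left <- a >= b
  left[, 1L, ] <- FALSE # window 1 holds (-Inf, x[1]): the right element wins
  left[, L + 1L, ] <- TRUE # window L+1 holds (x[L], -Inf)
  list(out = pmax(a, b), cache = list(left = left, L = L))
}

#' @export
layer_backward.maxpool211 <- function(layer, dout, cache) {
  d <- dim(dout)
  L <- cache$L
  dl <- dout * cache$left   # flows to padded position t - 1
  dr <- dout * !cache$left  # flows to padded position t
  dx <- dl[, 1L + seq_len(L), , drop = FALSE]
  dx <- dx + dr[, seq_len(L), , drop = FALSE]
  list(dx = dx, grads = list())
}

# ---- dropout ---------------------------------------------------------------

dropout_layer <- function(p) new_layer("dropout", p = p)

#' @export
layer_forward.dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p == 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- array(stats::runif(length(x)) >= layer$p, dim(x)) / (1 - layer$p)
  list(out = x * mask, cache = mask)
}

#' @export
layer_backward.dropout <- function(layer, dout, cache) {
  if (is.null(cache)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache, grads = list())
}

# ---- dense (on feature matrices of shape (features, batch)) ----------------

linear_layer <- function(in_features, out_features) {
  new_layer("linear",
            list(W = he_init(out_features, in_features, in_features),
                 b = numeric(out_features)),
            in_features = in_features, out_features = out_features)
}

#' @export
layer_forward.linear <- function(layer, x, training = FALSE) {
  list(out = layer$params$W %*% x + layer$params$b, cache = x)
}

#' @export
layer_backward.linear <- function(layer, dout, cache) {
  list(dx = crossprod(layer$params$W, dout),
       grads = list(W = dout %*% t(cache), b = rowSums(dout)))
}

# ---- elementwise tanh ------------------------------------------------------

tanh_layer <- function() new_layer("tanhsq")

#' @export
layer_forward.tanhsq <- function(layer, x, training = FALSE) {
  out <- tanh(x)
  list(out = out, cache = out)
}

#' @export
layer_backward.tanhsq <- function(layer, dout, cache) {
  list(dx = dout * (1 - cache^2), grads = list())
}

# ---- temporal mean pool: (C, L, n) -> (C, n) -------------------------------

meanpool_layer <- function() new_layer("meanpool")

#' @export
layer_forward.meanpool <- function(layer, x, training = FALSE) {
  d <- dim(x)
  xm <- aperm(x, c(1, 3, 2))
  dim(xm) <- c(d[1] * d[3], d[2])
  out <- rowMeans(xm)
  dim(out) <- c(d[1], d[3])
  list(out = out, cache = d)
}

#' @export
layer_backward.meanpool <- function(layer, dout, cache) {
  d <- cache
  dx <- aperm(array(dout / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
  list(dx = dx, grads = list())
}

# ---- softmax over classes: (K, n) -> (K, n) --------------------------------

softmax_layer <- function() new_layer("softmax")

#' @export
layer_forward.softmax <- function(layer, x, training = FALSE) {
  list(out = softmax_cols(x), cache = NULL)
}

#' @export
layer_backward.softmax <- function(layer, dout, cache) {
  # the training loop differentiates the loss directly w.r.t. the logits and
  # starts backward below this layer; dout here is already d(loss)/d(logits)
  list(dx = dout, grads = list())
}

# rebuild a parameter tree from its flattened form (inverse of
# flatten_params for a template tree with the same structure)
relist_params <- function(flat, template, prefix = "") {
  out <- template
  for (nm in names(template)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(template[[nm]])) {
      out[[nm]] <- relist_params(flat, template[[nm]], key)
    } else {
      out[[nm]] <- flat[[key]]
    }
  }
  out
}
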