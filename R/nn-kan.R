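# Kolmogorov-Arnold layer: every edge carries phi(u) = w_b*silu(u) +
# w_s * sum_i c_i B_i(u) on a fixed clamped B-spline grid; nodes only sum
# their incoming edges (plus a bias). A bounded tanh squash precedes each
# layer so inputs respect the spline range.

make_knots <- function(G, k, range = c(-1, 1)) {
  c(rep(range[1], k), seq(range[1], range[2], length.out = G + 1), rep(range[2], k))
}

#' B-spline basis functions on a clamped uniform grid
#'
#' Cox-de Boor recursion for the `G + k` basis functions of order (degree)
#' `k` on `G` uniform intervals over `range`, with endpoint knots repeated
#' `k` times. Values outside the range are clamped to the boundary. Interior
#' points satisfy the partition of unity; order 0 gives interval indicators.
#'
#' @param u numeric vector of evaluation points.
#' @param G number of grid intervals.
#' @param k spline order (polynomial degree).
#' @param range length-2 numeric grid range.
#' @param derivative if `TRUE`, also return the first-derivative matrix.
#' @return matrix `length(u) x (G + k)`, or `list(B, dB)` when
#'   `derivative = TRUE`.
#' @export
bspline_basis <- function(u, G = 5, k = 3, range = c(-1, 1), derivative = FALSE) {
  knots <- make_knots(G, k, range)
  nk <- length(knots)
  m <- length(u)
  u <- clamp(u, range[1], range[2])
  j <- findInterval(u, knots)
  j[u >= range[2]] <- k + G # last non-degenerate interval
  B <- matrix(0, m, nk - 1L)
  B[cbind(seq_len(m), j)] <- 1
  Bprev <- NULL
  for (p in seq_len(k)) {
    if (p == k) Bprev <- B
    nb <- nk - p - 1L
    Bn <- matrix(0, m, nb)
    for (i in seq_len(nb)) {
      d1 <- knots[i + p] - knots[i]
      d2 <- knots[i + p + 1L] - knots[i + 1L]
      if (d1 > 0) Bn[, i] <- Bn[, i] + (u - knots[i]) / d1 * B[, i]
      if (d2 > 0) Bn[, i] <- Bn[, i] + (knots[i + p + 1L] - u) / d2 * B[, i + 1L]
    }
    B <- Bn
  }
  if (!derivative) return(B)
  if (k == 0) return(list(B = B, dB = matrix(0, m, ncol(B))))
  nb <- nk - k - 1L
  dB <- matrix(0, m, nb)
  for (i in seq_len(nb)) {
    d1 <- knots[i + k] - knots[i]
    d2 <- knots[i + k + 1L] - knots[i + 1L]
    if (d1 > 0) dB[, i] <- dB[, i] + k / d1 * Bprev[, i]
    if (d2 > 0) dB[, i] <- dB[, i] - k / d2 * Bprev[, i + 1L]
  }
  list(B = B, dB = dB)
}

kan_layer <- function(in_dim, out_dim, G = 5, k = 3, range = c(-1, 1)) {
  nb <- G + k
  new_layer("kan",
            list(coef = array(stats::rnorm(out_dim * in_dim * nb, 0, 0.1 / sqrt(in_dim)),
                              c(out_dim, in_dim, nb)),
                 wb = he_init(out_dim, in_dim, in_dim),
                 ws = matrix(1, out_dim, in_dim),
                 bias = numeric(out_dim)),
            in_dim = in_dim, out_dim = out_dim, G = G, k = k, range = range,
            nb = nb)
}

#' @export
layer_forward.kan <- function(layer, x, training = FALSE) {
  if (nrow(x) != layer$in_dim) {
    stopf("kan: expected %d inputs, got %d", layer$in_dim, nrow(x))
  }
  n <- ncol(x)
  u <- clamp(x, layer$range[1], layer$range[2])
  bs <- bspline_basis(as.vector(u), layer$G, layer$k, layer$range, derivative = TRUE)
  S <- silu(u)
  out <- layer$params$wb %*% S + layer$params$bias
  for (b in seq_len(layer$nb)) {
    Bb <- matrix(bs$B[, b], layer$in_dim, n)
    out <- out + (layer$params$ws * layer$params$coef[, , b]) %*% Bb
  }
  list(out = out, cache = list(u = u, S = S, B = bs$B, dB = bs$dB, n = n,
                               clamped = x != u))
}

#' @export
layer_backward.kan <- function(layer, dout, cache) {
  p <- layer$params
  n <- cache$n
  grads <- list(coef = array(0, dim(p$coef)), wb = NULL, ws = matrix(0, layer$out_dim, layer$in_dim),
                bias = rowSums(dout))
  grads$wb <- dout %*% t(cache$S)
  du <- crossprod(p$wb, dout) * silu_grad(cache$u)
  for (b in seq_len(layer$nb)) {
    Bb <- matrix(cache$B[, b], layer$in_dim, n)
    M <- dout %*% t(Bb)
    grads$coef[, , b] <- p$ws * M
    grads$ws <- grads$ws + p$coef[, , b] * M
    dBb <- matrix(cache$dB[, b], layer$in_dim, n)
    du <- du + dBb * crossprod(p$ws * p$coef[, , b], dout)
  }
  du[cache$clamped] <- 0 # no gradient through the boundary clamp
  list(dx = du, grads = grads)
}

# evaluate one edge's activation phi(u) on a vector of points
kan_edge_curve <- function(layer, out_idx, in_idx, u) {
  B <- bspline_basis(u, layer$G, layer$k, layer$range)
  as.numeric(layer$params$wb[out_idx, in_idx] * silu(clamp(u, layer$range[1], layer$range[2])) +
               layer$params$ws[out_idx, in_idx] * (B %*% layer$params$coef[out_idx, in_idx, ]))
}

#' Export the learned spline activations of a model
#'
#' Serializable record of every KAN layer: grid knots, per-edge coefficients
#' and base/spline weights, and each edge's activation curve sampled at 101
#' points across the spline range.
#'
#' @param model a built model (see [build_model()]).
#' @param n_points samples per curve.
#' @return list of per-layer export records, class `kan_export`.
#' @export
kan_spline_export <- function(model, n_points = 101) {
  out <- list()
  for (nm in names(model$layers)) {
    layer <- model$layers[[nm]]
    if (!inherits(layer, "kan")) next
    u <- seq(layer$range[1], layer$range[2], length.out = n_points)
    curves <- array(0, c(layer$out_dim, layer$in_dim, n_points))
    for (o in seq_len(layer$out_dim)) {
      for (i in seq_len(layer$in_dim)) {
        curves[o, i, ] <- kan_edge_curve(layer, o, i, u)
      }
    }
    out[[nm]] <- list(name = nm, in_dim = layer$in_dim, out_dim = layer$out_dim,
                      G = layer$G, k = layer$k, range = layer$range,
                      knots = make_knots(layer$G, layer$k, layer$range),
                      coef = layer$params$coef, wb = layer$params$wb,
                      ws = layer$params$ws, bias = layer$params$bias,
                      u = u, curves = curves)
  }
  structure(out, class = "kan_export")
}

#' Rebuild a KAN layer from an export record
#' @param rec one element of a [kan_spline_export()].
#' @return a KAN layer with identical parameters (identical forward outputs).
#' @export
kan_layer_from_export <- function(rec) {
  layer <- kan_layer(rec$in_dim, rec$out_dim, rec$G, rec$k, rec$range)
  layer$params <- list(coef = rec$coef, wb = rec$wb, ws = rec$ws, bias = rec$bias)
  layer
}
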