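# Bidirectional GRU. Gating convention (per direction, per step, on column
# matrices of shape hidden x batch):
#   z_t = sigmoid(Wz x_t + Uz h_{t-1} + bz)        update gate
#   r_t = sigmoid(Wr x_t + Ur h_{t-1} + br)        reset gate
#   c_t = tanh(Wn x_t + r_t * (Un h_{t-1}) + bn)   candidate state
#   h_t = (1 - z_t) * c_t + z_t * h_{t-1}
# The per-step output concatenates forward and backward states. Backward
# runs the same recursion on the time-reversed input with its own
# parameters, and its output sequence is re-reversed before concatenation.
# Input-to-hidden products are hoisted out of the time loop (one BLAS call
# per gate over all steps); only hidden-to-hidden products recur.

gru_dir_params <- function(in_features, hidden) {
  bound <- 1 / sqrt(hidden)
  mk <- function(nr, nc) uniform_init(c(nr, nc), bound)
  list(Wz = mk(hidden, in_features), Uz = mk(hidden, hidden), bz = numeric(hidden),
       Wr = mk(hidden, in_features), Ur = mk(hidden, hidden), br = numeric(hidden),
       Wn = mk(hidden, in_features), Un = mk(hidden, hidden), bn = numeric(hidden))
}

bigru_layer <- function(in_features, hidden, n_layers = 2) {
  params <- list()
  inf <- in_features
  for (l in seq_len(n_layers)) {
    params[[paste0("l", l, "_fwd")]] <- gru_dir_params(inf, hidden)
    params[[paste0("l", l, "_bwd")]] <- gru_dir_params(inf, hidden)
    inf <- 2L * hidden
  }
  new_layer("bigru", params, in_features = in_features, hidden = hidden,
            n_layers = n_layers)
}

# one direction over a (D, L, n) input; returns (H, L, n) states + cache
gru_dir_forward <- function(p, x) {
  res <- gru_fwd_cpp(x, p$Wz, p$Uz, p$bz, p$Wr, p$Ur, p$br, p$Wn, p$Un, p$bn)
  list(out = res$out,
       cache = list(x = x, Z = res$Z, R = res$R, A = res$A, Cst = res$Cst,
                    Hprev = res$Hprev))
}

gru_dir_backward <- function(p, dout, cc) {
  res <- gru_bwd_cpp(dout, cc$x, cc$Z, cc$R, cc$A, cc$Cst, cc$Hprev,
                     p$Uz, p$Ur, p$Un, p$Wz, p$Wr, p$Wn)
  list(dx = res$dx,
       grads = list(Wz = res$gWz, Uz = res$gUz, bz = as.numeric(res$gbz),
                    Wr = res$gWr, Ur = res$gUr, br = as.numeric(res$gbr),
                    Wn = res$gWn, Un = res$gUn, bn = as.numeric(res$gbn)))
}

rev_time <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]

#' @export
layer_forward.bigru <- function(layer, x, training = FALSE) {
  caches <- list()
  cur <- x
  for (l in seq_len(layer$n_layers)) {
    fw <- gru_dir_forward(layer$params[[paste0("l", l, "_fwd")]], cur)
    bw <- gru_dir_forward(layer$params[[paste0("l", l, "_bwd")]], rev_time(cur))
    caches[[l]] <- list(fw = fw$cache, bw = bw$cache)
    H <- layer$hidden
    d <- dim(cur)
    out <- array(0, c(2L * H, d[2], d[3]))
    out[seq_len(H), , ] <- fw$out
    out[H + seq_len(H), , ] <- rev_time(bw$out)
    cur <- out
  }
  list(out = cur, cache = caches)
}

#' @export
layer_backward.bigru <- function(layer, dout, cache) {
  H <- layer$hidden
  grads <- list()
  for (l in rev(seq_len(layer$n_layers))) {
    cc <- cache[[l]]
    gf <- gru_dir_backward(layer$params[[paste0("l", l, "_fwd")]],
                           dout[seq_len(H), , , drop = FALSE], cc$fw)
    gb <- gru_dir_backward(layer$params[[paste0("l", l, "_bwd")]],
                           rev_time(dout[H + seq_len(H), , , drop = FALSE]), cc$bw)
    grads[[paste0("l", l, "_fwd")]] <- gf$grads
    grads[[paste0("l", l, "_bwd")]] <- gb$grads
    dout <- gf$dx + rev_time(gb$dx)
  }
  list(dx = dout, grads = grads)
}
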