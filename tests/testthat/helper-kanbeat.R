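# Shared test utilities: independent reference implementations (written
# against the textbook definitions, not the package internals) and small
# fixture builders.

# recursive scalar Cox-de Boor, the brute-force oracle for bspline_basis
ref_bspline_one <- function(u, i, p, knots) {
  if (p == 0) {
    # half-open intervals, closed at the right end of the grid
    hi <- knots[length(knots)]
    if (u == hi && knots[i] < knots[i + 1] && knots[i + 1] == hi) return(1)
    return(as.numeric(u >= knots[i] && u < knots[i + 1]))
  }
  d1 <- knots[i + p] - knots[i]
  d2 <- knots[i + p + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (u - knots[i]) / d1 * ref_bspline_one(u, i, p - 1, knots) else 0
  t2 <- if (d2 > 0) (knots[i + p + 1] - u) / d2 * ref_bspline_one(u, i + 1, p - 1, knots) else 0
  t1 + t2
}

ref_bspline_basis <- function(u, G, k, range = c(-1, 1)) {
  knots <- c(rep(range[1], k), seq(range[1], range[2], length.out = G + 1),
             rep(range[2], k))
  t(vapply(u, function(ui) {
    vapply(seq_len(G + k), function(i) ref_bspline_one(ui, i, k, knots),
           numeric(1))
  }, numeric(G + k)))
}

# plain-R single-direction GRU recursion (the direct-recursion oracle)
ref_gru_dir <- function(p, x) {
  d <- dim(x)
  H <- nrow(p$Wz)
  h <- matrix(0, H, d[3])
  out <- array(0, c(H, d[2], d[3]))
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in seq_len(d[2])) {
    xt <- matrix(x[, t, ], d[1], d[3])
    z <- sig(p$Wz %*% xt + p$Uz %*% h + p$bz)
    r <- sig(p$Wr %*% xt + p$Ur %*% h + p$br)
    cst <- tanh(p$Wn %*% xt + r * (p$Un %*% h) + p$bn)
    h <- (1 - z) * cst + z * h
    out[, t, ] <- h
  }
  out
}

# small separable dataset, denoised + normalized + split
tiny_dataset <- function(counts = c(N = 60, S = 20, V = 20, F = 10, Q = 20),
                         segment_len = 64, separability = 5, seed = 11,
                         wavelet = NULL) {
  spec <- synth_spec(counts = counts, segment_len = segment_len,
                     separability = separability, seed = seed)
  prepare_dataset(synth_dataset(spec), wavelet = wavelet,
                  split = split_spec(seed = seed + 1))
}

# finite-difference gradient check of d(loss)/d(theta) for a sample of
# parameter leaves; returns the worst relative error. The model is first
# moved to a smooth point (positive BN shifts keep ReLU inputs off the kink
# and break max-pool ties) so central differences are valid.
fd_gradcheck <- function(model, x, y, leaves_per_group = 1L, h = 1e-5,
                         loss = "ce", focal = focal_config(), seed = 99) {
  params0 <- kanbeat:::model_params(model)
  fp <- kanbeat:::flatten_params(params0)
  withr_seed <- function(s, expr) kanbeat:::with_seed(s, expr)
  fp <- withr_seed(seed, {
    for (nm in names(fp)) {
      if (grepl("beta$", nm)) fp[[nm]] <- fp[[nm]] + runif(length(fp[[nm]]), 0.5, 1)
      if (grepl("\\.b$", nm)) fp[[nm]] <- fp[[nm]] + runif(length(fp[[nm]]), 0.05, 0.2)
    }
    fp
  })
  model <- kanbeat:::model_set_params(
    model, kanbeat:::relist_params(fp, params0))
  loss_fn <- function(m) {
    fw <- kanbeat:::model_forward(m, x, training = TRUE)
    kanbeat:::batch_loss_grad(fw$probs, y, loss, focal)$value
  }
  fw <- kanbeat:::model_forward(model, x, training = TRUE)
  lg <- kanbeat:::batch_loss_grad(fw$probs, y, loss, focal)
  grads <- kanbeat:::model_backward(model, lg$dlogits, fw$caches)
  fg <- kanbeat:::flatten_params(grads)
  worst <- 0
  idxs <- withr_seed(seed + 1, lapply(fp, function(v) {
    sample.int(length(v), min(leaves_per_group, length(v)))
  }))
  for (nm in names(fp)) {
    for (idx in idxs[[nm]]) {
      bump <- function(delta) {
        f2 <- fp
        f2[[nm]][idx] <- f2[[nm]][idx] + delta
        loss_fn(kanbeat:::model_set_params(
          model, kanbeat:::relist_params(f2, params0)))
      }
      num <- (bump(h) - bump(-h)) / (2 * h)
      ana <- fg[[nm]][idx]
      worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-6))
    }
  }
  worst
}

# fresh temporary directory for I/O tests
withr_tempdir <- function() {
  d <- tempfile("kanbeat-test-")
  dir.create(d)
  d
}
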