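test_that("a ConvBlock grows the sequence by one sample and preserves zeros", {
  cb <- kanbeat:::with_seed(1, kanbeat:::conv_block_layer(1, 2))
  x <- array(rnorm(1 * 300 * 2), c(1, 300, 2))
  out <- kanbeat:::layer_forward(cb, x, training = FALSE)$out
  expect_equal(dim(out), c(2, 301, 2)) # pool(k=2, s=1, p=1): L + 1
  # zero input, zero biases, inference batch-norm with unit scale/zero shift
  z <- kanbeat:::layer_forward(cb, array(0, c(1, 300, 2)), training = FALSE)$out
  expect_equal(max(abs(z)), 0)
})

test_that("multi-scale fusion with a one-hot weight equals the single-kernel path", {
  ms <- kanbeat:::with_seed(2, kanbeat:::multiscale_layer(2, 3, dropout = 0))
  ms$params$logits <- c(60, 0, 0, 0) # softmax weight 1 on kernel 3 (to 1e-26)
  x <- array(rnorm(2 * 40 * 3), c(2, 40, 3))
  out <- kanbeat:::layer_forward(ms, x, training = FALSE)$out
  # assemble the same graph keeping only the kernel-3 branch
  b3 <- kanbeat:::layer_forward(ms$sub$k3, x)$out
  bn <- kanbeat:::layer_forward(ms$sub$bn, b3)$out
  rl <- pmax(bn, 0)
  pl <- kanbeat:::layer_forward(ms$pool, rl)$out
  cb <- kanbeat:::layer_forward(ms$sub$conv2, x)$out
  sk <- kanbeat:::layer_forward(ms$sub$skip, x)$out
  sp <- kanbeat:::layer_forward(ms$skip_pool, sk)$out
  expect_equal(out, pl + cb + sp, tolerance = 1e-6)
})

test_that("tied multi-scale branches reduce to a single branch regardless of weights", {
  ms <- kanbeat:::with_seed(3, kanbeat:::multiscale_layer(2, 3, kernels = c(3, 3, 3, 3),
                                                          dropout = 0))
  for (nm in c("k3.1", "k3.2", "k3.3")) ms$sub[[nm]]$params <- ms$sub$k3$params
  x <- array(rnorm(2 * 30 * 2), c(2, 30, 2))
  out_equal <- kanbeat:::layer_forward(ms, x)$out # uniform weights (logits 0)
  ms$params$logits <- c(60, 0, 0, 0)              # one-hot on the first branch
  out_onehot <- kanbeat:::layer_forward(ms, x)$out
  expect_equal(out_equal, out_onehot, tolerance = 1e-6)
  expect_equal(sum(kanbeat:::softmax_vec(ms$params$logits)), 1)
  expect_error(kanbeat:::multiscale_layer(2, 3, kernels = c(3, 4, 21, 31)), "odd")
})

test_that("the MLPBlock partial branch leaves untouched channels intact", {
  mlp <- kanbeat:::with_seed(4, kanbeat:::mlp_block_layer(8, partial_ratio = 0.25))
  expect_equal(mlp$cp, 2L) # ceil(0.25 * 8)
  mlp$sub$conv2$params$W[] <- 0 # silence the main branch
  mlp$sub$conv2$params$b[] <- 0
  x <- array(rnorm(8 * 20 * 2), c(8, 20, 2))
  out <- kanbeat:::layer_forward(mlp, x)$out
  expect_identical(out[3:8, , ], x[3:8, , ]) # identity on the untouched tail
  expect_false(isTRUE(all.equal(out[1:2, , ], x[1:2, , ])))
  # partial_ratio = 1 makes the partial branch a full convolution
  full <- kanbeat:::with_seed(4, kanbeat:::mlp_block_layer(8, partial_ratio = 1))
  expect_equal(full$cp, 8L)
  expect_equal(dim(full$sub$pconv$params$W), c(8L, 24L))
})

test_that("partial-branch parameter count follows the ratio-squared law", {
  mlp <- kanbeat:::mlp_block_layer(8, kernel = 3, partial_ratio = 0.25)
  n_partial <- kanbeat:::n_param_scalars(kanbeat:::collect_params(mlp$sub$pconv))
  n_full <- kanbeat:::n_param_scalars(
    kanbeat:::collect_params(kanbeat:::conv1d_layer(8, 8, 3)))
  expect_equal(n_partial, 14L) # hand count: 2 * (2 * 3) + 2
  expect_equal(n_full, 200L)   # hand count: 8 * (8 * 3) + 8
  expect_equal(n_partial / n_full, 0.25^2, tolerance = 0.15)
})

test_that("the adaptive ECA kernel matches hand-computed sizes", {
  expect_equal(eca_kernel_size(64, 2, 1), 3L)  # |6/2 + 1/2| = 3.5 -> 3
  expect_equal(eca_kernel_size(256, 2, 1), 5L) # 4.5 -> 5
  expect_equal(eca_kernel_size(2, 2, 1), 1L)   # 1.0 -> 1
  expect_true(eca_kernel_size(128, 2, 1) %% 2 == 1)
})

test_that("ECA reweights channels multiplicatively within (0, 1)", {
  eca <- kanbeat:::with_seed(5, kanbeat:::eca_layer(8))
  x <- array(abs(rnorm(8 * 16 * 3)) + 0.1, c(8, 16, 3))
  eca$params$w[] <- 0
  expect_equal(kanbeat:::layer_forward(eca, x)$out, 0.5 * x) # sigmoid(0)
  eca$params$w <- rnorm(eca$k)
  out <- kanbeat:::layer_forward(eca, x)$out
  ratio <- out / x
  expect_true(all(ratio > 0 & ratio < 1))
  # permutation symmetry: identical channels receive identical weights
  xe <- array(rep(rnorm(16 * 2), each = 8), c(8, 16, 2))
  re <- kanbeat:::layer_forward(eca, xe)$out / xe
  expect_lt(max(apply(matrix(re, 8), 2, function(col) diff(range(col)))), 1e-12)
})

test_that("the BiGRU matches a direct plain-R recursion in both directions", {
  set.seed(6)
  layer <- kanbeat:::bigru_layer(3, 4, n_layers = 1)
  x <- array(rnorm(3 * 12 * 2), c(3, 12, 2))
  out <- kanbeat:::layer_forward(layer, x)$out
  expect_equal(dim(out), c(8L, 12L, 2L)) # width 2 * hidden
  fwd_ref <- ref_gru_dir(layer$params$l1_fwd, x)
  bwd_ref <- kanbeat:::rev_time(
    ref_gru_dir(layer$params$l1_bwd, kanbeat:::rev_time(x)))
  expect_equal(out[1:4, , ], fwd_ref, tolerance = 1e-6)
  expect_equal(out[5:8, , ], bwd_ref, tolerance = 1e-6)
  # zero input with zero biases stays at the zero state
  z <- kanbeat:::layer_forward(layer, array(0, c(3, 12, 2)))$out
  expect_equal(max(abs(z)), 0)
})

test_that("B-spline bases satisfy partition of unity and match brute-force Cox-de Boor", {
  set.seed(7)
  u <- runif(1000, -1, 1)
  B <- bspline_basis(u, G = 5, k = 3)
  expect_equal(dim(B), c(1000L, 8L)) # G + k basis functions
  expect_true(all(B >= 0))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  expect_lt(max(abs(B - ref_bspline_basis(u, 5, 3))), 1e-12)
  # order 0: exactly one indicator active per point
  B0 <- bspline_basis(u, G = 4, k = 0)
  expect_true(all(rowSums(B0 == 1) == 1 & rowSums(B0) == 1))
  # derivative check against central differences at interior points
  ui <- runif(200, -0.9, 0.9)
  d <- bspline_basis(ui, 5, 3, derivative = TRUE)
  h <- 1e-6
  num <- (bspline_basis(ui + h, 5, 3) - bspline_basis(ui - h, 5, 3)) / (2 * h)
  expect_lt(max(abs(d$dB - num)), 1e-5)
})

test_that("KAN edges evaluate w_b silu + w_s spline sums exactly", {
  layer <- kanbeat:::with_seed(8, kanbeat:::kan_layer(3, 2, G = 5, k = 3))
  x <- matrix(runif(3 * 7, -1, 1), 3)
  # spline term off: nodes sum silu of inputs
  l0 <- layer
  l0$params$coef[] <- 0
  l0$params$wb[] <- 1
  l0$params$bias[] <- 0
  out <- kanbeat:::layer_forward(l0, x)$out
  expected <- matrix(rep(colSums(kanbeat:::silu(x)), each = 2), 2)
  expect_equal(out, expected, tolerance = 1e-10)
  # 1 -> 1 layer with known coefficients against a hand-rolled evaluation
  l1 <- kanbeat:::kan_layer(1, 1, G = 5, k = 3)
  coef <- seq(-0.7, 0.7, length.out = 8)
  l1$params$coef[1, 1, ] <- coef
  l1$params$wb[] <- 0.3; l1$params$ws[] <- 1.7; l1$params$bias[] <- 0.1
  u <- matrix(runif(100, -1, 1), 1)
  out1 <- kanbeat:::layer_forward(l1, u)$out
  hand <- 0.1 + 0.3 * kanbeat:::silu(u) +
    1.7 * as.numeric(bspline_basis(as.vector(u), 5, 3) %*% coef)
  expect_equal(as.numeric(out1), as.numeric(hand), tolerance = 1e-10)
})

test_that("spline coefficients fitted by least squares approximate sin(u)", {
  G <- 10; k <- 3
  grid <- seq(-1, 1, length.out = 201)
  Bg <- bspline_basis(grid, G, k)
  coef <- qr.solve(Bg, sin(grid))
  fine <- seq(-1, 1, length.out = 2001)
  approx <- as.numeric(bspline_basis(fine, G, k) %*% coef)
  expect_lt(max(abs(approx - sin(fine))), 0.01)
})

test_that("spline exports round-trip and rebuild identical layers", {
  model <- build_model(tiny_model_config(seed = 12))
  exp1 <- kan_spline_export(model)
  expect_named(exp1, c("kan1", "kan2"))
  expect_identical(unserialize(serialize(exp1, NULL)), exp1)
  # zero-coefficient edge exports the pure silu curve
  rec <- exp1$kan2
  lz <- kanbeat:::kan_layer(rec$in_dim, rec$out_dim, rec$G, rec$k, rec$range)
  lz$params$coef[] <- 0
  lz$params$wb[] <- 0.8
  cz <- kanbeat:::kan_edge_curve(lz, 1, 1, rec$u)
  expect_equal(cz, 0.8 * kanbeat:::silu(rec$u), tolerance = 1e-12)
  # rebuild from export: identical forward outputs
  rebuilt <- kan_layer_from_export(rec)
  x <- matrix(runif(rec$in_dim * 5, -1, 1), rec$in_dim)
  expect_equal(kanbeat:::layer_forward(rebuilt, x)$out,
               kanbeat:::layer_forward(model$layers$kan2, x)$out,
               tolerance = 1e-12)
})

test_that("all ablation variants build, run, and produce softmax rows", {
  x <- matrix(rnorm(2 * 64), 2)
  for (v in c("full", "single_scale_3", "single_scale_11", "single_scale_21",
              "single_scale_31", "no_attention", "no_bigru", "no_kan")) {
    m <- build_model(tiny_model_config(seed = 13), v)
    p <- predict_proba(m, x)
    expect_equal(dim(p), c(2L, 5L))
    expect_true(all(p >= 0))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  }
  expect_error(build_model(tiny_model_config(), "no_such"), "valid variants")
})

test_that("identical config and seed give identical initial parameters", {
  cfg <- tiny_model_config(seed = 14)
  p1 <- kanbeat:::flatten_params(kanbeat:::model_params(build_model(cfg)))
  p2 <- kanbeat:::flatten_params(kanbeat:::model_params(build_model(cfg)))
  expect_identical(p1, p2)
  cfg2 <- tiny_model_config(seed = 15)
  p3 <- kanbeat:::flatten_params(kanbeat:::model_params(build_model(cfg2)))
  expect_false(identical(p1, p3))
})

test_that("shape contracts hold across input lengths", {
  for (L in c(64, 80, 100)) {
    m <- build_model(tiny_model_config(input_len = L, seed = 16))
    p <- predict_proba(m, matrix(rnorm(3 * L), 3))
    expect_equal(dim(p), c(3L, 5L))
  }
})

test_that("parameter counting matches hand counts", {
  conv <- kanbeat:::conv1d_layer(1, 2, 3)
  expect_equal(kanbeat:::n_param_scalars(kanbeat:::collect_params(conv)), 8L)
  kan <- kanbeat:::kan_layer(2, 3, G = 5, k = 3)
  # 3*2*(5+3) spline coefficients + 2 * (3*2) base/spline weights + 3 biases
  expect_equal(kanbeat:::n_param_scalars(kanbeat:::collect_params(kan)), 63L)
})

test_that("analytic gradients match finite differences in every block type", {
  cfg <- tiny_model_config(seed = 17)
  cfg$dropout <- 0
  model <- build_model(cfg)
  set.seed(18)
  x <- array(rnorm(1 * 64 * 3), c(1, 64, 3))
  y <- c(1L, 4L, 5L)
  expect_lt(fd_gradcheck(model, x, y, leaves_per_group = 1), 1e-3)
  expect_lt(fd_gradcheck(model, x, y, leaves_per_group = 1, loss = "focal",
                         focal = focal_config(gamma = 2, alpha = c(1, 0.5, 1, 0.25, 1))),
            1e-3)
  # the linear head of the no_kan variant
  m2 <- build_model(cfg, "no_kan")
  expect_lt(fd_gradcheck(m2, x, y, leaves_per_group = 1), 1e-3)
})
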