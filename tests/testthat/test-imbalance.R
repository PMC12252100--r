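test_that("cross-entropy matches -log(p_t) and validates its input", {
  expect_equal(cross_entropy(c(1, 0, 0, 0, 0), "N"), 0)
  expect_equal(cross_entropy(c(0.5, 0.5, 0, 0, 0), "N"), 0.6931, tolerance = 1e-4)
  probs <- matrix(c(0.7, 0.1, 0.1, 0.05, 0.05,
                    0.2, 0.5, 0.1, 0.1, 0.1), 2, byrow = TRUE)
  expect_equal(cross_entropy(probs, c("N", "S")),
               mean(-log(c(0.7, 0.5))))
  expect_error(cross_entropy(c(0.5, 0.2, 0, 0, 0), "N"), "sum to 1")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches Eq.-style hand values", {
  expect_equal(focal_loss(c(1, 0, 0, 0, 0), "N", focal_config(gamma = 2)), 0)
  expect_equal(focal_loss(c(0.5, 0.5, 0, 0, 0), "N", focal_config(gamma = 2)),
               0.25 * 0.6931, tolerance = 1e-4)
  set.seed(4)
  for (rep in 1:20) {
    p <- t(apply(matrix(rexp(25), 5), 1, function(r) r / sum(r)))
    y <- sample(c("N", "S", "V", "F", "Q"), 5, replace = TRUE)
    expect_equal(focal_loss(p, y, focal_config(gamma = 0, alpha = rep(1, 5))),
                 cross_entropy(p, y), tolerance = 1e-10)
  }
  # per-class alpha scales each sample's contribution
  a <- c(0.25, 0.5, 0.75, 1, 0.1)
  p <- matrix(0.2, 2, 5)
  expect_equal(focal_loss(p, c("N", "Q"), focal_config(gamma = 0, alpha = a)),
               mean(a[c(1, 5)] * -log(0.2)), tolerance = 1e-10)
  expect_error(focal_config(gamma = -1), "gamma")
})

test_that("focal loss decreases strictly in gamma for imperfect predictions", {
  p <- c(0.6, 0.1, 0.1, 0.1, 0.1)
  losses <- vapply(c(0, 1, 2, 5), function(g) {
    focal_loss(p, "N", focal_config(gamma = g))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("SMOTE targets implement equalize-to-majority, including the published counts", {
  counts <- c(N = 54171, S = 1807, V = 4348, F = 483, Q = 4858)
  targets <- setNames(rep(max(counts), 5), names(counts))
  expect_equal(sum(targets), 270855)
  # the same rule exercised end-to-end on a small imbalanced set
  set.seed(1)
  feats <- matrix(rnorm(130 * 4), 130)
  labels <- rep(c("N", "S", "V", "F", "Q"), c(100, 10, 8, 5, 7))
  out <- smote_oversample(feats, labels, smote_config(k_neighbors = 3, seed = 2))
  expect_equal(as.vector(table(out$labels)), rep(100L, 5))
})

test_that("SMOTE synthetics are convex combinations and originals are untouched", {
  set.seed(5)
  feats <- rbind(matrix(rnorm(40, 0, 1), 20), matrix(rnorm(12, 5, 1), 6))
  labels <- rep(c("N", "V"), c(20, 6))
  out <- smote_oversample(feats, labels, smote_config(k_neighbors = 3, seed = 7))
  expect_identical(out$features[1:26, ], feats)          # verbatim, same order
  expect_identical(as.character(out$labels[1:26]), labels)
  syn <- out$features[out$synthetic, , drop = FALSE]
  expect_true(all(out$labels[out$synthetic] == "V"))
  hull_lo <- apply(feats[21:26, ], 2, min)
  hull_hi <- apply(feats[21:26, ], 2, max)
  expect_true(all(t(syn) >= hull_lo - 1e-12 & t(syn) <= hull_hi + 1e-12))
})

test_that("a two-point class interpolates exactly on the connecting segment", {
  a <- c(0, 0, 0); b <- c(1, 2, 3)
  feats <- rbind(matrix(rnorm(9), 3), a, b)
  labels <- c("N", "N", "N", "F", "F")
  out <- smote_oversample(feats, labels,
                          smote_config(k_neighbors = 1, seed = 3,
                                       target_counts = c(F = 3)))
  syn <- out$features[out$synthetic, ]
  u <- syn[1] / b[1]
  expect_equal(unname(syn), u * b, tolerance = 1e-10) # on segment [a, b]
  expect_gte(u, 0); expect_lte(u, 1)
})

test_that("SMOTE guards: singleton classes error, oversized k clamps with warning", {
  feats <- matrix(rnorm(24), 6)
  expect_error(
    smote_oversample(feats, c("N", "N", "N", "N", "N", "F"), smote_config()),
    "class F")
  expect_warning(
    smote_oversample(matrix(rnorm(32), 8), rep(c("N", "S"), c(5, 3)),
                     smote_config(k_neighbors = 5, seed = 1)),
    "clamped")
  expect_error(
    smote_oversample(feats, rep(c("N", "S"), c(4, 2)),
                     smote_config(target_counts = c(N = 2), seed = 1)),
    "below current count")
})

test_that("SMOTE can only reach the training fold of a split dataset", {
  ds <- tiny_dataset(counts = c(N = 60, S = 10, V = 10, F = 10, Q = 10), seed = 23)
  expect_error(apply_smote(beat_dataset(ds$features, ds$labels)), "split")
  aug <- apply_smote(ds, smote_config(k_neighbors = 2, seed = 5))
  n0 <- n_beats(ds)
  expect_identical(aug$features[seq_len(n0), ], ds$features)
  expect_identical(aug$split[seq_len(n0)], ds$split)
  added <- seq.int(n0 + 1L, n_beats(aug))
  expect_true(all(aug$split[added] == "train"))
  expect_true(all(aug$record_id[added] == "smote"))
  tr <- table(aug$labels[aug$split == "train"])
  expect_true(all(tr == max(tr)))
})
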