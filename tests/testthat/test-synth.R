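test_that("a beat with silent waves and zero noise is the zero vector", {
  tpl <- beat_template("N", segment_len = 120)
  tpl$wave_params[, "amp"] <- 0
  silent <- noise_spec(baseline_amp = 0, powerline_amp = 0, white_sd = 0)
  expect_identical(synth_beat(tpl, silent, seed = 4), rep(0, 120))
})

test_that("beat generation is bit-identical under a repeated seed", {
  tpl <- beat_template("V")
  b1 <- synth_beat(tpl, noise_spec(), seed = 123)
  b2 <- synth_beat(tpl, noise_spec(), seed = 123)
  expect_identical(b1, b2)
  expect_false(identical(b1, synth_beat(tpl, noise_spec(), seed = 124)))
})

test_that("white-noise residuals match the requested standard deviation", {
  tpl <- beat_template("N")
  nz <- noise_spec(baseline_amp = 0, powerline_amp = 0, white_sd = 0.05)
  resid <- vapply(1:1000, function(s) {
    b <- synth_beat(tpl, nz, seed = s, components = TRUE)
    b$beat - b$clean
  }, numeric(tpl$segment_len))
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.10)
})

test_that("wave centres outside the window raise an error naming the wave", {
  tpl <- beat_template("N", segment_len = 300)
  tpl$wave_params["T", "centre"] <- 400
  expect_error(synth_beat(tpl, noise_spec(), 1), "wave T")
})

test_that("a jitter-free record places R peaks on an arithmetic progression", {
  tpls <- default_templates(segment_len = 300)
  for (nm in names(tpls)) {
    tpls[[nm]]$rr_mean <- 360
    tpls[[nm]]$rr_jitter_sd <- 0
  }
  spec <- synth_spec(counts = c(N = 10, S = 0, V = 0, F = 0, Q = 0), seed = 5)
  rec <- synth_record(spec, tpls)
  expect_equal(diff(rec$ann$r_index), rep(360L, 9))
})

test_that("records carry one annotation per beat with class-consistent symbols", {
  spec <- synth_spec(counts = c(N = 2, S = 1, V = 1, F = 0, Q = 1),
                     segment_len = 120, seed = 7)
  rec <- synth_record(spec)
  expect_equal(nrow(rec$ann), 5L)
  expect_true(all(diff(rec$ann$r_index) > 0))
  for (i in seq_len(nrow(rec$ann))) {
    expect_identical(unname(map_symbol(rec$ann$symbol[i])), rec$ann$aami[i])
  }
  expect_error(synth_record(spec, templates = list()), "template")
})

test_that("datasets honour per-class counts exactly and reproduce under a seed", {
  counts <- c(N = 100, S = 10, V = 20, F = 5, Q = 20)
  spec <- synth_spec(counts = counts, segment_len = 80, seed = 21)
  ds <- synth_dataset(spec)
  expect_equal(n_beats(ds), 155L)
  expect_equal(as.vector(table(ds$labels)), unname(counts[c("N","S","V","F","Q")]))
  ds2 <- synth_dataset(spec)
  expect_identical(ds$features, ds2$features)
  expect_error(synth_dataset(synth_spec(counts = c(N = 0, S = 0, V = 0, F = 0, Q = 0))),
               "count")
})

nearest_centroid_accuracy <- function(separability, n_per_class, seed) {
  spec <- synth_spec(counts = setNames(rep(n_per_class, 5), c("N","S","V","F","Q")),
                     segment_len = 120, separability = separability, seed = seed)
  ds <- synth_dataset(spec)
  idx <- seq_len(n_beats(ds))
  train <- idx %% 2 == 0
  cents <- sapply(levels(ds$labels), function(cl) {
    colMeans(ds$features[train & ds$labels == cl, , drop = FALSE])
  })
  d2 <- sapply(seq_len(ncol(cents)), function(j) {
    rowSums(sweep(ds$features[!train, , drop = FALSE], 2, cents[, j])^2)
  })
  pred <- levels(ds$labels)[apply(d2, 1, which.min)]
  mean(pred == as.character(ds$labels[!train]))
}

test_that("high separability yields near-perfect nearest-centroid accuracy", {
  expect_gt(nearest_centroid_accuracy(5, 60, seed = 31), 0.95)
})

test_that("zero separability collapses classes to chance level", {
  acc <- nearest_centroid_accuracy(0, 400, seed = 32) # 1000 held-out beats
  expect_lt(abs(acc - 0.2), 0.03)
})

test_that("output variance grows monotonically with each noise amplitude", {
  tpl <- beat_template("N", segment_len = 100)
  mean_var <- function(nz) {
    mean(vapply(1:100, function(s) var(synth_beat(tpl, nz, seed = s)), numeric(1)))
  }
  for (field in c("white_sd", "baseline_amp", "powerline_amp")) {
    vars <- vapply(c(0, 0.05, 0.15), function(a) {
      args <- list(baseline_amp = 0, powerline_amp = 0, white_sd = 0)
      args[[field]] <- a
      mean_var(do.call(noise_spec, args))
    }, numeric(1))
    expect_true(all(diff(vars) > 0), label = paste("monotone in", field))
  }
})
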