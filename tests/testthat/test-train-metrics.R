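test_that("per-class metrics match the hand-evaluated one-vs-rest example", {
  # class S: TP = 8, FN = 2, FP = 1, TN = 9 (20 beats total)
  cm <- confusion_matrix(rep(c("N", "S"), c(10, 10)),
                         c(rep("N", 9), "S", rep("S", 8), "N", "N"))
  s <- per_class_metrics(cm)[2, ]
  expect_equal(s$recall, 0.8000, tolerance = 1e-6)
  expect_equal(s$precision, 0.888889, tolerance = 1e-6)
  expect_equal(s$f1, 0.842105, tolerance = 1e-6)
  expect_equal(s$specificity, 0.9000, tolerance = 1e-6)
  expect_equal(s$accuracy, s$recall) # table convention
})

test_that("a diagonal confusion matrix yields perfect metrics", {
  true <- rep(c("N", "S", "V", "F", "Q"), 2)
  cm <- confusion_matrix(true, true)
  pc <- per_class_metrics(cm)
  expect_true(all(abs(as.matrix(pc[, c("accuracy", "f1", "recall",
                                       "precision", "specificity")]) - 1) < 1e-12))
})

test_that("confusion matrices conserve counts", {
  set.seed(20)
  true <- sample(c("N", "S", "V", "F", "Q"), 200, replace = TRUE,
                 prob = c(0.6, 0.1, 0.15, 0.05, 0.1))
  pred <- sample(c("N", "S", "V", "F", "Q"), 200, replace = TRUE)
  cm <- confusion_matrix(true, pred)
  expect_equal(sum(cm), 200)
  expect_equal(as.vector(rowSums(cm)), as.vector(table(factor(true, c("N","S","V","F","Q")))))
  pc <- per_class_metrics(cm)
  expect_equal(pc$support, as.vector(rowSums(cm)))
  # a constant-N predictor puts every beat in column N
  cmN <- confusion_matrix(rep(c("N", "S"), c(5, 5)), rep("N", 10))
  expect_equal(as.vector(cmN[, "N"]), as.vector(rowSums(cmN)))
  expect_equal(sum(cmN[, -1]), 0)
})

test_that("micro-average recall equals overall accuracy on random matrices", {
  set.seed(21)
  for (rep in 1:25) {
    cm <- matrix(rpois(25, 8), 5, dimnames = list(true = kanbeat:::AAMI_CLASSES,
                                                  pred = kanbeat:::AAMI_CLASSES))
    class(cm) <- c("confusion_matrix", "matrix")
    pc <- per_class_metrics(cm)
    micro <- sum(vapply(1:5, function(i) kanbeat:::ovr_counts(cm, i)["tp"],
                        numeric(1))) / sum(cm)
    expect_equal(micro, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("zero-support classes report zeros with a flag instead of NaN", {
  cm <- confusion_matrix(rep("N", 10), rep("N", 10))
  pc <- per_class_metrics(cm)
  expect_true(all(pc$zero_denominator[2:5]))
  expect_false(any(is.nan(as.matrix(pc[, 2:6]))))
  expect_equal(pc$recall[2:5], rep(0, 4))
})

test_that("aggregate rows are macro means except overall accuracy, rounded half-up", {
  rep_df <- data.frame(f1 = c(0.9960, 0.9292, 0.9806, 0.8903, 0.9933),
                       recall = c(0.9962, 0.9208, 0.9826, 0.9020, 0.9910),
                       precision = c(0.9958, 0.9378, 0.9785, 0.8790, 0.9955),
                       specificity = c(0.9798, 0.9982, 0.9985, 0.9991, 0.9997))
  agg <- aggregate_metrics(rep_df)
  expect_equal(agg$f1, 0.9579)
  expect_equal(agg$recall, 0.9585)
  expect_equal(agg$precision, 0.9573)
  expect_equal(agg$specificity, 0.9951)
  same <- data.frame(f1 = rep(0.9, 5), recall = rep(0.8, 5),
                     precision = rep(0.7, 5), specificity = rep(0.6, 5))
  a2 <- aggregate_metrics(same)
  expect_equal(unlist(a2[, c("f1", "recall", "precision", "specificity")]),
               c(f1 = 0.9, recall = 0.8, precision = 0.7, specificity = 0.6))
  expect_equal(round_half_up(0.97105), 0.9711) # half goes up, not to even
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("training reduces the loss on a separable dataset and checkpoints the best epoch", {
  ds <- tiny_dataset(counts = c(N = 150, S = 50, V = 50, F = 25, Q = 25),
                     separability = 5, seed = 41)
  cfg <- train_config(batch_size = 64, learning_rate = 5e-3, epochs = 5, seed = 7)
  fit <- train_model(build_model(tiny_model_config(seed = 7)), ds, cfg)
  expect_s3_class(fit, "train_result")
  expect_equal(nrow(fit$history), 5L)
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  # returned checkpoint reproduces the best validation macro-F1 in history
  best <- max(fit$history$val_macro_f1)
  cm_val <- evaluate_model(fit$model, dataset_split(ds, "val"))
  expect_equal(macro_f1(cm_val), best, tolerance = 1e-12)
  expect_equal(fit$history$val_macro_f1[fit$best_epoch], best)
})

test_that("training is deterministic and a zero learning rate freezes parameters", {
  ds <- tiny_dataset(counts = c(N = 40, S = 10, V = 10, F = 8, Q = 10), seed = 43)
  cfg <- train_config(batch_size = 32, learning_rate = 3e-3, epochs = 2, seed = 5)
  f1 <- train_model(build_model(tiny_model_config(seed = 3)), ds, cfg)
  f2 <- train_model(build_model(tiny_model_config(seed = 3)), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(kanbeat:::model_params(f1$model), kanbeat:::model_params(f2$model))

  cfg0 <- train_config(batch_size = 32, learning_rate = 0, epochs = 1, seed = 5,
                       checkpoint_policy = "last")
  m0 <- build_model(tiny_model_config(seed = 3))
  fit0 <- train_model(m0, ds, cfg0)
  expect_identical(kanbeat:::model_params(fit0$model), kanbeat:::model_params(m0))
  # learnable fusion weights remain a probability vector after training
  wts <- kanbeat:::softmax_vec(f1$model$layers$multiscale$params$logits)
  expect_equal(sum(wts), 1, tolerance = 1e-12)
  expect_error(train_model(m0, tiny_dataset()[0], cfg0), "split|empty")
})

test_that("evaluation fills a confusion matrix whose total is the split size", {
  ds <- tiny_dataset(counts = c(N = 30, S = 10, V = 10, F = 6, Q = 10), seed = 44)
  m <- build_model(tiny_model_config(seed = 2))
  te <- dataset_split(ds, "test")
  cm <- evaluate_model(m, te)
  expect_equal(sum(cm), n_beats(te))
  expect_equal(as.vector(rowSums(cm)),
               as.vector(table(te$labels)))
})

test_that("argmax ties break toward the lower class index", {
  # craft a model-free check through the same argmax rule used in predict
  p <- matrix(c(0.3, 0.3, 0.2, 0.1, 0.1), 1)
  expect_equal(which.max(p[1, ]), 1L)
})

test_that("ablation and imbalance drivers emit one labelled row per run", {
  ds <- tiny_dataset(counts = c(N = 60, S = 10, V = 12, F = 6, Q = 12), seed = 45)
  tc <- train_config(batch_size = 32, learning_rate = 3e-3, epochs = 1, seed = 1)
  tab <- run_ablation(ds, c("full", "no_bigru"),
                      tiny_model_config(), tc, seeds = 1)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("variant", "seed", "accuracy", "f1", "recall", "precision",
                    "specificity") %in% names(tab)))
  tab2 <- run_ablation(ds, c("full", "no_bigru"), tiny_model_config(), tc, seeds = 1)
  expect_identical(tab, tab2)
  expect_error(run_ablation(ds, "bogus"), "unknown variant")

  cmp <- compare_imbalance(ds, c("none", "focal", "smote"),
                           tiny_model_config(), tc, seeds = 1,
                           smote = smote_config(k_neighbors = 3))
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$strategy, c("none", "focal", "smote"))
  expect_true(all(paste0("recall_", kanbeat:::AAMI_CLASSES) %in% names(cmp)))
})
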