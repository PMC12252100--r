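# Benchmark drivers: the ablation grid and the imbalance-strategy
# comparison, both returning one metrics row per configuration per seed.

agg_row <- function(cm) {
  rep <- per_class_metrics(cm)
  agg <- aggregate_metrics(rep, cm)
  cbind(agg[, c("accuracy", "f1", "recall", "precision", "specificity")],
        stats::setNames(as.data.frame(t(round_half_up(rep$recall, 4))),
                        paste0("recall_", AAMI_CLASSES)))
}

#' Run the ablation grid
#'
#' Trains each requested variant with an identical training configuration
#' and seed list and evaluates it on the test split, one row per
#' (variant, seed).
#'
#' @param ds a split [beat_dataset()].
#' @param variants subset of the eight ablation configurations (see
#'   [build_model()]).
#' @param model_cfg a [model_config()] (`seed` is overridden per run).
#' @param train_cfg a [train_config()] (`seed` is overridden per run).
#' @param seeds integer vector of run seeds.
#' @return data.frame with variant, seed, aggregate metrics and per-class
#'   recalls.
#' @export
run_ablation <- function(ds, variants = MODEL_VARIANTS,
                         model_cfg = tiny_model_config(),
                         train_cfg = train_config(epochs = 5, loss = "focal"),
                         seeds = 1:5) {
  bad <- setdiff(variants, MODEL_VARIANTS)
  if (length(bad)) stopf("unknown variant(s): %s", paste(bad, collapse = ", "))
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      mc <- model_cfg; mc$seed <- s
      tc <- train_cfg; tc$seed <- s
      fit <- train_model(build_model(mc, v), ds, tc)
      cm <- evaluate_model(fit$model, dataset_split(ds, "test"))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variant = v, seed = s), agg_row(cm))
    }
  }
  do.call(rbind, rows)
}

#' Compare class-imbalance strategies
#'
#' Trains the same model under `none` (plain cross-entropy), `focal`
#' (focal loss), and `smote` (SMOTE-balanced training fold, cross-entropy),
#' sharing the model configuration and seed per run. SMOTE touches the
#' training fold only.
#'
#' @param ds a split, imbalanced [beat_dataset()].
#' @param strategies subset of `c("none", "focal", "smote")`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()] (loss field is set per strategy).
#' @param seeds integer vector of run seeds.
#' @param focal a [focal_config()].
#' @param smote a [smote_config()].
#' @return data.frame with strategy, seed, aggregate metrics and per-class
#'   recalls.
#' @export
compare_imbalance <- function(ds, strategies = c("none", "focal", "smote"),
                              model_cfg = tiny_model_config(),
                              train_cfg = train_config(epochs = 5),
                              seeds = 1:5,
                              focal = focal_config(),
                              smote = smote_config()) {
  strategies <- match.arg(strategies, c("none", "focal", "smote"),
                          several.ok = TRUE)
  rows <- list()
  for (strat in strategies) {
    for (s in seeds) {
      mc <- model_cfg; mc$seed <- s
      tc <- train_cfg; tc$seed <- s
      tc$loss <- if (strat == "focal") "focal" else "ce"
      tc$focal <- focal
      ds_run <- ds
      if (strat == "smote") {
        sm <- smote; sm$seed <- s
        ds_run <- apply_smote(ds, sm)
      }
      fit <- train_model(build_model(mc), ds_run, tc)
      cm <- evaluate_model(fit$model, dataset_split(ds, "test"))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(strategy = strat, seed = s), agg_row(cm))
    }
  }
  do.call(rbind, rows)
}

#' Synthetic imbalanced benchmark dataset
#'
#' The desk-scale study conditions used by the ablation and imbalance
#' comparisons: five classes with counts proportional to the published
#' training distribution (54,171 / 1,807 / 4,348 / 483 / 4,858) scaled to
#' about 3,000 beats, 64-sample QRS-centred windows at 360 Hz, default
#' noise, full class separability, denoised and split 60/20/20.
#'
#' @param seed integer seed for generation and splitting.
#' @param n_total approximate total beat count.
#' @param segment_len beat window length in samples.
#' @return a preprocessed, split [beat_dataset()].
#' @export
benchmark_dataset <- function(seed = 1, n_total = 3000, segment_len = 64) {
  counts <- round(n_total * c(N = 54171, S = 1807, V = 4348,
                              F = 483, Q = 4858) / 65667)
  counts[counts < 1] <- 1
  seeds <- derive_seeds(seed, 2)
  spec <- synth_spec(counts = counts, segment_len = segment_len,
                     separability = 1, seed = seeds[1])
  prepare_dataset(synth_dataset(spec),
                  wavelet = wavelet_spec(level = min(3, dwt_max_level(segment_len))),
                  split = split_spec(seed = seeds[2]))
}
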