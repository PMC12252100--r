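# Class-imbalance remedies: multi-class focal loss (with per-class alpha)
# and from-scratch SMOTE with exact brute-force nearest neighbours, applied
# only to training folds.

PROB_EPS <- 1e-12

#' Focal loss configuration
#'
#' @param gamma focusing exponent, >= 0. `gamma = 0` with unit alpha reduces
#'   the loss to plain cross-entropy.
#' @param alpha per-class weight vector in `[0, 1]` (recycled to 5); all 1
#'   means unweighted.
#' @return an object of class `focal_config`.
#' @export
focal_config <- function(gamma = 2.0, alpha = rep(1, 5)) {
  if (gamma < 0) stopf("gamma must be >= 0")
  alpha <- rep_len(alpha, 5L)
  if (any(alpha < 0 | alpha > 1)) stopf("alpha entries must lie in [0, 1]")
  structure(list(gamma = gamma, alpha = alpha), class = "focal_config")
}

#' SMOTE configuration
#'
#' @param k_neighbors number of same-class nearest neighbours to interpolate
#'   towards (clamped with a warning when a class is smaller than `k + 1`).
#' @param target_counts `"equalize"` (bring every class up to the majority
#'   count) or a named class->count vector; targets below current counts are
#'   errors.
#' @param seed integer seed.
#' @return an object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_counts = "equalize", seed = 1) {
  if (k_neighbors < 1) stopf("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_counts = target_counts, seed = as.integer(seed)),
            class = "smote_config")
}

check_prob_rows <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    stopf("probability rows must sum to 1 (worst deviation %.3g)",
          max(abs(sums - 1)))
  }
  if (any(probs < -1e-12)) stopf("probabilities must be non-negative")
  probs
}

true_class_prob <- function(probs, true_class) {
  probs <- check_prob_rows(probs)
  idx <- if (is.numeric(true_class)) as.integer(true_class)
         else match(as.character(true_class), AAMI_CLASSES)
  if (anyNA(idx) || any(idx < 1L | idx > ncol(probs))) {
    stopf("true_class out of range")
  }
  list(pt = pmax(probs[cbind(seq_len(nrow(probs)), idx)], PROB_EPS), idx = idx)
}

#' Cross-entropy loss on predicted probabilities
#'
#' `-log(p_t)` per sample, where `p_t` is the predicted probability of the
#' true class (clamped at 1e-12); the batch value is the mean.
#'
#' @param probs numeric vector (one sample) or matrix (samples x classes) of
#'   per-class probabilities, each row summing to 1.
#' @param true_class class labels (AAMI characters or 1-based indices).
#' @param reduce if `FALSE`, return per-sample losses.
#' @return loss in nats.
#' @export
cross_entropy <- function(probs, true_class, reduce = TRUE) {
  pt <- true_class_prob(probs, true_class)$pt
  loss <- -log(pt)
  if (reduce) mean(loss) else loss
}

#' Focal loss on predicted probabilities
#'
#' `alpha_y * (1 - p_t)^gamma * (-log p_t)` per sample, batch mean. With
#' `gamma = 0` and unit alpha this equals [cross_entropy()].
#'
#' @inheritParams cross_entropy
#' @param cfg a [focal_config()].
#' @return loss in nats.
#' @export
focal_loss <- function(probs, true_class, cfg = focal_config(), reduce = TRUE) {
  tc <- true_class_prob(probs, true_class)
  loss <- cfg$alpha[tc$idx] * (1 - tc$pt)^cfg$gamma * (-log(tc$pt))
  if (reduce) mean(loss) else loss
}

# d(mean loss)/d(p_t) per sample, used by the training loop; returns a list
# with the per-sample derivative and the true-class column indices
loss_grad_pt <- function(probs, true_class, loss = c("ce", "focal"),
                         cfg = focal_config()) {
  loss <- match.arg(loss)
  tc <- true_class_prob(probs, true_class)
  pt <- tc$pt
  g <- if (loss == "ce") {
    -1 / pt
  } else {
    a <- cfg$alpha[tc$idx]
    gam <- cfg$gamma
    omp <- 1 - pt
    # derivative of -a (1-p)^g log p  w.r.t. p
    a * (ifelse(gam == 0, 0, gam * omp^(pmax(gam - 1, 0)) * log(pt)) - omp^gam / pt)
  }
  list(dpt = g / nrow(check_prob_rows(probs)), idx = tc$idx)
}

#' SMOTE oversampling of minority classes
#'
#' For each synthetic point, picks a seed row of the minority class, one of
#' its `k` nearest same-class neighbours (exact Euclidean distances), and a
#' uniform weight `u` in `[0, 1]`, and emits `x + u * (x_nn - x)`. Original
#' rows are preserved verbatim and in order; synthetic rows are appended.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels class labels aligned with `features`.
#' @param cfg a [smote_config()].
#' @return `list(features, labels, synthetic)` where `synthetic` flags the
#'   appended rows.
#' @export
smote_oversample <- function(features, labels, cfg = smote_config()) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = AAMI_CLASSES)
  counts <- table(labels)
  targets <- if (identical(cfg$target_counts, "equalize") ||
                 identical(cfg$target_counts, "equalize-to-majority")) {
    stats::setNames(rep(max(counts), 5L), AAMI_CLASSES)
  } else {
    tc <- cfg$target_counts[AAMI_CLASSES]
    tc[is.na(tc)] <- 0
    stats::setNames(pmax(as.numeric(tc), as.numeric(counts)), AAMI_CLASSES)
  }
  if (!identical(cfg$target_counts, "equalize") &&
      !identical(cfg$target_counts, "equalize-to-majority")) {
    low <- !is.na(cfg$target_counts[AAMI_CLASSES]) &
      cfg$target_counts[AAMI_CLASSES] < as.numeric(counts)
    if (any(low)) {
      stopf("target count below current count for class(es): %s",
            paste(AAMI_CLASSES[low], collapse = ", "))
    }
  }
  new_feats <- list()
  new_labels <- character(0)
  with_seed(cfg$seed, {
    for (cl in AAMI_CLASSES) {
      if (counts[[cl]] == 0) next # absent classes have nothing to interpolate
      need <- targets[[cl]] - counts[[cl]]
      if (need <= 0) next
      rows <- which(labels == cl)
      if (length(rows) < 2L) {
        stopf("class %s has %d sample(s); SMOTE needs at least 2", cl, length(rows))
      }
      k <- cfg$k_neighbors
      if (k > length(rows) - 1L) {
        warnf("class %s: k_neighbors clamped from %d to %d", cl, k, length(rows) - 1L)
        k <- length(rows) - 1L
      }
      xm <- features[rows, , drop = FALSE]
      dm <- as.matrix(stats::dist(xm))
      diag(dm) <- Inf
      nn <- apply(dm, 1L, function(d) order(d)[seq_len(k)])
      nn <- matrix(nn, nrow = k) # k x n_class
      base <- sample.int(length(rows), need, replace = TRUE)
      pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], integer(1))
      u <- stats::runif(need)
      syn <- xm[base, , drop = FALSE] +
        u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
      new_feats[[cl]] <- syn
      new_labels <- c(new_labels, rep(cl, need))
    }
  })
  if (length(new_feats)) {
    syn_mat <- do.call(rbind, new_feats)
    list(features = rbind(features, syn_mat),
         labels = factor(c(as.character(labels), new_labels), levels = AAMI_CLASSES),
         synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, nrow(syn_mat))))
  } else {
    list(features = features, labels = labels,
         synthetic = rep(FALSE, nrow(features)))
  }
}

#' Apply SMOTE to the training fold of a split dataset
#'
#' The only SMOTE entry point that accepts a [beat_dataset()]: it requires
#' split tags, oversamples exclusively the train-tagged rows, and leaves
#' validation and test rows byte-identical, so synthetic beats can never
#' leak into evaluation folds.
#'
#' @param ds a split [beat_dataset()].
#' @param cfg a [smote_config()].
#' @return the dataset with synthetic train rows appended (tagged `train`,
#'   `record_id = "smote"`).
#' @export
apply_smote <- function(ds, cfg = smote_config()) {
  if (!inherits(ds, "beat_dataset")) stopf("apply_smote expects a beat_dataset")
  if (all(is.na(ds$split))) {
    stopf("dataset has no split tags; SMOTE may only touch the training fold")
  }
  tr <- !is.na(ds$split) & ds$split == "train"
  res <- smote_oversample(ds$features[tr, , drop = FALSE], ds$labels[tr], cfg)
  n_syn <- sum(res$synthetic)
  if (n_syn == 0L) return(ds)
  syn <- res$features[res$synthetic, , drop = FALSE]
  beat_dataset(rbind(ds$features, syn),
               c(as.character(ds$labels), as.character(res$labels[res$synthetic])),
               c(as.character(ds$split), rep("train", n_syn)),
               c(ds$record_id, rep("smote", n_syn)),
               c(ds$r_index, rep(NA_integer_, n_syn)),
               fs = ds$fs,
               meta = c(ds$meta, list(smote_seed = cfg$seed, smote_k = cfg$k_neighbors)))
}
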