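# Training loop: Adam, fixed epochs, seeded shuffling, best-validation
# macro-F1 checkpoint.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 64, learning rate 5e-4,
#' Adam, 60 epochs, cross-entropy loss.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs fixed number of epochs (no early stopping).
#' @param loss `"ce"` or `"focal"`.
#' @param focal a [focal_config()] (used when `loss = "focal"`).
#' @param seed integer seed for shuffling and dropout.
#' @param checkpoint_policy `"best_val_macro_f1"` or `"last"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, learning_rate = 5e-4, epochs = 60,
                         loss = c("ce", "focal"), focal = focal_config(),
                         seed = 1,
                         checkpoint_policy = c("best_val_macro_f1", "last")) {
  loss <- match.arg(loss)
  checkpoint_policy <- match.arg(checkpoint_policy)
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (learning_rate < 0) stopf("learning_rate must be >= 0")
  if (epochs < 1) stopf("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 loss = loss, focal = focal, seed = as.integer(seed),
                 checkpoint_policy = checkpoint_policy),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  list(params = map2_params(params, upd, function(p, u) p - u), state = state)
}

# loss value and d(mean loss)/d(logits) for a batch; probs is (K, n),
# label_idx 1-based true classes
batch_loss_grad <- function(probs, label_idx, loss, focal) {
  n <- ncol(probs)
  pt <- pmax(probs[cbind(label_idx, seq_len(n))], PROB_EPS)
  if (loss == "ce") {
    value <- mean(-log(pt))
    dpt <- (-1 / pt) / n
  } else {
    a <- focal$alpha[label_idx]
    gam <- focal$gamma
    omp <- 1 - pt
    value <- mean(a * omp^gam * (-log(pt)))
    dlog <- if (gam == 0) 0 else gam * omp^(max(gam - 1, 0)) * log(pt)
    dpt <- a * (dlog - omp^gam / pt) / n
  }
  # chain through softmax: dlogit_j = dpt * p_t * (1{j = t} - p_j)
  scale <- dpt * pt
  dlogits <- -probs * rep(scale, each = nrow(probs))
  dlogits[cbind(label_idx, seq_len(n))] <-
    dlogits[cbind(label_idx, seq_len(n))] + scale
  list(value = value, dlogits = dlogits)
}

#' Train a model
#'
#' Fixed-epoch Adam loop with seeded per-epoch shuffling. History records
#' the mean training loss and validation macro-F1 per epoch; the returned
#' model is the checkpoint with the best validation macro-F1 (earliest epoch
#' on ties) unless `checkpoint_policy = "last"`.
#'
#' @param model a [build_model()] result.
#' @param ds a split [beat_dataset()] with train and val tags.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return `list(model, history, best_epoch)` of class `train_result`.
#' @export
train_model <- function(model, ds, cfg = train_config(), verbose = FALSE) {
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "val")
  if (n_beats(tr) == 0L) stopf("training split is empty")
  x_tr <- tr$features
  y_tr <- as.integer(tr$labels)
  params <- model_params(model)
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_macro_f1 = numeric(0))
  best <- list(f1 = -Inf, model = model, epoch = 0L)
  n <- nrow(x_tr)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      total_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- features_to_input(x_tr[idx, , drop = FALSE])
        fw <- model_forward(model, xb, training = TRUE)
        model <- fw$model # batch-norm running statistics advance
        lg <- batch_loss_grad(fw$probs, y_tr[idx], cfg$loss, cfg$focal)
        grads <- model_backward(model, lg$dlogits, fw$caches)
        if (cfg$learning_rate > 0) {
          st <- adam_step(params, grads, opt, cfg$learning_rate)
          params <- st$params
          opt <- st$state
          model <- model_set_params(model, params)
        }
        total_loss <- total_loss + lg$value
        n_batches <- n_batches + 1L
      }
      cm <- evaluate_model(model, va)
      f1 <- macro_f1(cm)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = total_loss / n_batches,
                                  val_macro_f1 = f1))
      if (f1 > best$f1) best <- list(f1 = f1, model = model, epoch = epoch)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  val macro-F1 %.4f",
                        epoch, cfg$epochs, total_loss / n_batches, f1))
      }
    }
  })
  final <- if (cfg$checkpoint_policy == "best_val_macro_f1") best$model else model
  structure(list(model = final, history = history,
                 best_epoch = if (cfg$checkpoint_policy == "best_val_macro_f1")
                   best$epoch else cfg$epochs),
            class = "train_result")
}

#' Evaluate a model on one split
#'
#' Argmax prediction per segment (ties to the lower class index); the
#' confusion-matrix total equals the split size.
#'
#' @param model a `beat_model`.
#' @param ds a [beat_dataset()] (evaluated whole) — pass e.g.
#'   `dataset_split(ds, "test")` to evaluate one split.
#' @return a [confusion_matrix()].
#' @export
evaluate_model <- function(model, ds) {
  if (n_beats(ds) == 0L) stopf("evaluation split is empty")
  pred <- predict_class(model, ds$features)
  confusion_matrix(ds$labels, pred)
}
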