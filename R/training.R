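#' Training configuration
#'
#' Hyperparameters of the seeded training loop.  The defaults follow the
#' reference protocol for this architecture: Adam with initial learning
#' rate 1e-4, minibatch size 64 and an epoch budget of 64, minimizing
#' categorical cross-entropy on the softmax outputs.  Adam moment decays
#' default to 0.9 / 0.999 with epsilon 1e-8; batch-normalization running
#' statistics use momentum 0.1.
#'
#' @param optimizer Only `"adam"` is supported.
#' @param learning_rate Positive step size (constant; no schedule).
#' @param batch_size Minibatch size (>= 1).
#' @param max_epochs Epoch budget (>= 1).
#' @param seed Integer seed governing minibatch shuffling.
#' @param loss Only `"cross_entropy"` is supported.
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation accuracy (`NULL` = never).
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @param freeze_batchnorm_stats If `TRUE`, batch-normalization running
#'   statistics are not updated during training (useful for controlled
#'   experiments; normalization still uses batch statistics).
#' @param verbose Print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-4,
                         batch_size = 64L, max_epochs = 64L, seed = 1L,
                         loss = "cross_entropy",
                         early_stop_patience = NULL,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         freeze_batchnorm_stats = FALSE,
                         verbose = FALSE) {
  if (!identical(optimizer, "adam"))
    stop("unsupported optimizer '", optimizer, "'", call. = FALSE)
  if (!identical(loss, "cross_entropy"))
    stop("unsupported loss '", loss, "'", call. = FALSE)
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), loss = loss,
                 early_stop_patience = early_stop_patience,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 freeze_batchnorm_stats = freeze_batchnorm_stats,
                 verbose = verbose),
            class = "train_config")
}

trainable_fields_ <- function(kind) {
  switch(kind, conv = c("W", "b"), fully_connected = c("W", "b"),
         batchnorm = c("gamma", "beta"), character(0))
}

cross_entropy_ <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p, 1e-12)))
}

# Loss and accuracy of a model over a set, evaluated in inference mode.
evaluate_ <- function(model, set, batch_size = 32L) {
  pr <- predict(model, set, batch_size = batch_size)
  list(loss = cross_entropy_(pr$probs, set$labels),
       accuracy = mean(pr$labels == set$labels))
}

#' Train a model by minibatch Adam on cross-entropy
#'
#' Runs a seeded minibatch training loop: per epoch, the training set is
#' reshuffled (deterministically under `cfg$seed`), forward/backward
#' passes accumulate gradients per minibatch, and Adam updates every
#' trainable tensor.  After each epoch the model is evaluated on the
#' training and validation sets in inference mode.  The returned model
#' carries the parameters of the epoch with the best validation accuracy
#' (ties resolved in favor of the earlier epoch).
#'
#' @param model A [build_network()] model.
#' @param train_set,val_set [labeled_image_set()]s; the model's output
#'   width must equal the number of classes.
#' @param cfg A [train_config()].
#' @return List with `model` (best-validation parameters), `final_model`
#'   (last-epoch parameters), and `history` (data frame with per-epoch
#'   `epoch`, `train_loss`, `train_accuracy`, `val_loss`,
#'   `val_accuracy`).
#' @export
train_network <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"),
            inherits(train_set, "labeled_image_set"))
  k <- model$spec$num_classes
  if (length(train_set$class_names) != k)
    stop("model has ", k, " outputs but the data has ",
         length(train_set$class_names), " classes", call. = FALSE)

  # Adam state per layer/field
  state <- lapply(model$layers, function(l) {
    fields <- trainable_fields_(l$kind)
    setNames(lapply(fields, function(f)
      list(m = 0 * l[[f]], v = 0 * l[[f]])), fields)
  })
  step <- 0L
  n <- length(train_set)
  history <- NULL
  best <- list(acc = -Inf, layers = NULL, epoch = NA_integer_)
  stale <- 0L

  with_seed_(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        sel <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- train_set$images[, , , sel, drop = FALSE]
        yb <- train_set$labels[sel]
        fw <- forward_(model, xb, training = TRUE)
        if (!all(is.finite(fw$logits)))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        if (!cfg$freeze_batchnorm_stats) {
          for (li in seq_along(model$layers)) {
            l <- model$layers[[li]]
            if (l$kind == "batchnorm") {
              cache <- fw$caches[[li]]
              model$layers[[li]]$running_mean <-
                (1 - l$momentum) * l$running_mean + l$momentum * cache$batch_mean
              model$layers[[li]]$running_var <-
                (1 - l$momentum) * l$running_var + l$momentum * cache$batch_var
            }
          }
        }
        ep_loss <- ep_loss + length(sel) * cross_entropy_(fw$probs, yb)
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") == yb)
        onehot <- matrix(0, length(sel), k)
        onehot[cbind(seq_along(sel), yb)] <- 1
        dlogits <- (fw$probs - onehot) / length(sel)
        grads <- backward_(model, fw, dlogits)
        rm(fw, xb)
        step <- step + 1L
        lr_t <- cfg$learning_rate *
          sqrt(1 - cfg$beta2^step) / (1 - cfg$beta1^step)
        for (li in seq_along(model$layers)) {
          for (f in names(state[[li]])) {
            g <- grads[[li]][[f]]
            st <- state[[li]][[f]]
            st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
            st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
            state[[li]][[f]] <- st
            model$layers[[li]][[f]] <- model$layers[[li]][[f]] -
              lr_t * st$m / (sqrt(st$v) + cfg$epsilon)
          }
        }
      }
      # training metrics are running averages over the epoch's minibatches
      # (training-mode batchnorm); validation is a clean inference pass
      tr <- list(loss = ep_loss / n, accuracy = ep_correct / n)
      va <- if (length(val_set) > 0) evaluate_(model, val_set)
            else list(loss = NA_real_, accuracy = NA_real_)
      gc(verbose = FALSE)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr$loss, train_accuracy = tr$accuracy,
        val_loss = va$loss, val_accuracy = va$accuracy))
      if (cfg$verbose)
        message(sprintf(
          "epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, tr$loss, tr$accuracy, va$loss, va$accuracy))
      score <- if (is.na(va$accuracy)) tr$accuracy else va$accuracy
      if (score > best$acc) {
        best <- list(acc = score, layers = model$layers, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (!is.null(cfg$early_stop_patience) &&
            stale >= cfg$early_stop_patience) break
      }
    }
  })
  final_model <- model
  model$layers <- best$layers
  attr(history, "best_epoch") <- best$epoch
  list(model = model, final_model = final_model, history = history)
}
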