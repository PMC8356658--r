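# Training recipe and binary-classification evaluation suite.
#
# Training: mini-batch SGD with momentum 0.9 and weight decay 1e-4 on a
# cross-entropy loss over the raw two-way scores; the learning rate starts
# at 0.001 and is multiplied by 0.1 every 30 epochs (step decay at the
# epoch boundary, so epochs 31+ run at 0.0001).  Inputs are standardized
# per channel by the training split's mean and SD; the record is stored on
# the network so inference applies the same transform.

#' Training configuration
#'
#' @param initial_lr Initial learning rate (default 0.001).
#' @param lr_decay_factor Multiplicative decay factor (default 0.1).
#' @param lr_decay_epoch Epoch period of the step decay (default 30).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay coefficient (default 1e-4).
#' @param epochs Number of training epochs (default 100).
#' @param batch_size Mini-batch size (default 16).
#' @param rng_seed Integer seed controlling shuffling, dropout and any
#'   weight initialization done by the caller.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.001, lr_decay_factor = 0.1,
                         lr_decay_epoch = 30L, momentum = 0.9,
                         weight_decay = 1e-4, epochs = 100L,
                         batch_size = 16L, rng_seed = 1L) {
  stopifnot(initial_lr > 0, lr_decay_factor > 0, lr_decay_epoch >= 1,
            epochs >= 1, batch_size >= 1)
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_epoch = as.integer(lr_decay_epoch),
                 momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Learning rate in force at a given epoch
#'
#' @param config A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The step-decayed learning rate (e.g. 0.001 for epochs 1-30 and
#'   0.0001 from epoch 31 under the defaults).
#' @export
lr_at_epoch <- function(config, epoch) {
  config$initial_lr *
    config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_epoch)
}

softmax_rows <- function(s) {
  p <- exp(s - apply(s, 1, max))
  p / rowSums(p)
}

cross_entropy <- function(scores, labels01) {
  p <- softmax_rows(scores)
  n <- nrow(scores)
  idx <- cbind(seq_len(n), labels01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, dscores = dscores / n)
}

#' Train a network on labeled image splits
#'
#' @param network A [build_network()] result (modified in place).
#' @param splits A list with elements `train` and (optionally) `test`,
#'   each a `labeled_image_set`; splits must be disjoint.
#' @param config A [train_config()].
#' @param eval_test Evaluate test accuracy after every epoch (default
#'   `TRUE` when a test split is supplied).
#' @param stop_at_train_acc Optional running-train-accuracy threshold at
#'   which training stops early (e.g. 1.0).
#' @param verbose Print one line per epoch.
#' @return A list with `network` (trained, same object) and `history`
#'   (data frame: epoch, lr, train_loss, train_acc, test_acc).
#' @export
train <- function(network, splits, config = train_config(),
                  eval_test = !is.null(splits$test),
                  stop_at_train_acc = NULL, verbose = FALSE) {
  if (is.null(splits$train) || length(splits$train$images) == 0)
    stop("train: empty training split")
  size <- network$config$input_size
  xtr <- as_input_batch(splits$train, size)
  ytr <- splits$train$labels
  d <- dim(xtr)
  ch_stats <- function(x) {
    xm <- matrix(x, d[1] * d[2], d[3] * d[4])
    mu <- rowMeans(matrix(colMeans(xm), d[3], d[4]))
    sd_ <- sqrt(pmax(rowMeans(matrix(colMeans(xm^2), d[3], d[4])) - mu^2,
                     1e-8))
    list(mean = mu, sd = sd_)
  }
  network$norm <- ch_stats(xtr)
  xtr <- (xtr - bcast_channel(network$norm$mean, d)) /
    bcast_channel(network$norm$sd, d)
  if (eval_test) {
    xte <- as_input_batch(splits$test, size)
    dte <- dim(xte)
    xte <- (xte - bcast_channel(network$norm$mean, dte)) /
      bcast_channel(network$norm$sd, dte)
    yte <- splits$test$labels
  }
  n <- length(ytr)
  hist_rows <- list()
  with_seed(config$rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      idx <- sample.int(n)
      losses <- c(); correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        take <- idx[start:min(start + config$batch_size - 1L, n)]
        xb <- xtr[, , , take, drop = FALSE]
        yb <- ytr[take]
        scores <- network_forward(network, xb, training = TRUE)
        ce <- cross_entropy(scores, yb)
        if (!is.finite(ce$loss))
          stop(sprintf("train: non-finite loss at epoch %d (lr %.2g)",
                       epoch, lr))
        losses <- c(losses, ce$loss)
        correct <- correct + sum(max.col(scores) - 1L == yb)
        network_backward(network, ce$dscores)
        for (ly in network$layers)
          sgd_update_layer(ly, lr, config$momentum, config$weight_decay)
      }
      train_acc <- correct / n
      test_acc <- NA_real_
      if (eval_test) {
        pr <- network_forward(network, xte, training = FALSE)
        test_acc <- mean(max.col(pr) - 1L == yte)
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        train_acc = train_acc, test_acc = test_acc)
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.5f  loss %.4f  train_acc %.3f  test_acc %s",
          epoch, lr, mean(losses), train_acc,
          ifelse(is.na(test_acc), "-", sprintf("%.3f", test_acc))))
      if (!is.null(stop_at_train_acc) && train_acc >= stop_at_train_acc)
        break
    }
  })
  list(network = network, history = do.call(rbind, hist_rows))
}

# ---- evaluation -------------------------------------------------------------

#' Confusion counts for binary predictions
#'
#' Positive class is label 1 (haploid / normal seed); negative is label 0.
#'
#' @param predicted,truth Equal-length vectors of 0/1 labels.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("confusion_counts: length mismatch")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("confusion_counts: labels must be 0/1")
  structure(list(
    tp = sum(predicted == 1 & truth == 1),
    tn = sum(predicted == 0 & truth == 0),
    fp = sum(predicted == 1 & truth == 0),
    fn = sum(predicted == 0 & truth == 1)
  ), class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Ratios with zero denominators are reported as `NaN` and listed in the
#' `undefined` field rather than silently coerced to zero.
#'
#' @param counts A [confusion_counts()] object.
#' @return A list with `accuracy`, `precision`, `recall`, `f1` and
#'   `undefined` (character vector of metrics with zero denominators).
#' @export
classification_metrics <- function(counts) {
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  if (n == 0) stop("classification_metrics: no evaluated samples")
  undef <- character(0)
  acc <- (counts$tp + counts$tn) / n
  p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp)
       else { undef <- c(undef, "precision"); NaN }
  r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
       else { undef <- c(undef, "recall"); NaN }
  f1 <- if (is.finite(p) && is.finite(r) && p + r > 0) 2 * p * r / (p + r)
        else { undef <- c(undef, "f1"); NaN }
  list(accuracy = acc, precision = p, recall = r, f1 = f1, undefined = undef)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties grouped into
#' one step), producing an ROC that starts at (0, 0) and ends at (1, 1);
#' the AUC is the trapezoidal area under it.
#'
#' @param scores Numeric classifier scores, larger meaning more positive.
#' @param truth 0/1 labels; both classes must be present.
#' @return A list with `roc` (data frame with `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("roc_auc: length mismatch")
  np <- sum(truth == 1); nn <- sum(truth == 0)
  if (np == 0 || nn == 0) stop("roc_auc: need both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(y == 1, grp, sum)
  fp_steps <- tapply(y == 0, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / np)
  fpr <- c(0, cumsum(fp_steps) / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       auc = auc)
}
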