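# Training protocol, metric suite and class-activation rendering.
#
# Protocol: Adam (initial learning rate 0.001), batch size 4, categorical
# cross-entropy, 65 epochs; learning rate halved after 5 epochs without a
# validation-accuracy improvement of at least 1e-4; early stop after 30 such
# epochs with best-weight restore. Reported metrics: per-class precision,
# recall, F1 and one-vs-rest accuracy; overall precision/recall/F1 as the
# unweighted (macro) mean over classes; overall accuracy as the pooled
# (micro) fraction correct; per-class one-vs-rest ROC-AUC.

#' Training configuration
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Initial Adam learning rate.
#' @param lr_factor,lr_patience Plateau schedule: multiply `lr` by
#'   `lr_factor` after `lr_patience` epochs without improvement.
#' @param min_delta Minimum validation-accuracy improvement that counts.
#' @param es_patience Early-stopping patience (epochs without improvement).
#' @param val_frac Fraction of training cases held out for validation when no
#'   explicit validation set is supplied.
#' @param seed Seed for shuffling and weight initialization bookkeeping.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 65L, batch_size = 4L, lr = 1e-3,
                         lr_factor = 0.5, lr_patience = 5L, min_delta = 1e-4,
                         es_patience = 30L, val_frac = 0.1, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_delta = min_delta,
                 es_patience = as.integer(es_patience), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- optimizer -------------------------------------------------------------

adam_optimizer <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  self <- new.env(parent = emptyenv())
  self$lr <- lr
  self$t <- 0
  self$leaves <- Filter(function(l) length(l$params()) > 0, module_leaves(model))
  for (l in self$leaves) {
    l$opt <- lapply(l$params(), function(p) list(m = p * 0, v = p * 0))
  }
  self$step <- function() {
    self$t <- self$t + 1
    bc1 <- 1 - beta1^self$t
    bc2 <- 1 - beta2^self$t
    for (l in self$leaves) {
      p <- l$params(); g <- l$grads()
      for (nm in names(p)) {
        st <- l$opt[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
        l$opt[[nm]] <- st
        p[[nm]] <- p[[nm]] - self$lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      }
      l$set_params(p)
    }
  }
  self
}

cross_entropy_grad <- function(logits, y_idx) {
  probs <- softmax_cols(logits)
  n <- ncol(probs)
  picked <- probs[cbind(y_idx, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, nrow(probs), n)
  onehot[cbind(y_idx, seq_len(n))] <- 1
  list(loss = loss, grad = (probs - onehot) / n)
}

predict_proba_batched <- function(model, x, batch_size = 16L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- t(model$predict_proba(x[, , , i:j, drop = FALSE]))
    i <- j + 1L
  }
  out
}

## ---- training --------------------------------------------------------------

#' Train a model
#'
#' Minibatch Adam with the plateau learning-rate schedule and early stopping
#' monitored on validation accuracy; the best-epoch weights are restored at
#' the end. When `x_val` is `NULL`, a seeded `val_frac` of the training
#' samples is held out (pass case ids in `case_id` to keep the holdout
#' case-respecting).
#'
#' @param model A model from [build_variant()] whose input size matches `x`.
#' @param x Training tensor `(S, S, 3, N)` (preprocessed patches).
#' @param y Factor of class labels, length `N`.
#' @param cfg A [train_config()].
#' @param x_val,y_val Optional explicit validation set.
#' @param case_id Optional case ids (length `N`) for case-respecting holdout.
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and a `history` data.frame
#'   (`epoch`, `loss`, `val_acc`, `lr`).
#' @export
train_model <- function(model, x, y, cfg = train_config(),
                        x_val = NULL, y_val = NULL, case_id = NULL,
                        verbose = FALSE) {
  n <- dim(x)[4]
  if (n == 0L) stop("empty training set")
  y <- factor(y)
  set.seed(cfg$seed)
  if (is.null(x_val)) {
    hold <- validation_holdout(y, case_id, cfg$val_frac)
    x_val <- x[, , , hold, drop = FALSE]
    y_val <- y[hold]
    x <- x[, , , -hold, drop = FALSE]
    y <- y[-hold]
    n <- dim(x)[4]
  }
  y_idx <- as.integer(y)
  yv_idx <- as.integer(factor(y_val, levels = levels(y)))
  opt <- adam_optimizer(model, lr = cfg$lr)
  best_acc <- -Inf
  best_state <- NULL
  wait <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_acc = numeric(), lr = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      idx <- ord[i:j]
      module_zero_grads(model)
      out <- model$forward(x[, , , idx, drop = FALSE], train = TRUE)
      ce <- cross_entropy_grad(out$logits, y_idx[idx])
      model$backward(ce$grad)
      opt$step()
      losses <- c(losses, ce$loss)
      i <- j + 1L
    }
    pv <- predict_proba_batched(model, x_val)
    val_acc <- mean(max.col(pv) == yv_idx)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_acc = val_acc, lr = opt$lr))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_acc %.4f  lr %.2e",
                      epoch, mean(losses), val_acc, opt$lr))
    }
    if (val_acc > best_acc + cfg$min_delta) {
      best_acc <- val_acc
      best_state <- module_get_state(model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait %% cfg$lr_patience == 0L) opt$lr <- opt$lr * cfg$lr_factor
      if (wait >= cfg$es_patience) break
    }
  }
  if (!is.null(best_state)) module_set_state(model, best_state)
  list(model = model, history = hist, best_val_acc = best_acc)
}

validation_holdout <- function(y, case_id, val_frac) {
  n <- length(y)
  target <- max(1L, round(val_frac * n))
  if (is.null(case_id)) return(sample.int(n, target))
  hold <- integer(0)
  for (cls in levels(y)) {
    rc <- which(y == cls)
    per_cls <- max(1L, round(val_frac * length(rc)))
    cases <- sample(unique(case_id[rc]))
    got <- integer(0)
    for (cs in cases) {
      got <- c(got, rc[case_id[rc] == cs])
      if (length(got) >= per_cls) break
    }
    hold <- c(hold, got)
  }
  hold
}

## ---- metrics ---------------------------------------------------------------

#' Unweighted (macro) average of per-class metric values
#'
#' The aggregation used for the "Overall" precision, recall and F1 rows;
#' `NA` entries (classes absent from both truth and prediction) are dropped
#' with a warning by [metrics_report()] before averaging.
#'
#' @param x Numeric vector of per-class values.
#' @return Their unweighted mean.
#' @export
macro_average <- function(x) mean(x, na.rm = TRUE)

#' Multiclass classification report
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels (same levels).
#' @param scores Optional `N x K` score matrix for ROC-AUC.
#' @return A list of class `metrics_report`: `$confusion` (truth in rows),
#'   `$per_class` (precision, recall, f1, one-vs-rest accuracy, auc),
#'   `$overall` (macro precision/recall/f1, micro accuracy), `$n`.
#' @export
metrics_report <- function(truth, pred, scores = NULL) {
  if (!is.factor(truth)) truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  k <- nlevels(truth)
  cm <- table(truth = truth, pred = pred)
  n <- sum(cm)
  per <- data.frame(class = levels(truth), precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, accuracy = NA_real_,
                    auc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n - tp - fp - fn
    if (tp + fn == 0 && tp + fp == 0) {
      warning(sprintf("class '%s' absent from truth and prediction; metrics undefined",
                      levels(truth)[i]))
      next
    }
    per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$f1[i] <- if (per$precision[i] + per$recall[i] > 0) {
      2 * per$precision[i] * per$recall[i] / (per$precision[i] + per$recall[i])
    } else {
      0
    }
    per$accuracy[i] <- (tp + tn) / n
  }
  if (!is.null(scores)) per$auc <- roc_auc(scores, truth)
  overall <- list(precision = macro_average(per$precision),
                  recall = macro_average(per$recall),
                  f1 = macro_average(per$f1),
                  accuracy = sum(diag(cm)) / n)
  structure(list(confusion = cm, per_class = per, overall = overall, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics on %d samples\n", x$n))
  print(x$per_class, digits = 4)
  cat(sprintf("Overall: precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f\n",
              x$overall$precision, x$overall$recall, x$overall$f1,
              x$overall$accuracy))
  invisible(x)
}

#' Evaluate a model on a test tensor
#'
#' @param model Trained model.
#' @param x Test tensor `(S, S, 3, N)`.
#' @param y Factor of true labels.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, x, y) {
  y <- factor(y)
  scores <- predict_proba_batched(model, x)
  pred <- factor(levels(y)[max.col(scores)], levels = levels(y))
  metrics_report(y, pred, scores)
}

#' Per-class one-vs-rest ROC-AUC
#'
#' Trapezoidal AUC (equivalently the Mann-Whitney pair statistic) for each
#' class against the rest.
#'
#' @param scores `N x K` score matrix, columns ordered as `levels(labels)`.
#' @param labels Factor of true labels.
#' @return Named numeric vector of per-class AUCs; `NA` (with a warning) for
#'   classes absent from the labels.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == nlevels(labels))
  out <- stats::setNames(rep(NA_real_, nlevels(labels)), levels(labels))
  for (i in seq_len(nlevels(labels))) {
    pos <- labels == levels(labels)[i]
    if (all(pos) || !any(pos)) {
      warning(sprintf("AUC undefined for class '%s' (single-class labels)",
                      levels(labels)[i]))
      next
    }
    r <- pROC::roc(response = pos, predictor = scores[, i],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    out[i] <- as.numeric(pROC::auc(r))
  }
  out
}

## ---- experimental procedures -----------------------------------------------

average_reports <- function(reports) {
  per <- reports[[1]]$per_class
  cols <- c("precision", "recall", "f1", "accuracy", "auc")
  for (cl in cols) {
    per[[cl]] <- rowMeans(sapply(reports, function(r) r$per_class[[cl]]))
  }
  overall <- list()
  for (nm in names(reports[[1]]$overall)) {
    overall[[nm]] <- mean(sapply(reports, function(r) r$overall[[nm]]))
  }
  cm <- Reduce(`+`, lapply(reports, function(r) r$confusion)) / length(reports)
  structure(list(confusion = cm, per_class = per, overall = overall,
                 n = reports[[1]]$n, n_reports = length(reports)),
            class = "metrics_report")
}

#' Average of independently initialized training trials
#'
#' Trains a fresh model per trial (random weights, seeded per trial) and
#' element-wise averages the per-trial metric reports.
#'
#' @param spec A [variant_spec()] or variant name.
#' @param cfg A [renalnet_config()].
#' @param x,y,x_test,y_test Train and test tensors/labels.
#' @param train_cfg A [train_config()].
#' @param seeds Integer vector, one seed per trial (default 3 trials).
#' @param input_size Model input size; default taken from `x`.
#' @return List with `average` (a `metrics_report`) and `trials`
#'   (per-trial reports), plus the seeds used.
#' @export
run_trials <- function(spec, cfg, x, y, x_test, y_test,
                       train_cfg = train_config(), seeds = 1:3,
                       input_size = dim(x)[1]) {
  reports <- list()
  for (s in seeds) {
    set.seed(s)
    model <- build_variant(spec, cfg, input_size = input_size)
    tc <- train_cfg
    tc$seed <- as.integer(s)
    train_model(model, x, y, tc)
    reports[[length(reports) + 1L]] <- evaluate_model(model, x_test, y_test)
  }
  list(average = average_reports(reports), trials = reports, seeds = seeds)
}

#' k-fold cross-validation over a fold-annotated manifest tensor
#'
#' Run r trains on all folds but r and tests on fold r; reports are returned
#' per fold together with their element-wise mean.
#'
#' @param spec A [variant_spec()] or variant name.
#' @param cfg A [renalnet_config()].
#' @param x,y Full tensor stack and labels.
#' @param folds Integer fold assignment (from [make_folds()]).
#' @param train_cfg A [train_config()].
#' @return List with `per_fold` reports and `average`.
#' @export
cross_validate <- function(spec, cfg, x, y, folds,
                           train_cfg = train_config()) {
  ks <- sort(unique(folds))
  reports <- list()
  for (r in ks) {
    test <- which(folds == r)
    set.seed(train_cfg$seed + r)
    model <- build_variant(spec, cfg, input_size = dim(x)[1])
    tc <- train_cfg
    tc$seed <- as.integer(train_cfg$seed + r)
    train_model(model, x[, , , -test, drop = FALSE], y[-test], tc)
    reports[[length(reports) + 1L]] <-
      evaluate_model(model, x[, , , test, drop = FALSE], y[test])
  }
  list(per_fold = reports, average = average_reports(reports))
}

## ---- class-activation maps -------------------------------------------------

#' Gradient-weighted class-activation overlay
#'
#' Backpropagates the target-class logit to the pre-classifier feature map
#' (the merged GCDL map, or the stage-3 map for variants without the head),
#' weights each channel by its spatially averaged gradient, rectifies and
#' min-max normalizes the weighted sum, upsamples to the input size and bands
#' it into three levels: red (high, >= `thresholds[1]`), orange (medium) and
#' light blue (low, < `thresholds[2]`).
#'
#' @param model Trained model.
#' @param img Preprocessed input `(S, S, 3)` (see [preprocess_patch()]).
#' @param target_class Class index (1-based) or label.
#' @param thresholds High/medium band thresholds on the normalized map.
#' @param raw_img Optional unnormalized `(S, S, 3)` image for the overlay
#'   blend; defaults to a grey rescale of `img`.
#' @return List with `map` (normalized `(S, S)` activation), `bands`
#'   (integer map: 3 high, 2 medium, 1 low) and `overlay` (`(S, S, 3)` RGB).
#' @export
activation_map <- function(model, img, target_class,
                           thresholds = c(0.7, 0.4), raw_img = NULL) {
  x <- as_batch(img)
  out <- model$forward(x, train = FALSE)
  if (is.character(target_class) || is.factor(target_class)) {
    target_class <- match(as.character(target_class), RCC_CLASSES)
  }
  g <- matrix(0, model$n_classes, 1)
  g[target_class, 1] <- 1
  module_zero_grads(model)
  model$backward(g)
  feat <- model$feature_map
  grad <- model$feature_grad
  d <- dim(feat)
  wts <- apply(grad[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) cam <- cam + wts[c] * feat[, , c, 1]
  cam[cam < 0] <- 0
  rng <- range(cam)
  if (rng[2] - rng[1] < 1e-12) {
    warning("uniform activation map (degenerate or untrained model)")
    cam[] <- 0
  } else {
    cam <- (cam - rng[1]) / (rng[2] - rng[1])
  }
  S <- dim(x)[1]
  if (d[1] != S) {
    cam <- t(as.matrix(EBImage::imageData(EBImage::resize(
      EBImage::Image(t(cam)), w = S, h = S, filter = "bilinear"))))
  }
  bands <- matrix(1L, S, S)
  bands[cam >= thresholds[2]] <- 2L
  bands[cam >= thresholds[1]] <- 3L
  band_cols <- rbind(c(0.55, 0.80, 0.95),  # light blue: low
                     c(1.00, 0.60, 0.10),  # orange: medium
                     c(0.90, 0.10, 0.10))  # red: high
  if (is.null(raw_img)) {
    raw_img <- (img - min(img)) / max(1e-12, diff(range(img)))
  }
  overlay <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    col <- matrix(band_cols[bands, ch], S, S)
    overlay[, , ch] <- 0.55 * raw_img[, , ch] + 0.45 * col
  }
  list(map = cam, bands = bands, overlay = overlay,
       probs = as.numeric(out$probs))
}
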