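#' Expression classifier configuration
#'
#' Defines the spatio-temporal window classifier. The default, `"cnn-tcn"`,
#' stacks a CNN block (1-D convolutions along time over the 7 input
#' channels, batch normalization, ReLU, max-pooling), a TCN block (residual
#' dilated causal convolutions), and a fully connected block (global average
#' pooling, hidden layer, 4-way softmax). Baseline architectures `"cnn"`,
#' `"tcn"`, `"lstm"`, `"cnn-lstm"`, and `"gru"` share the training and
#' evaluation contract.
#'
#' @param architecture one of cnn-tcn, cnn, tcn, lstm, cnn-lstm, gru.
#' @param cnn list: `filters` (per conv layer), `kernel`, `pool` factor.
#' @param tcn list: `filters`, `kernel`, `dilations` (strictly increasing
#'   powers of 2), `dropout`.
#' @param fc list: `hidden` layer width.
#' @param rnn list: `hidden` state size and `max_steps` (inputs longer than
#'   this are average-pooled down before the recurrence).
#' @param optimizer list: `lr`, `batch_size`, `max_epochs`, `patience`
#'   (early stopping on validation weighted F1).
#' @param class_weighting "inverse" (inverse-frequency loss weights) or
#'   "none".
#' @param seed integer seed for initialization, shuffling, and dropout.
#' @return List of class `femg_model_config`.
#' @export
expression_model <- function(architecture = "cnn-tcn",
                             cnn = list(filters = c(32, 64), kernel = 5,
                                        pool = 2),
                             tcn = list(filters = 64, kernel = 3,
                                        dilations = c(1, 2, 4),
                                        dropout = 0.2),
                             fc = list(hidden = 64),
                             rnn = list(hidden = 32, max_steps = 64),
                             optimizer = list(lr = 1e-3, batch_size = 64,
                                              max_epochs = 100,
                                              patience = 10),
                             class_weighting = c("inverse", "none"),
                             seed = 1L) {
  architecture <- match.arg(architecture,
                            c("cnn-tcn", "cnn", "tcn", "lstm", "cnn-lstm",
                              "gru"))
  dl <- tcn$dilations
  if (length(dl) < 1 || any(diff(dl) <= 0) ||
      any(abs(log2(dl) - round(log2(dl))) > 1e-9))
    stop("tcn dilations must be strictly increasing powers of 2")
  structure(list(architecture = architecture, cnn = cnn, tcn = tcn, fc = fc,
                 rnn = rnn, optimizer = optimizer,
                 class_weighting = match.arg(class_weighting),
                 n_classes = 4L, seed = as.integer(seed)),
            class = "femg_model_config")
}

#' Receptive field of the TCN stack
#'
#' Closed form for a stack of residual blocks each holding two dilated
#' causal convolutions: `1 + 2 * (kernel - 1) * sum(dilations)` samples.
#'
#' @param config a [expression_model()] config.
#' @return Receptive field in samples (at the TCN's input resolution).
#' @export
receptive_field <- function(config) {
  1 + 2 * (config$tcn$kernel - 1) * sum(config$tcn$dilations)
}

cnn_layers <- function(cfg, cin) {
  layers <- list()
  for (f in cfg$cnn$filters) {
    layers <- c(layers, list(layer_conv1d(cin, f, cfg$cnn$kernel),
                             layer_bn(f), layer_relu(), layer_maxpool()))
    cin <- f
  }
  list(layers = layers, cout = cin,
       pool_total = cfg$cnn$pool^0 * 2^length(cfg$cnn$filters))
}

tcn_layers <- function(cfg, cin) {
  layers <- list()
  f <- cfg$tcn$filters; k <- cfg$tcn$kernel
  for (d in cfg$tcn$dilations) {
    inner <- list(layer_conv1d(cin, f, k, dilation = d, causal = TRUE),
                  layer_relu(), layer_dropout(cfg$tcn$dropout),
                  layer_conv1d(f, f, k, dilation = d, causal = TRUE),
                  layer_relu(), layer_dropout(cfg$tcn$dropout))
    layers <- c(layers, list(layer_residual(inner, cin, f)))
    cin <- f
  }
  list(layers = layers, cout = cin)
}

rnn_prefix <- function(cfg, w) {
  f <- max(1L, ceiling(w / cfg$rnn$max_steps))
  if (f > 1) list(layer_avgpool(f)) else list()
}

#' Build an untrained expression classifier
#'
#' Accepts a `(w x 7)` window and emits 4 class probabilities summing to 1.
#' Weight initialization is seeded from the config, so two builds with the
#' same seed have identical initial parameters.
#'
#' @param config a [expression_model()] config.
#' @param w window length in samples.
#' @return Object of class `femg_model` (untrained).
#' @export
build_model <- function(config, w) {
  stopifnot(inherits(config, "femg_model_config"))
  arch <- config$architecture
  uses_cnn <- arch %in% c("cnn-tcn", "cnn", "cnn-lstm")
  if (uses_cnn && w < 2^length(config$cnn$filters))
    stop("window length ", w, " incompatible with ",
         length(config$cnn$filters), " pooling stages")
  layers <- with_seed(config$seed, {
    head_in <- 7L
    ll <- list()
    if (uses_cnn) {
      cb <- cnn_layers(config, 7L)
      ll <- cb$layers
      head_in <- cb$cout
    }
    if (arch %in% c("cnn-tcn", "tcn")) {
      tb <- tcn_layers(config, head_in)
      ll <- c(ll, tb$layers)
      head_in <- tb$cout
    }
    if (arch %in% c("lstm", "gru")) {
      ll <- c(ll, rnn_prefix(config, w))
      rec <- if (arch == "lstm") layer_lstm(7L, config$rnn$hidden) else
        layer_gru(7L, config$rnn$hidden)
      ll <- c(ll, list(rec))
      head_in <- config$rnn$hidden
    } else if (arch == "cnn-lstm") {
      ll <- c(ll, list(layer_lstm(head_in, config$rnn$hidden)))
      head_in <- config$rnn$hidden
    } else {
      ll <- c(ll, list(layer_gap()))
    }
    c(ll, list(layer_dense(head_in, config$fc$hidden), layer_relu(),
               layer_dense(config$fc$hidden, config$n_classes,
                           init = "glorot")))
  })
  structure(list(config = config, layers = layers, w = as.integer(w),
                 channels = femg_channels(),
                 class_levels = expression_levels(),
                 n_params = count_params(layers), trained = FALSE,
                 history = NULL),
            class = "femg_model")
}

#' @export
print.femg_model <- function(x, ...) {
  cat(sprintf("femg_model [%s] w=%d, %d parameters (%s)\n",
              x$config$architecture, x$w, x$n_params,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.femg_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  trained %d epochs (best %d); final val weighted F1 %.3f\n",
                nrow(h), object$best_epoch, max(h$val_wf1, na.rm = TRUE)))
  }
  invisible(object)
}

windows_to_array <- function(newdata, w) {
  if (is.list(newdata) && !is.array(newdata) &&
      !is.null(newdata[[1]]$data)) {
    newdata <- stack_windows(newdata)$x
  } else if (is.matrix(newdata)) {
    newdata <- array(newdata, c(1, nrow(newdata), ncol(newdata)))
  }
  if (length(dim(newdata)) != 3 || dim(newdata)[2] != w ||
      dim(newdata)[3] != 7)
    stop("windows must be (batch x ", w, " x 7); got dims ",
         paste(dim(newdata), collapse = "x"))
  newdata
}

#' Predict expression labels for windows
#'
#' The predicted label is the probability argmax; exact ties resolve to the
#' earlier class in the fixed order neutral < smile < frown < raised_eyebrow.
#'
#' @param object a trained `femg_model`.
#' @param newdata a `(w x 7)` matrix, a `(B x w x 7)` array, or a list of
#'   windows from [segment_windows()].
#' @param type "class" or "prob".
#' @param ... unused.
#' @return Factor of labels, or a probability matrix with one row per window.
#' @export
predict.femg_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  x <- windows_to_array(newdata, object$w)
  probs <- predict_probs(object$layers, x,
                         batch = object$config$optimizer$batch_size)
  colnames(probs) <- object$class_levels
  if (type == "prob") return(probs)
  factor(object$class_levels[max.col(probs, ties.method = "first")],
         levels = object$class_levels)
}

predict_probs <- function(layers, x, batch = 256L) {
  B <- dim(x)[1]
  out <- matrix(0, B, 4L)
  i <- 1L
  while (i <= B) {
    j <- min(B, i + batch - 1L)
    r <- net_fwd(layers, x[i:j, , , drop = FALSE], train = FALSE)
    out[i:j, ] <- softmax_probs(r$out)
    i <- j + 1L
  }
  out
}

class_weights <- function(y, scheme) {
  lev <- expression_levels()
  cnt <- table(factor(y, levels = lev))
  w <- rep(1, 4)
  if (scheme == "inverse") {
    present <- cnt > 0
    w[present] <- sum(cnt) / (sum(present) * cnt[present])
    w[!present] <- 0
  }
  stats::setNames(w, lev)
}

#' Train an expression classifier
#'
#' Minimizes class-weighted cross-entropy with Adam, early-stopping on the
#' validation weighted F1 (patience from the config); the best-epoch weights
#' are restored. The history records per-epoch loss and weighted F1 for both
#' splits. Deterministic given the config seed.
#'
#' @param model an untrained (or trained) `femg_model`.
#' @param x `(B x w x 7)` array of training windows.
#' @param y expression labels (factor or character) of length B.
#' @param x_val,y_val validation split (required for early stopping; if
#'   omitted, trains for `max_epochs`).
#' @param verbose print per-epoch progress.
#' @return The trained `femg_model` with `$history` and `$best_epoch`.
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "femg_model"))
  y <- as_expression_factor(y)
  if (length(unique(y)) < 2) stop("need at least 2 classes in training labels")
  if (dim(x)[1] == 0) stop("empty training set")
  opt <- model$config$optimizer
  wts <- class_weights(y, model$config$class_weighting)
  yi <- as.integer(y)
  has_val <- !is.null(x_val)
  if (has_val) {
    y_val <- as_expression_factor(y_val)
    if (length(setdiff(levels(y), unique(as.character(y_val)))) > 0)
      warning("validation set is missing some class(es); ",
              "validation metrics computed over present classes")
    yv <- as.integer(y_val)
  }
  layers <- model$layers
  state <- adam_init(layers)
  n <- dim(x)[1]
  hist <- list()
  best <- list(score = -Inf, layers = layers, epoch = 0L)
  wait <- 0L
  step <- 0L
  with_seed(model$config$seed + 1L, {
    for (epoch in seq_len(opt$max_epochs)) {
      ord <- sample.int(n)
      i <- 1L
      while (i <= n) {
        j <- min(n, i + opt$batch_size - 1L)
        idx <- ord[i:j]
        fw <- net_fwd(layers, x[idx, , , drop = FALSE], train = TRUE)
        layers <- fw$layers
        sx <- softmax_xent(fw$out, yi[idx], wts)
        bk <- net_bwd(layers, fw$caches, sx$dlogits)
        step <- step + 1L
        up <- adam_step(layers, bk$grads, state, opt$lr, step)
        layers <- up$layers
        state <- up$state
        i <- j + 1L
      }
      ptr <- predict_probs(layers, x, opt$batch_size)
      tr_loss <- softmax_xent(log(ptr + 1e-12), yi, wts)$loss
      tr_pred <- expression_levels()[max.col(ptr, ties.method = "first")]
      tr_wf1 <- suppressWarnings(
        evaluate_classification(y, tr_pred)$weighted_f1)
      if (has_val) {
        pv <- predict_probs(layers, x_val, opt$batch_size)
        va_loss <- softmax_xent(log(pv + 1e-12), yv, wts)$loss
        va_pred <- expression_levels()[max.col(pv, ties.method = "first")]
        va_wf1 <- suppressWarnings(
          evaluate_classification(y_val, va_pred)$weighted_f1)
      } else {
        va_loss <- NA_real_; va_wf1 <- NA_real_
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                  val_loss = va_loss, train_wf1 = tr_wf1,
                                  val_wf1 = va_wf1)
      if (verbose)
        message(sprintf("epoch %3d loss %.4f wF1 %.3f | val %.4f / %.3f",
                        epoch, tr_loss, tr_wf1, va_loss, va_wf1))
      score <- if (has_val) va_wf1 else tr_wf1
      if (is.finite(score) && score > best$score + 1e-9) {
        best <- list(score = score, layers = layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (has_val && wait >= opt$patience) break
      }
    }
  })
  model$layers <- best$layers
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model
}

#' Classification metric suite
#'
#' Accuracy, macro and class-frequency-weighted precision/recall/F1, a
#' row-normalized 4x4 confusion matrix, and (when probabilities are given)
#' the macro one-vs-rest ROC-AUC. Macro metrics average over the classes
#' present in the truth (with a warning if any class is absent); the
#' precision of a never-predicted class is 0.
#'
#' @param true,pred equal-length label vectors over the 4 expression classes.
#' @param prob optional probability matrix (rows sum to 1, columns in
#'   canonical class order).
#' @return Object of class `femg_metrics`.
#' @export
evaluate_classification <- function(true, pred, prob = NULL) {
  true <- as_expression_factor(true)
  pred <- as_expression_factor(pred)
  if (length(true) != length(pred))
    stop("true and pred must have equal length")
  lev <- expression_levels()
  if (!is.null(prob)) {
    if (nrow(prob) != length(true)) stop("prob rows must match labels")
    if (any(abs(rowSums(prob) - 1) > 1e-6))
      stop("probability rows must sum to 1")
  }
  cm <- table(true = true, pred = pred)
  support <- rowSums(cm)
  present <- which(support > 0)
  if (length(present) < 4)
    warning("class(es) absent from truth: ",
            paste(lev[-present], collapse = ", "),
            "; macro metrics computed over present classes")
  tp <- diag(cm)
  prec <- rec <- f1 <- numeric(4)
  for (k in seq_len(4)) {
    pp <- sum(cm[, k])
    prec[k] <- if (pp > 0) tp[k] / pp else 0
    rec[k] <- if (support[k] > 0) tp[k] / support[k] else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  wts <- support[present] / sum(support)
  auc <- NA_real_
  if (!is.null(prob)) {
    aucs <- numeric(0)
    skipped <- character(0)
    for (k in seq_len(4)) {
      pos <- true == lev[k]
      if (any(pos) && any(!pos)) {
        r <- rank(prob[, k])
        np <- sum(pos); nn <- sum(!pos)
        aucs <- c(aucs, (sum(r[pos]) - np * (np + 1) / 2) / (np * nn))
      } else skipped <- c(skipped, lev[k])
    }
    if (length(skipped) > 0)
      warning("ROC-AUC undefined for class(es) ",
              paste(skipped, collapse = ", "), "; excluded from macro average")
    auc <- mean(aucs)
  }
  conf <- matrix(0, 4, 4, dimnames = dimnames(cm))
  conf[present, ] <- sweep(cm[present, , drop = FALSE], 1,
                           support[present], "/")
  structure(list(
    accuracy = mean(true == pred),
    macro_precision = mean(prec[present]),
    macro_recall = mean(rec[present]),
    macro_f1 = mean(f1[present]),
    weighted_precision = sum(prec[present] * wts),
    weighted_recall = sum(rec[present] * wts),
    weighted_f1 = sum(f1[present] * wts),
    roc_auc = auc,
    confusion = conf,
    per_class = data.frame(class = lev, precision = prec, recall = rec,
                           f1 = f1, support = as.integer(support))),
    class = "femg_metrics")
}

#' @export
print.femg_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | macro P/R/F1 %.4f/%.4f/%.4f | ",
                     "weighted F1 %.4f | ROC-AUC %s\n"),
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$weighted_f1,
              if (is.na(x$roc_auc)) "-" else sprintf("%.4f", x$roc_auc)))
  invisible(x)
}

metric_names <- function() {
  c("accuracy", "macro_precision", "macro_recall", "macro_f1",
    "weighted_precision", "weighted_recall", "weighted_f1", "roc_auc")
}

#' Leave-one-participant-out cross-validation
#'
#' Each participant's calibration windows are the test set exactly once;
#' within each fold the remaining participants are split participant-disjoint
#' into a validation subset (`val_participants` of them, rotating with the
#' fold index) and a training subset, so no window of a held-out participant
#' ever reaches a training or validation batch.
#'
#' @param windows calibration windows from [segment_windows()] (labeled).
#' @param config a [expression_model()] config.
#' @param val_participants validation participants per fold (default 2,
#'   reduced when few participants remain).
#' @param verbose print per-fold progress.
#' @return Object of class `femg_lopo`: per-fold metrics and participants,
#'   plus an `aggregate` mean/sd table over folds.
#' @export
lopo_cross_validate <- function(windows, config, val_participants = 2,
                                verbose = FALSE) {
  st <- stack_windows(windows)
  parts <- sort(unique(st$participant))
  if (length(parts) < 3)
    stop("LOPO needs >= 3 participants (train / validation / test)")
  folds <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p_test <- parts[i]
    rest <- setdiff(parts, p_test)
    nv <- min(val_participants, length(rest) - 1L)
    p_val <- rest[((i - 1L) + seq_len(nv) - 1L) %% length(rest) + 1L]
    p_train <- setdiff(rest, p_val)
    idx_tr <- st$participant %in% p_train
    idx_va <- st$participant %in% p_val
    idx_te <- st$participant == p_test
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", p_test)
    model <- build_model(cfg, st$w)
    model <- train_model(model, st$x[idx_tr, , , drop = FALSE],
                         st$y[idx_tr],
                         st$x[idx_va, , , drop = FALSE], st$y[idx_va])
    eval_split <- function(idx) {
      pr <- predict_probs(model$layers, st$x[idx, , , drop = FALSE])
      pred <- expression_levels()[max.col(pr, ties.method = "first")]
      suppressWarnings(evaluate_classification(st$y[idx], pred, pr))
    }
    folds[[i]] <- list(test_participant = p_test,
                       train_participants = p_train,
                       val_participants = p_val,
                       train = eval_split(idx_tr), val = eval_split(idx_va),
                       test = eval_split(idx_te))
    if (verbose)
      message(sprintf("fold %d/%d (%s): test macro-F1 %.3f", i,
                      length(parts), p_test, folds[[i]]$test$macro_f1))
  }
  agg <- lapply(c(train = "train", val = "val", test = "test"),
                function(split) {
    m <- sapply(metric_names(), function(nm)
      vapply(folds, function(f) f[[split]][[nm]], numeric(1)))
    data.frame(metric = metric_names(), mean = colMeans(m),
               sd = apply(m, 2, stats::sd), row.names = NULL)
  })
  structure(list(folds = folds, aggregate = agg, participants = parts,
                 config = config),
            class = "femg_lopo")
}

#' @export
print.femg_lopo <- function(x, ...) {
  cat("LOPO cross-validation over", length(x$folds), "participants\n")
  te <- x$aggregate$test
  for (nm in c("accuracy", "macro_f1", "weighted_f1", "roc_auc")) {
    r <- te[te$metric == nm, ]
    cat(sprintf("  test %-12s %.4f +/- %.4f\n", nm, r$mean, r$sd))
  }
  invisible(x)
}

#' Retrain the final shared model on the full calibration set
#'
#' After cross-validation the classifier is retrained on all participants'
#' calibration windows to produce the single shared inference model. A
#' seeded random window split (`val_frac`) is held out for early stopping
#' and for the reported training metrics.
#'
#' @param windows all calibration windows.
#' @param config a [expression_model()] config.
#' @param expected_participants optional vector; a warning is issued for any
#'   expected participant with no calibration windows.
#' @param val_frac held-out window fraction.
#' @return A trained `femg_model` with `$holdout_metrics`.
#' @export
retrain_full <- function(windows, config, expected_participants = NULL,
                         val_frac = 0.1) {
  st <- stack_windows(windows)
  if (!is.null(expected_participants)) {
    missing <- setdiff(expected_participants, unique(st$participant))
    if (length(missing) > 0)
      warning("no calibration windows for participant(s): ",
              paste(missing, collapse = ", "), "; proceeding without them")
  }
  n <- dim(st$x)[1]
  idx_val <- with_seed(derive_seed(config$seed, "retrain-split"),
                       sample.int(n, max(1L, round(val_frac * n))))
  idx_tr <- setdiff(seq_len(n), idx_val)
  cfg <- config
  cfg$seed <- derive_seed(config$seed, "retrain")
  model <- build_model(cfg, st$w)
  model <- train_model(model, st$x[idx_tr, , , drop = FALSE], st$y[idx_tr],
                       st$x[idx_val, , , drop = FALSE], st$y[idx_val])
  pr <- predict_probs(model$layers, st$x[idx_val, , , drop = FALSE])
  pred <- expression_levels()[max.col(pr, ties.method = "first")]
  model$holdout_metrics <- suppressWarnings(
    evaluate_classification(st$y[idx_val], pred, pr))
  model
}

#' Benchmark a baseline architecture under LOPO
#'
#' Runs the identical training/evaluation contract as the CNN-TCN for one of
#' the comparison architectures, enabling macro-F1 / macro-recall comparison
#' tables across architectures on the same cohort.
#'
#' @param architecture one of cnn, tcn, lstm, cnn-lstm, gru, cnn-tcn.
#' @param windows calibration windows.
#' @param config a [expression_model()] config (its architecture field is
#'   overridden).
#' @param ... passed to [lopo_cross_validate()].
#' @return A `femg_lopo` result.
#' @export
train_baseline <- function(architecture, windows, config, ...) {
  architecture <- match.arg(architecture,
                            c("cnn", "tcn", "lstm", "cnn-lstm", "gru",
                              "cnn-tcn"))
  config$architecture <- architecture
  lopo_cross_validate(windows, config, ...)
}
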