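#' Configuration for the vigilance-state MLP
#'
#' The network is fully connected: 210 input neurons (five 42-feature
#' epochs), one hidden layer of 512 rectified-linear units, and 3 softmax
#' output neurons, trained with cross-entropy until the validation loss
#' plateaus. Optimizer details are not part of the published architecture;
#' the defaults here (Adam, learning rate 1e-3, minibatch 256, one
#' validation check per pass, patience 10 checks) are exposed so they can
#' be changed.
#'
#' @param input_size,hidden_size,output_size Layer widths.
#' @param split_fractions Train/validation/test fractions; must sum to 1.
#' @param oversample Balance training classes by resampling minority
#'   classes with replacement (validation/test untouched).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param patience Validation checks without improvement before stopping.
#' @param max_iterations Maximum full passes over the training data.
#' @param min_delta Smallest validation-loss decrease that counts as an
#'   improvement.
#' @param seed Seed for initialization and batch shuffling.
#'
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(input_size = 210,
                       hidden_size = 512,
                       output_size = 3,
                       split_fractions = c(train = 0.64, validation = 0.16, test = 0.20),
                       oversample = TRUE,
                       learning_rate = 1e-3,
                       batch_size = 256,
                       patience = 10,
                       max_iterations = 60,
                       min_delta = 1e-5,
                       seed = 1) {
  split_fractions <- stats::setNames(as.numeric(unlist(split_fractions)),
                                     c("train", "validation", "test"))
  if (abs(sum(split_fractions) - 1) > 1e-9) {
    abort_validation("`split_fractions` must sum to 1.")
  }
  if (any(c(input_size, hidden_size, output_size, batch_size) <= 0)) {
    abort_validation("Layer and batch sizes must be positive.")
  }
  structure(
    list(
      input_size = input_size, hidden_size = hidden_size,
      output_size = output_size,
      split_fractions = split_fractions, oversample = oversample,
      learning_rate = learning_rate, batch_size = batch_size,
      patience = patience, max_iterations = max_iterations,
      min_delta = min_delta, seed = seed
    ),
    class = "mlp_config"
  )
}

#' Stratified train/validation/test split
#'
#' Partitions window samples into disjoint, exhaustive train (64%),
#' validation (16%) and test (20%) sets by default. Splitting is stratified
#' by label: the validation and test totals are fixed globally (rounded to
#' the nearest integer) and apportioned across classes by largest
#' remainder, with all remaining samples going to training, so 1000 samples
#' always split 640/160/200. Shuffling is seeded and reproducible.
#'
#' @param windows Window-sample tibble from [build_windows()] with a
#'   non-missing `label` column.
#' @param fractions Length-3 fractions (train, validation, test), sum 1.
#' @param seed Integer seed for the within-class shuffles.
#'
#' @return The input tibble with an added `split` factor column
#'   (train/validation/test), rows in original order.
#' @export
split_windows <- function(windows,
                          fractions = c(train = 0.64, validation = 0.16, test = 0.20),
                          seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) abort_validation("`fractions` must sum to 1.")
  n <- nrow(windows)
  if (n < 5) abort_validation("Need at least 5 samples to split.")
  lab <- as_state_factor(windows$label, "label")
  if (anyNA(lab)) abort_validation("All samples must be labeled to split.")

  n_val <- round(fractions[[2]] * n)
  n_test <- round(fractions[[3]] * n)

  class_n <- table(lab)
  alloc_val <- largest_remainder(as.numeric(class_n) / n * n_val, n_val)
  alloc_test <- largest_remainder(as.numeric(class_n) / n * n_test, n_test)

  split <- rep(NA_character_, n)
  withr::with_seed(seed, {
    for (ci in seq_along(class_n)) {
      idx <- which(as.integer(lab) == ci)
      idx <- idx[sample.int(length(idx))] # sample(idx) misbehaves at length 1
      nv <- alloc_val[ci]
      nt <- alloc_test[ci]
      if (nv + nt > length(idx)) {
        abort_validation(sprintf(
          "Class %s has too few samples (%d) for the requested split.",
          names(class_n)[ci], length(idx)
        ))
      }
      split[idx[seq_len(nv)]] <- "validation"
      split[idx[nv + seq_len(nt)]] <- "test"
      rest <- if (nv + nt > 0) idx[-seq_len(nv + nt)] else idx
      split[rest] <- "train"
    }
  })
  out <- windows
  out$split <- factor(split, levels = c("train", "validation", "test"))
  # Guard: at workable class sizes every class must appear in every split.
  if (all(class_n >= 50) &&
      any(table(lab, out$split) == 0)) {
    abort_validation("Stratification failed: a class is absent from a split.")
  }
  out
}

# Integer apportionment of `total` across classes proportional to `target`
# (largest-remainder / Hamilton method); deterministic.
largest_remainder <- function(target, total) {
  fl <- floor(target)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(target - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Oversample minority classes in the training split
#'
#' Balances the class distribution by resampling each minority class with
#' replacement until every class count equals the majority count. Apply to
#' the training split only; validation and test data must never be
#' resampled.
#'
#' @param train Labeled window-sample tibble (the training split).
#' @param seed Integer seed for the resampling draws.
#'
#' @return Tibble with equal class counts; original rows all retained.
#' @export
oversample_training <- function(train, seed = 1) {
  lab <- as_state_factor(train$label, "label")
  counts <- table(lab)
  present <- counts[counts > 0]
  if (length(present) < nlevels(lab)) {
    abort_validation(sprintf(
      "Cannot oversample: class(es) %s absent from the training data.",
      paste(setdiff(names(counts), names(present)), collapse = ", ")
    ))
  }
  target <- max(counts)
  extra <- integer(0)
  withr::with_seed(seed, {
    for (ci in seq_along(counts)) {
      need <- target - counts[[ci]]
      if (need > 0) {
        pool <- which(as.integer(lab) == ci)
        extra <- c(extra, pool[sample.int(length(pool), need, replace = TRUE)])
      }
    }
  })
  dplyr::bind_rows(train, train[extra, , drop = FALSE])
}

window_feature_cols <- function() sprintf("f%03d", seq_len(210))

# Extract the n x 210 feature matrix and integer labels from a window tibble.
window_matrix <- function(windows, config = NULL) {
  cols <- grep("^f[0-9]{3}$", names(windows), value = TRUE)
  x <- as.matrix(windows[, cols])
  if (!is.null(config) && ncol(x) != config$input_size) {
    abort_validation(sprintf(
      "Samples have %d features but the model expects %d.",
      ncol(x), config$input_size
    ))
  }
  x
}

#' Train the vigilance-state MLP
#'
#' Fits the fully connected 210-512-3 network (ReLU hidden layer, softmax
#' output) by minibatch Adam on the cross-entropy loss. Features are
#' z-scored with mean/sd fitted on the training split only (constant
#' features get sd 1); the same constants are stored in the model and
#' applied at prediction time. After every full pass the validation loss is
#' checked; training stops when it has failed to improve for `patience`
#' checks (the weights from the best check are kept) or at
#' `max_iterations` passes. Initialization and shuffling are seeded, so a
#' given (data, config) pair reproduces identical weights.
#'
#' @param train,validation Labeled window-sample tibbles (see
#'   [build_windows()], [split_windows()]).
#' @param config An [mlp_config()].
#'
#' @return An object of class `vigilance_mlp`: weights, standardization
#'   constants, config, and a training-history tibble.
#' @export
fit_vigilance_mlp <- function(train, validation, config = mlp_config()) {
  x_tr <- window_matrix(train, config)
  y_tr <- as.integer(as_state_factor(train$label, "label"))
  x_va <- window_matrix(validation, config)
  y_va <- as.integer(as_state_factor(validation$label, "label"))
  if (anyNA(y_tr) || anyNA(y_va)) abort_validation("Training labels must be complete.")

  mu <- colMeans(x_tr)
  sdv <- apply(x_tr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  x_tr <- scale(x_tr, center = mu, scale = sdv)
  x_va <- scale(x_va, center = mu, scale = sdv)

  d <- config$input_size; h <- config$hidden_size; k <- config$output_size
  withr::with_seed(config$seed, {
    w1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h) # He init for ReLU
    b1 <- numeric(h)
    w2 <- matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k)
    b2 <- numeric(k)
    adam <- adam_state(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2))

    n <- nrow(x_tr)
    y_onehot <- matrix(0, n, k)
    y_onehot[cbind(seq_len(n), y_tr)] <- 1

    best <- list(loss = Inf, w1 = w1, b1 = b1, w2 = w2, b2 = b2, pass = 0L)
    history <- vector("list", config$max_iterations)
    stale <- 0L
    for (pass in seq_len(config$max_iterations)) {
      ord <- sample.int(n)
      tr_loss <- 0
      for (lo in seq(1L, n, by = config$batch_size)) {
        idx <- ord[lo:min(lo + config$batch_size - 1L, n)]
        xb <- x_tr[idx, , drop = FALSE]
        yb <- y_onehot[idx, , drop = FALSE]
        a1 <- xb %*% w1
        a1 <- sweep(a1, 2, b1, `+`)
        z1 <- pmax(a1, 0)
        logits <- sweep(z1 %*% w2, 2, b2, `+`)
        p <- softmax_rows(logits)
        m <- length(idx)
        tr_loss <- tr_loss - sum(yb * log(pmax(p, 1e-12))) # accumulate
        if (!is.finite(tr_loss)) {
          rlang::abort("Non-finite training loss; try a smaller learning rate.",
                       class = "somnoscore_training_error")
        }
        dlogits <- (p - yb) / m
        gw2 <- crossprod(z1, dlogits)
        gb2 <- colSums(dlogits)
        dz1 <- dlogits %*% t(w2)
        dz1[a1 <= 0] <- 0
        gw1 <- crossprod(xb, dz1)
        gb1 <- colSums(dz1)
        upd <- adam_update(adam, list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2),
                           config$learning_rate)
        adam <- upd$state
        w1 <- w1 - upd$delta$w1; b1 <- b1 - upd$delta$b1
        w2 <- w2 - upd$delta$w2; b2 <- b2 - upd$delta$b2
      }
      va <- mlp_forward(x_va, w1, b1, w2, b2)
      va_loss <- -mean(log(pmax(va[cbind(seq_along(y_va), y_va)], 1e-12)))
      history[[pass]] <- tibble::tibble(
        pass = pass, train_loss = tr_loss / n, validation_loss = va_loss
      )
      if (va_loss < best$loss - config$min_delta) {
        best <- list(loss = va_loss, w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                     pass = pass)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })

  structure(
    list(
      w1 = best$w1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
      center = mu, scale = sdv, config = config,
      history = dplyr::bind_rows(history),
      best_pass = best$pass, best_validation_loss = best$loss,
      n_train = nrow(x_tr), n_validation = nrow(x_va),
      class_levels = vigilance_states()
    ),
    class = "vigilance_mlp"
  )
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

mlp_forward <- function(x, w1, b1, w2, b2) {
  z1 <- pmax(sweep(x %*% w1, 2, b1, `+`), 0)
  softmax_rows(sweep(z1 %*% w2, 2, b2, `+`))
}

# Minimal Adam optimizer over a named list of parameter arrays.
adam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L, beta1 = beta1, beta2 = beta2, eps = eps
  )
}

adam_update <- function(state, grads, lr) {
  state$t <- state$t + 1L
  delta <- vector("list", length(grads))
  names(delta) <- names(grads)
  for (nm in names(grads)) {
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * grads[[nm]]
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - state$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - state$beta2^state$t)
    delta[[nm]] <- lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, delta = delta)
}

#' Predict vigilance states for window samples
#'
#' Applies the stored standardization and network to each 210-feature
#' sample and returns the argmax of the softmax output (an exact
#' probability tie resolves to the lowest class index, i.e. WAKE before
#' NREM before REM).
#'
#' @param object A fitted `vigilance_mlp`.
#' @param newdata Window-sample tibble.
#' @param type `"state"` for a factor of labels, `"prob"` for a tibble of
#'   class probabilities.
#' @param ... Unused.
#'
#' @return Factor of predicted states, or a probability tibble.
#' @export
predict.vigilance_mlp <- function(object, newdata, type = c("state", "prob"), ...) {
  type <- match.arg(type)
  x <- window_matrix(newdata, object$config)
  x <- scale(x, center = object$center, scale = object$scale)
  p <- mlp_forward(x, object$w1, object$b1, object$w2, object$b2)
  colnames(p) <- object$class_levels
  if (type == "prob") return(tibble::as_tibble(p))
  idx <- max.col(p, ties.method = "first")
  factor(object$class_levels[idx], levels = object$class_levels)
}

#' Score a full recording's features into a per-epoch hypnogram
#'
#' Builds the 5-epoch windows from a per-epoch feature table, predicts each
#' window's state, and assigns every epoch the label of the window centered
#' on it. The first two and last two epochs, which have no centered window,
#' inherit the nearest window's label.
#'
#' @param model A fitted `vigilance_mlp`.
#' @param features Per-epoch feature tibble from [featurize_recording()].
#'
#' @return Hypnogram tibble (`epoch`, `zt`, `state`).
#' @export
predict_hypnogram <- function(model, features) {
  windows <- build_windows(features)
  pred <- predict(model, windows)
  n <- nrow(features)
  state <- pred[pmin(pmax(seq_len(n) - 2L, 1L), length(pred))]
  tibble::tibble(epoch = features$epoch, zt = features$zt, state = state)
}

#' Evaluate a classifier on held-out samples
#'
#' Computes accuracy, per-class and macro F1 (F1 = 2PR/(P+R), defined as 0
#' when precision + recall is 0), and the 3x3 confusion matrix (rows =
#' true state, columns = predicted).
#'
#' @param model A fitted `vigilance_mlp`.
#' @param test Labeled window-sample tibble, disjoint from training.
#'
#' @return An object of class `classifier_evaluation` with fields
#'   `accuracy`, `f1` (named per-class vector), `macro_f1`,
#'   `confusion` (matrix) and `n`.
#' @export
evaluate_classifier <- function(model, test) {
  if (nrow(test) == 0) abort_validation("Test set is empty.")
  truth <- as_state_factor(test$label, "label")
  pred <- predict(model, test)
  confusion_evaluation(truth, pred)
}

# Shared metric computation from truth/prediction factors.
confusion_evaluation <- function(truth, pred) {
  lv <- vigilance_states()
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(true = lv, predicted = lv))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- lv
  structure(
    list(
      accuracy = sum(tp) / sum(cm),
      f1 = f1,
      macro_f1 = mean(f1),
      confusion = cm,
      n = sum(cm)
    ),
    class = "classifier_evaluation"
  )
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> n = %d, accuracy = %.4f, macro F1 = %.4f\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @export
print.vigilance_mlp <- function(x, ...) {
  cat(sprintf(
    "<vigilance_mlp> %d-%d-%d, best validation loss %.4f at pass %d (of %d run)\n",
    x$config$input_size, x$config$hidden_size, x$config$output_size,
    x$best_validation_loss, x$best_pass, nrow(x$history)
  ))
  invisible(x)
}
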