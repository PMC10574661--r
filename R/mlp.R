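#' Fully connected feed-forward network (multilayer perceptron)
#'
#' A four-hidden-layer (by default) ReLU network trained with the Adam
#' optimizer at learning rate 1e-4, for binary classification (sigmoid
#' output, cross-entropy loss) or regression (linear output, squared loss).
#' The training epoch count is chosen by early stopping inside repeated
#' 5-fold cross-validation: each fold trains with a patience of
#' `patience` epochs on validation accuracy (classification) or validation
#' MSE (regression), the best epoch of each fold is recorded, and the final
#' model is refit on the full data for the median of those epochs. All
#' random draws (weight init, shuffling, fold assignment) are seeded.
#'
#' @param x numeric training matrix.
#' @param y factor (high/weak) or numeric response.
#' @param hidden hidden-layer widths (default `c(256, 128, 64, 32)`).
#' @param learning_rate Adam step size (default 1e-4).
#' @param patience early-stopping patience in epochs (default 50).
#' @param max_epochs hard epoch cap (default 500).
#' @param batch_size mini-batch size (default 32).
#' @param epoch_repeats repeats of the 5-fold epoch-selection loop
#'   (default 5; raise to 50 to run the heavier protocol).
#' @param cv_folds folds in the epoch-selection loop (default 5).
#' @param seed integer seed.
#' @return object of class `mlp_net`.
#' @export
mlp_fit <- function(x, y, hidden = c(256, 128, 64, 32),
                    learning_rate = 1e-4, patience = 50L, max_epochs = 500L,
                    batch_size = 32L, epoch_repeats = 5L, cv_folds = 5L,
                    seed = 1L) {
  task <- if (is.factor(y)) "classification" else "regression"
  yt <- if (task == "classification") as.numeric(y == "high") else y
  x <- as.matrix(x)

  best_epochs <- integer(0)
  for (r in seq_len(epoch_repeats)) {
    fold <- make_folds(y, cv_folds, seed = seed + 7000L * r)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      res <- mlp_train(x[tr, , drop = FALSE], yt[tr], task, hidden,
                       learning_rate, batch_size,
                       max_epochs = max_epochs, patience = patience,
                       x_val = x[!tr, , drop = FALSE], y_val = yt[!tr],
                       seed = seed + 131L * r + f)
      best_epochs <- c(best_epochs, res$best_epoch)
    }
  }
  epochs <- max(1L, round_half_up(stats::median(best_epochs)))
  final <- mlp_train(x, yt, task, hidden, learning_rate, batch_size,
                     max_epochs = epochs, patience = Inf, seed = seed)
  structure(list(weights = final$weights, biases = final$biases,
                 task = task, hidden = hidden, epochs = epochs,
                 best_epochs = best_epochs, features = colnames(x),
                 learning_rate = learning_rate, seed = seed),
            class = "mlp_net")
}

# core training loop; returns weights at the best validation epoch (when a
# validation set is given) or at the last epoch otherwise
mlp_train <- function(x, y, task, hidden, lr, batch_size, max_epochs,
                      patience, x_val = NULL, y_val = NULL, seed = 1L) {
  set.seed(seed)
  n <- nrow(x)
  dims <- c(ncol(x), hidden, 1L)
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  mW <- vW <- W; mb <- vb <- b
  for (l in seq_len(L)) {
    sd0 <- sqrt(2 / dims[l])  # He initialization for ReLU layers
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], 0, sd0),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
    mW[[l]] <- vW[[l]] <- matrix(0, dims[l], dims[l + 1L])
    mb[[l]] <- vb[[l]] <- rep(0, dims[l + 1L])
  }
  beta1 <- 0.9; beta2 <- 0.999; epsad <- 1e-8
  step <- 0L
  best_metric <- Inf; best_epoch <- 1L; bad <- 0L
  bw <- W; bb <- b
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      # forward
      A <- vector("list", L + 1L); A[[1L]] <- xb
      for (l in seq_len(L)) {
        z <- A[[l]] %*% W[[l]]
        z <- sweep(z, 2L, b[[l]], "+")
        A[[l + 1L]] <- if (l < L) pmax(z, 0) else z
      }
      out <- A[[L + 1L]][, 1L]
      if (task == "classification") out <- stats::plogis(out)
      if (any(!is.finite(out))) stop("non-finite network output; ",
                                     "lower the learning rate")
      # backward: both losses give delta = (out - y) at the output
      delta <- matrix((out - yb) / length(yb), ncol = 1L)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mh <- mW[[l]] / (1 - beta1^step); vh <- vW[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mh / (sqrt(vh) + epsad)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + epsad)
      }
    }
    if (!is.null(x_val)) {
      pv <- mlp_forward(W, b, task, x_val)
      metric <- if (task == "classification") {
        mean((pv >= 0.5) != (y_val == 1))  # 1 - accuracy
      } else {
        mean((pv - y_val)^2)
      }
      if (metric < best_metric - 1e-12) {
        best_metric <- metric; best_epoch <- epoch; bad <- 0L
        bw <- W; bb <- b
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    } else {
      bw <- W; bb <- b; best_epoch <- epoch
    }
  }
  list(weights = bw, biases = bb, best_epoch = best_epoch)
}

mlp_forward <- function(W, b, task, x) {
  A <- as.matrix(x)
  L <- length(W)
  for (l in seq_len(L)) {
    z <- sweep(A %*% W[[l]], 2L, b[[l]], "+")
    A <- if (l < L) pmax(z, 0) else z
  }
  out <- A[, 1L]
  if (task == "classification") stats::plogis(out) else out
}

#' Predict from a fitted multilayer perceptron
#'
#' @param object an `mlp_net`.
#' @param newx numeric matrix.
#' @return positive-class probabilities (classification) or numeric
#'   predictions (regression).
#' @export
mlp_predict <- function(object, newx) {
  newx <- as.matrix(newx)
  if (!is.null(object$features)) {
    newx <- newx[, object$features, drop = FALSE]
  }
  mlp_forward(object$weights, object$biases, object$task, newx)
}

#' @export
print.mlp_net <- function(x, ...) {
  cat("<mlp_net> ", x$task, ", layers ", paste(x$hidden, collapse = "-"),
      ", trained ", x$epochs, " epochs (median of ",
      length(x$best_epochs), " CV stops)\n", sep = "")
  invisible(x)
}
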