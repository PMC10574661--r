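#' Stacked generalization over fingerprint-specific classifiers
#'
#' Combines classification models built with the same algorithm but on
#' different fingerprint representations of the same training molecules: the
#' base models' positive-class probabilities become meta-features for a
#' logistic-regression meta-learner. By default the meta-features are
#' out-of-fold probabilities (each base configuration is refit on k-1 folds
#' and predicts the held-out fold), which keeps the meta-learner from seeing
#' its own training predictions; `oof = FALSE` instead uses the fitted base
#' models' in-sample probabilities.
#'
#' @param base_models named list of `qsar_model` classifiers, one per
#'   fingerprint kind, all trained on the same molecules.
#' @param x_list named list of training `feature_matrix` objects, names
#'   matching `base_models`.
#' @param y training labels (factor high/weak).
#' @param folds folds for out-of-fold probability generation (default 5).
#' @param seed integer seed.
#' @param oof use out-of-fold meta-features (default TRUE).
#' @return object of class `qsar_stack`.
#' @export
qsar_stack <- function(base_models, x_list, y, folds = 5L, seed = 1L,
                       oof = TRUE) {
  stopifnot(length(base_models) >= 2L,
            identical(sort(names(base_models)), sort(names(x_list))))
  y <- factor(as.character(y), levels = c("high", "weak"))
  n <- length(y)
  for (nm in names(base_models)) {
    if (base_models[[nm]]$task != "classification") {
      stop("stacking is defined for classifiers only")
    }
    if (nrow(x_list[[nm]]) != n) stop("x_list/y size mismatch for ", nm)
  }
  meta <- matrix(NA_real_, n, length(base_models),
                 dimnames = list(NULL, names(base_models)))
  if (oof) {
    fold <- make_folds(y, folds, seed = seed + 99L)
    for (nm in names(base_models)) {
      bm <- base_models[[nm]]
      xm <- unclass(x_list[[nm]])[, bm$features, drop = FALSE]
      for (f in seq_len(folds)) {
        tr <- fold != f
        refit <- fit_single(bm$algorithm, "classification",
                            bm$hyperparameters, xm[tr, , drop = FALSE],
                            y[tr], seed = seed + f)
        meta[!tr, nm] <- predict_single(refit, xm[!tr, , drop = FALSE],
                                        type = "prob")
      }
    }
  } else {
    for (nm in names(base_models)) {
      meta[, nm] <- predict(base_models[[nm]], x_list[[nm]], type = "prob")
    }
  }
  df <- data.frame(.y = as.numeric(y == "high"), meta)
  glm_fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  structure(list(base_models = base_models,
                 coefficients = stats::coef(glm_fit),
                 oof = oof, folds = folds, seed = seed, n_train = n),
            class = "qsar_stack")
}

#' Predict from a stacked ensemble
#'
#' @param object a `qsar_stack`.
#' @param newdata named list of `feature_matrix` objects, one per base
#'   fingerprint kind (names matching the base models).
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor (high/weak) or probabilities; label = probability >= 0.5.
#' @export
predict.qsar_stack <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  nms <- names(object$base_models)
  miss <- setdiff(nms, names(newdata))
  if (length(miss)) stop("newdata is missing fingerprint(s): ",
                         paste(miss, collapse = ", "))
  P <- vapply(nms, function(nm)
    predict(object$base_models[[nm]], newdata[[nm]], type = "prob"),
    numeric(nrow(newdata[[nms[1L]]])))
  P <- matrix(P, ncol = length(nms), dimnames = list(NULL, nms))
  co <- object$coefficients
  eta <- co[1L] + P %*% co[-1L]
  prob <- as.numeric(stats::plogis(eta))
  # guard against numerically degenerate meta-fits (perfect separation)
  prob[is.na(prob)] <- rowMeans(P)[is.na(prob)]
  if (type == "prob") return(prob)
  factor(ifelse(prob >= 0.5, "high", "weak"), levels = c("high", "weak"))
}

#' @export
print.qsar_stack <- function(x, ...) {
  cat("<qsar_stack> ", length(x$base_models), " base ",
      x$base_models[[1L]]$algorithm, " classifiers (",
      paste(names(x$base_models), collapse = ", "), ")\n", sep = "")
  cat("meta coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}
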