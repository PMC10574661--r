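#' Default hyperparameter grids
#'
#' Grid-search ranges for the four supervised model families. All values are
#' configuration, not claims about any external benchmark; pass a reduced
#' grid for quick runs.
#'
#' @param algorithm `"svm_rbf"`, `"random_forest"`, `"grad_boost"` or
#'   `"dnn"`.
#' @param task `"classification"` or `"regression"`.
#' @return data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm = c("svm_rbf", "random_forest",
                                       "grad_boost", "dnn"),
                         task = c("classification", "regression")) {
  algorithm <- match.arg(algorithm)
  task <- match.arg(task)
  switch(algorithm,
    svm_rbf = if (task == "classification") {
      expand.grid(C = c(0.1, 1, 10, 100), gamma = c(1e-3, 1e-2, 1e-1, 1))
    } else {
      expand.grid(C = c(0.1, 1, 10, 100), gamma = c(1e-3, 1e-2, 1e-1, 1),
                  epsilon = c(0.01, 0.1, 0.2))
    },
    random_forest = expand.grid(n_estimators = c(100, 300, 500),
                                max_leaf_nodes = c(32, 128, 512, Inf)),
    grad_boost = expand.grid(n_estimators = c(100, 300, 500),
                             max_depth = c(3, 6, 9),
                             subsample = c(0.6, 0.8, 1),
                             colsample_bytree = c(0.6, 0.8, 1)),
    dnn = expand.grid(learning_rate = 1e-4)
  )
}

# stratified CV fold ids (classification: per class; regression: per
# response-quantile bin)
make_folds <- function(y, k, seed) {
  n <- length(y)
  strata <- if (is.factor(y)) y else {
    qs <- unique(stats::quantile(y, probs = seq(0, 1, length.out = 6)))
    if (length(qs) < 2L) factor(rep(1L, n))
    else cut(y, breaks = qs, include.lowest = TRUE)
  }
  set.seed(seed)
  fold <- integer(n)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit a tuned QSAR model
#'
#' The central fitting function: grid search with repeated stratified k-fold
#' cross-validation over `grid` (and, for regression with a descriptor
#' `ranking`, over the number of top-ranked descriptors), selection by the
#' smallest mean CV mean-squared-error (regression) or the largest mean CV
#' Matthews correlation coefficient (classification), then a final refit of
#' the chosen configuration on the full training matrix. Fully seeded and
#' deterministic: the same inputs and seed give the same chosen model.
#'
#' Backends: `svm_rbf` = e1071 (RBF kernel), `random_forest` =
#' randomForest (max_leaf_nodes via `maxnodes`), `grad_boost` = xgboost,
#' `dnn` = the package's four-hidden-layer ReLU/Adam multilayer perceptron
#' (see [mlp_fit()]).
#'
#' @param x training `feature_matrix` (already filtered/scaled; fitted on
#'   the training partition only).
#' @param y response: factor with levels `high`/`weak` for classification,
#'   numeric pIC50 for regression.
#' @param algorithm model family.
#' @param grid hyperparameter grid (data.frame); default [default_grid()].
#' @param n_descriptors integer vector of top-k descriptor counts to include
#'   in the grid (regression; requires `ranking`).
#' @param ranking feature names ranked most- to least-important (from
#'   [rfrfe_rank()]).
#' @param cv_folds,cv_repeats cross-validation protocol (default 5 x 10).
#' @param seed integer seed.
#' @param featurization_id tag recording which featurization produced `x`
#'   (e.g. `"ecfp4_1024"`); used by the screening cascade.
#' @param scaler optional `scaler_params` already applied to `x`, stored for
#'   reuse on new molecules.
#' @param dnn_control list of extra settings for the `dnn` family (see
#'   [mlp_fit()] arguments `hidden`, `patience`, `max_epochs`,
#'   `epoch_repeats`, `batch_size`).
#' @return object of class `qsar_model`.
#' @seealso [predict.qsar_model()], [evaluate_model()], [qsar_stack()]
#' @export
qsar_fit <- function(x, y, algorithm = c("svm_rbf", "random_forest",
                                         "grad_boost", "dnn"),
                     grid = NULL, n_descriptors = NULL, ranking = NULL,
                     cv_folds = 5L, cv_repeats = 10L, seed = 1L,
                     featurization_id = NA_character_, scaler = NULL,
                     dnn_control = list()) {
  algorithm <- match.arg(algorithm)
  task <- if (is.factor(y)) "classification" else "regression"
  if (task == "classification") {
    y <- factor(as.character(y), levels = c("high", "weak"))
    if (any(table(y) == 0L)) stop("training labels must contain both classes")
  }
  stopifnot(nrow(x) == length(y), cv_folds >= 2L)
  if (is.null(grid)) grid <- default_grid(algorithm, task)
  stopifnot(nrow(grid) >= 1L)
  if (!is.null(n_descriptors)) {
    if (is.null(ranking)) stop("n_descriptors requires a ranking")
    n_descriptors <- pmin(as.integer(n_descriptors), ncol(x))
    grid <- merge(grid, data.frame(n_desc = sort(unique(n_descriptors))))
  }
  xm <- unclass(x)

  cv_scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    cols <- if (!is.null(params$n_desc))
      intersect(ranking, colnames(xm))[seq_len(params$n_desc)]
      else colnames(xm)
    per_fold <- numeric(0)
    for (r in seq_len(cv_repeats)) {
      fold <- make_folds(y, cv_folds, seed = seed + 1000L * r)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        fit <- fit_single(algorithm, task, params,
                          xm[tr, cols, drop = FALSE], y[tr],
                          seed = seed + r, dnn_control = dnn_control)
        pred <- predict_single(fit, xm[!tr, cols, drop = FALSE])
        per_fold <- c(per_fold, if (task == "regression") {
          mean((y[!tr] - pred)^2)
        } else {
          mcc(confusion(y[!tr], pred))
        })
      }
    }
    cv_scores[g] <- mean(per_fold)
  }
  best <- if (task == "regression") which.min(cv_scores) else
    which.max(cv_scores)
  params <- as.list(grid[best, , drop = FALSE])
  cols <- if (!is.null(params$n_desc))
    intersect(ranking, colnames(xm))[seq_len(params$n_desc)]
    else colnames(xm)
  fit <- fit_single(algorithm, task, params, xm[, cols, drop = FALSE], y,
                    seed = seed, dnn_control = dnn_control)
  structure(list(
    algorithm = algorithm, task = task,
    hyperparameters = params,
    cv_table = cbind(grid, cv_score = cv_scores),
    cv_metric = if (task == "regression") "mse" else "mcc",
    fit = fit, features = cols,
    featurization_id = featurization_id, scaler = scaler,
    n_train = nrow(xm), seed = seed
  ), class = "qsar_model")
}

# one estimator fit; returns a list(backend, object, task) consumed by
# predict_single
fit_single <- function(algorithm, task, params, x, y, seed,
                       dnn_control = list()) {
  set.seed(seed)
  obj <- switch(algorithm,
    svm_rbf = e1071::svm(
      x = x, y = y,
      type = if (task == "classification") "C-classification"
             else "eps-regression",
      kernel = "radial", cost = params$C, gamma = params$gamma,
      epsilon = if (is.null(params$epsilon)) 0.1 else params$epsilon,
      probability = task == "classification", scale = FALSE),
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = params$n_estimators,
      maxnodes = if (is.finite(params$max_leaf_nodes))
        params$max_leaf_nodes else NULL),
    grad_boost = {
      lab <- if (task == "classification") as.numeric(y == "high") else y
      dm <- xgboost::xgb.DMatrix(x, label = lab)
      xgboost::xgb.train(
        params = list(
          objective = if (task == "classification") "binary:logistic"
                      else "reg:squarederror",
          max_depth = params$max_depth,
          subsample = if (is.null(params$subsample)) 1 else params$subsample,
          colsample_bytree = if (is.null(params$colsample_bytree)) 1
                             else params$colsample_bytree,
          nthread = 1, seed = seed),
        data = dm, nrounds = params$n_estimators, verbose = 0)
    },
    dnn = do.call(mlp_fit, c(list(x = x, y = y, seed = seed,
      learning_rate = if (is.null(params$learning_rate)) 1e-4
                      else params$learning_rate), dnn_control))
  )
  list(backend = algorithm, object = obj, task = task,
       features = colnames(x))
}

predict_single <- function(fit, newx, type = c("class", "prob")) {
  type <- match.arg(type)
  newx <- newx[, fit$features, drop = FALSE]
  if (fit$task == "regression") {
    return(switch(fit$backend,
      svm_rbf = as.numeric(stats::predict(fit$object, newx)),
      random_forest = as.numeric(stats::predict(fit$object, newx)),
      grad_boost = as.numeric(stats::predict(fit$object,
                                             xgboost::xgb.DMatrix(newx))),
      dnn = mlp_predict(fit$object, newx)))
  }
  prob <- switch(fit$backend,
    svm_rbf = {
      p <- stats::predict(fit$object, newx, probability = TRUE)
      attr(p, "probabilities")[, "high"]
    },
    random_forest = stats::predict(fit$object, newx, type = "prob")[, "high"],
    grad_boost = as.numeric(stats::predict(fit$object,
                                           xgboost::xgb.DMatrix(newx))),
    dnn = mlp_predict(fit$object, newx))
  if (type == "prob") return(as.numeric(prob))
  factor(ifelse(prob >= 0.5, "high", "weak"), levels = c("high", "weak"))
}

#' Predict from a fitted QSAR model
#'
#' Applies the model's stored featurization contract: the new feature matrix
#' is subset to the model's features (and range-scaled with the model's
#' stored scaler when the matrix is raw). Prediction on a matrix whose
#' features do not cover the model's feature list is an error.
#'
#' @param object a `qsar_model`.
#' @param newdata `feature_matrix` or numeric matrix with named columns.
#' @param type `"class"` (default for classification; factor high/weak),
#'   `"prob"` (positive-class probability), or `"response"` (numeric
#'   prediction, regression).
#' @param ... unused.
#' @export
predict.qsar_model <- function(object, newdata,
                               type = c("class", "prob", "response"), ...) {
  type <- match.arg(type)
  newx <- prepare_newx(object, newdata)
  if (object$task == "regression" || type == "response") {
    if (object$task == "classification") stop(
      "type='response' is for regression models")
    return(predict_single(object$fit, newx))
  }
  predict_single(object$fit, newx, type = type)
}

prepare_newx <- function(object, newdata) {
  newx <- if (inherits(newdata, "feature_matrix")) unclass(newdata)
          else as.matrix(newdata)
  prov <- attr(newdata, "provenance")
  already_scaled <- any(grepl("autoscale", if (is.null(prov)) "" else prov))
  if (!is.null(object$scaler) && !already_scaled) {
    sc <- object$scaler
    miss <- setdiff(sc$features, colnames(newx))
    if (length(miss)) {
      stop("newdata lacks ", length(miss), " feature(s) of the model's ",
           "scaler: ", paste(utils::head(miss, 3L), collapse = ", "))
    }
    fmn <- feature_matrix(newx[, sc$features, drop = FALSE],
                          kind = "descriptor")
    newx <- unclass(autoscale_apply(fmn, sc))
  }
  missing <- setdiff(object$features, colnames(newx))
  if (length(missing)) {
    stop("newdata lacks ", length(missing), " model feature(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  newx
}

#' Evaluate a model on labeled data
#'
#' @param object a `qsar_model`.
#' @param x `feature_matrix` of the evaluation partition.
#' @param y true labels (factor high/weak) or pIC50 values.
#' @return named list: `Q` and `MCC` (classification) or `R2` and `RMSE`
#'   (regression).
#' @export
evaluate_model <- function(object, x, y) {
  if (object$task == "classification") {
    cc <- confusion(y, predict(object, x, type = "class"))
    list(Q = q_accuracy(cc), MCC = mcc(cc))
  } else {
    pred <- predict(object, x)
    list(R2 = r2(y, pred), RMSE = rmse(y, pred))
  }
}

#' @export
print.qsar_model <- function(x, ...) {
  hp <- x$hyperparameters
  hp <- hp[!vapply(hp, is.null, TRUE)]
  cat("<qsar_model> ", x$algorithm, " (", x$task, "), ",
      length(x$features), " features, n=", x$n_train, "\n", sep = "")
  cat("chosen:", paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
      "\n")
  cat("CV ", x$cv_metric, " (", nrow(x$cv_table), "-point grid): best = ",
      signif(x$cv_table$cv_score[best_row(x)], 4), "\n", sep = "")
  invisible(x)
}

best_row <- function(x) {
  if (x$cv_metric == "mse") which.min(x$cv_table$cv_score)
  else which.max(x$cv_table$cv_score)
}

#' @export
summary.qsar_model <- function(object, ...) {
  print(object)
  cat("\nCV grid:\n")
  print(object$cv_table)
  invisible(object)
}

#' Factorial experiment grid
#'
#' Enumerates one modeling job per (dataset, repeat, featurization,
#' algorithm) combination — the full factorial design used to count and
#' organize model-building runs (e.g. 4 datasets x 10 repeats x 3
#' fingerprints x 4 algorithms = 480 classification models).
#'
#' @param datasets,featurizations,algorithms character vectors of ids.
#' @param n_repeats number of random splits per dataset.
#' @return data.frame with one row per job, in stable
#'   dataset/repeat/featurization/algorithm order.
#' @export
experiment_grid <- function(datasets, featurizations, algorithms,
                            n_repeats = 10L) {
  stopifnot(length(datasets) > 0, length(featurizations) > 0,
            length(algorithms) > 0, n_repeats >= 1L)
  g <- expand.grid(algorithm = algorithms, featurization = featurizations,
                   repeat_idx = seq_len(n_repeats), dataset = datasets,
                   stringsAsFactors = FALSE)
  g <- g[, c("dataset", "repeat_idx", "featurization", "algorithm")]
  g <- g[order(match(g$dataset, datasets), g$repeat_idx,
               match(g$featurization, featurizations),
               match(g$algorithm, algorithms)), , drop = FALSE]
  rownames(g) <- NULL
  g
}
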