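#' End-to-end synthetic recovery benchmark
#'
#' Runs the whole pipeline on the default synthetic study
#' ([generate_benchmark()] with a 2000-molecule labeled set) and measures how
#' well each stage recovers the planted structure-activity signal:
#' fingerprint classifiers (RBF-SVM and gradient boosting on all three
#' fingerprint kinds) with an 80/20 stratified split, a stacked ensemble of
#' the gradient-boosting classifiers, descriptor regressors on functional
#' group counts, a 10 x 11 self-organizing map, and the full screening
#' cascade against the ground-truth table. Tuning grids are deliberately
#' small so the benchmark runs in minutes on one CPU; every random draw
#' derives from `seed`.
#'
#' @param seed integer seed driving data generation, splitting, tuning and
#'   SOM training.
#' @param n_train,n_external,n_screen study sizes (defaults 2000/400/1000).
#' @return list with per-stage metrics: `classifier_mcc` (named per
#'   fingerprint/algorithm), `stack_mcc`, `stack_delta_vs_best_base`,
#'   `regressor_rmse` (named), `cascade_recall`,
#'   `inactive_passthrough`, plus the fitted components (invisible parts:
#'   `result`, `truth`).
#' @export
run_recovery_benchmark <- function(seed = 1L, n_train = 2000L,
                                   n_external = 400L, n_screen = 1000L) {
  seed <- as.integer(seed)
  spec <- synthetic_spec(n_molecules = n_train, seed = seed)
  bench <- generate_benchmark(spec, n_external = n_external,
                              n_screen = n_screen)
  ds <- activity_dataset(bench$train, task = "classification",
                         scheme = bench$scheme)
  sp <- stratified_split(ds, 0.2, seed = seed)

  kinds <- c("maccs166", "path1024", "ecfp4_1024")
  grids <- list(
    svm_rbf = expand.grid(C = c(1, 10), gamma = 0.01),
    grad_boost = expand.grid(n_estimators = 150, max_depth = c(3, 5),
                             subsample = 1, colsample_bytree = 1))
  classifiers <- list()
  classifier_mcc <- c()
  fm_train <- list(); fm_test <- list()
  for (k in kinds) {
    fm <- fingerprints(ds, k)
    tr <- variance_filter(
      feature_matrix(unclass(fm)[sp$train, , drop = FALSE], "fingerprint"))
    te <- feature_matrix(
      unclass(fm)[sp$test, colnames(tr), drop = FALSE], "fingerprint")
    fm_train[[k]] <- tr; fm_test[[k]] <- te
    for (alg in names(grids)) {
      m <- qsar_fit(tr, ds$label[sp$train], alg, grid = grids[[alg]],
                    cv_repeats = 1L, seed = seed, featurization_id = k)
      classifiers[[paste(k, alg, sep = "/")]] <- m
      ev <- evaluate_model(m, te, ds$label[sp$test])
      classifier_mcc[paste(k, alg, sep = "/")] <- ev$MCC
    }
  }

  # stacked ensemble of the three gradient-boosting base classifiers
  gb <- classifiers[paste(kinds, "grad_boost", sep = "/")]
  names(gb) <- kinds
  st <- qsar_stack(gb, fm_train, ds$label[sp$train], seed = seed)
  st_pred <- predict(st, fm_test, type = "class")
  stack_mcc <- mcc(confusion(ds$label[sp$test], st_pred))
  best_base <- max(classifier_mcc[paste(kinds, "grad_boost", sep = "/")])

  # descriptor regressors on pIC50
  dfm <- descriptors(bench$train, "fragment_counts")
  dtr <- feature_matrix(unclass(dfm)[sp$train, , drop = FALSE], "descriptor")
  dtr <- pcc_filter(dtr, bench$train$pic50[sp$train], r_cut = 0.95)
  sc <- autoscale_fit(dtr)
  dtr_s <- autoscale_apply(dtr, sc)
  dte <- feature_matrix(
    unclass(dfm)[sp$test, colnames(dtr), drop = FALSE], "descriptor")
  dte_s <- autoscale_apply(dte, sc)
  rank <- rfrfe_rank(dtr_s, bench$train$pic50[sp$train], seed = seed,
                     num_trees = 200L)
  reg_grids <- list(
    grad_boost = expand.grid(n_estimators = 200, max_depth = 4,
                             subsample = 1, colsample_bytree = 1),
    svm_rbf = expand.grid(C = 10, gamma = 0.1, epsilon = 0.1))
  regressors <- list()
  regressor_rmse <- c()
  for (alg in names(reg_grids)) {
    m <- qsar_fit(dtr_s, bench$train$pic50[sp$train], alg,
                  grid = reg_grids[[alg]],
                  n_descriptors = c(10L, ncol(dtr_s)), ranking = rank,
                  cv_repeats = 1L, seed = seed,
                  featurization_id = "fragment_counts", scaler = sc)
    regressors[[alg]] <- m
    regressor_rmse[alg] <- rmse(bench$train$pic50[sp$test],
                                predict(m, dte_s))
  }

  # SOM on the full labeled set, ECFP4 features
  som <- som_fit(fingerprints(ds, "ecfp4_1024"), ds$label,
                 width = 10L, height = 11L, epochs = 10L, seed = seed)

  aggs <- suppressMessages(load_aggregators(
    system.file("extdata", "aggregators_synthetic.csv",
                package = "vscascade")))
  res <- run_cascade(bench$screen, classifiers, regressors, som = som,
                     aggregators = aggs, config = cascade_config())
  truth <- bench$truth
  passed <- res$id[res$status == "passed"]
  act <- truth$id[truth$true_label == "high"]
  inact <- truth$id[truth$true_label == "weak"]

  list(
    classifier_mcc = classifier_mcc,
    stack_mcc = stack_mcc,
    stack_delta_vs_best_base = stack_mcc - best_base,
    regressor_rmse = regressor_rmse,
    cascade_recall = length(intersect(passed, act)) / length(act),
    inactive_passthrough = length(intersect(passed, inact)),
    n_train = n_train, n_screen = n_screen,
    n_planted_active = length(act),
    result = res, truth = truth, som = som
  )
}
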