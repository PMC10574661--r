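# Shared small synthetic benchmark, generated once per test run.
.bench_env <- new.env(parent = emptyenv())

test_bench <- function() {
  if (is.null(.bench_env$bench)) {
    spec <- synthetic_spec(n_molecules = 300L, seed = 42L)
    .bench_env$bench <- generate_benchmark(spec, n_external = 100L,
                                           n_screen = 150L)
  }
  .bench_env$bench
}

# tiny single-point grids so model fits stay fast in unit tests
tiny_grid <- function(algorithm) {
  switch(algorithm,
    svm_rbf = expand.grid(C = 10, gamma = 0.01),
    random_forest = expand.grid(n_estimators = 100, max_leaf_nodes = Inf),
    grad_boost = expand.grid(n_estimators = 100, max_depth = 4,
                             subsample = 1, colsample_bytree = 1),
    dnn = expand.grid(learning_rate = 1e-3))
}

# a small trained screening kit (classifiers, regressor, SOM) on the shared
# benchmark, built once per test run
test_kit <- function() {
  if (!is.null(.bench_env$kit)) return(.bench_env$kit)
  bench <- test_bench()
  ds <- activity_dataset(bench$train, task = "classification",
                         scheme = bench$scheme)
  classifiers <- lapply(
    stats::setNames(nm = c("maccs166", "ecfp4_1024")), function(k) {
      fm <- variance_filter(fingerprints(ds, k))
      qsar_fit(fm, ds$label, "grad_boost", grid = tiny_grid("grad_boost"),
               cv_repeats = 1, seed = 4, featurization_id = k)
    })
  dtr <- descriptors(bench$train, "fragment_counts")
  sc <- autoscale_fit(dtr)
  regressor <- qsar_fit(autoscale_apply(dtr, sc), bench$train$pic50,
                        "grad_boost", grid = tiny_grid("grad_boost"),
                        cv_repeats = 1, seed = 6,
                        featurization_id = "fragment_counts", scaler = sc)
  som <- som_fit(fingerprints(ds, "ecfp4_1024"), ds$label,
                 width = 7, height = 7, epochs = 6, seed = 8)
  aggs <- suppressMessages(load_aggregators(
    system.file("extdata", "aggregators_synthetic.csv",
                package = "vscascade")))
  .bench_env$kit <- list(bench = bench, ds = ds, classifiers = classifiers,
                         regressor = regressor, som = som, aggs = aggs)
  .bench_env$kit
}

# fingerprint matrices for a dataset, variance-filtered on the training rows
split_fingerprints <- function(ds, split, kind) {
  fm <- fingerprints(ds, kind)
  tr <- feature_matrix(unclass(fm)[split$train, , drop = FALSE],
                       "fingerprint")
  tr <- variance_filter(tr)
  te <- feature_matrix(
    unclass(fm)[split$test, colnames(tr), drop = FALSE], "fingerprint")
  list(train = tr, test = te)
}
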