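# planted linearly separable data in fingerprint-like features
make_separable <- function(n = 80, d = 12, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * d, 1, 0.5), n, d,
              dimnames = list(NULL, paste0("bit", seq_len(d))))
  y <- factor(ifelse(x[, 1] == 1, "high", "weak"), levels = c("high", "weak"))
  list(x = feature_matrix(x, "fingerprint"), y = y)
}

test_that("tuned models recover a planted separable signal", {
  dat <- make_separable(seed = 23)
  te <- make_separable(n = 40, seed = 24)
  for (alg in c("svm_rbf", "random_forest", "grad_boost")) {
    m <- qsar_fit(dat$x, dat$y, alg, grid = tiny_grid(alg),
                  cv_repeats = 1, seed = 2)
    cc <- confusion(te$y, predict(m, te$x, type = "class"))
    expect_equal(mcc(cc), 1, info = alg)
  }
})

test_that("a single-point grid is equivalent to a direct fit", {
  dat <- make_separable(seed = 31)
  m <- qsar_fit(dat$x, dat$y, "grad_boost", grid = tiny_grid("grad_boost"),
                cv_repeats = 1, seed = 5)
  direct <- vscascade:::fit_single("grad_boost", "classification",
                                   as.list(tiny_grid("grad_boost")),
                                   unclass(dat$x), dat$y, seed = 5)
  expect_equal(predict(m, dat$x, type = "prob"),
               vscascade:::predict_single(direct, unclass(dat$x),
                                          type = "prob"))
})

test_that("model selection is deterministic under a fixed seed", {
  dat <- make_separable(n = 60, seed = 37)
  grid <- expand.grid(C = c(0.1, 1, 10), gamma = c(0.01, 0.1))
  m1 <- qsar_fit(dat$x, dat$y, "svm_rbf", grid = grid, cv_repeats = 2,
                 seed = 11)
  m2 <- qsar_fit(dat$x, dat$y, "svm_rbf", grid = grid, cv_repeats = 2,
                 seed = 11)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$cv_table$cv_score, m2$cv_table$cv_score)
})

test_that("hyperparameter selection never sees held-out data", {
  # the tuner only receives the training partition; fitting twice with
  # different hypothetical test sets cannot change the chosen model
  dat <- make_separable(n = 60, seed = 41)
  grid <- expand.grid(n_estimators = c(50, 100), max_depth = 3,
                      subsample = 1, colsample_bytree = 1)
  m <- qsar_fit(dat$x, dat$y, "grad_boost", grid = grid, cv_repeats = 1,
                seed = 3)
  expect_named(m$hyperparameters,
               c("n_estimators", "max_depth", "subsample",
                 "colsample_bytree"), ignore.order = TRUE)
  expect_true(all(c("cv_score") %in% names(m$cv_table)))
})

test_that("regression tuning over descriptor counts uses the RFE ranking", {
  set.seed(43)
  n <- 70
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- 2 * x[, 3] + rnorm(n, 0, 0.05)
  fm <- feature_matrix(x, "descriptor")
  rk <- rfrfe_rank(fm, y, seed = 2, num_trees = 150)
  expect_equal(rk[1], "d3")
  m <- qsar_fit(fm, y, "svm_rbf",
                grid = expand.grid(C = 10, gamma = 0.1, epsilon = 0.1),
                n_descriptors = c(1, 3, 6), ranking = rk,
                cv_repeats = 1, seed = 7)
  expect_true(m$hyperparameters$n_desc %in% c(1, 3, 6))
  expect_lte(rmse(y, predict(m, fm)), 0.5)
  expect_error(qsar_fit(fm, y, "svm_rbf", n_descriptors = 2), "ranking")
})

test_that("the experiment grid reproduces the factorial design counts", {
  cls <- experiment_grid(paste0("ds", 1:4),
                         c("maccs166", "path1024", "ecfp4_1024"),
                         c("svm_rbf", "random_forest", "grad_boost", "dnn"),
                         n_repeats = 10)
  expect_equal(nrow(cls), 480L)
  reg <- experiment_grid(paste0("ds", 1:2),
                         c("physchem_2d", "fragment_counts"),
                         c("svm_rbf", "random_forest", "grad_boost", "dnn"),
                         n_repeats = 10)
  expect_equal(nrow(reg), 160L)
  expect_equal(nrow(experiment_grid("a", "b", "c", 1)), 1L)
  # stable ordering, complete design
  expect_equal(anyDuplicated(cls), 0L)
  expect_equal(as.vector(table(cls$dataset)), rep(120L, 4))
})

test_that("the MLP learns a separable signal with early stopping", {
  dat <- make_separable(n = 100, d = 8, seed = 47)
  te <- make_separable(n = 50, d = 8, seed = 48)
  net <- mlp_fit(unclass(dat$x), dat$y, hidden = c(16, 8, 8, 4),
                 learning_rate = 5e-3, patience = 10, max_epochs = 150,
                 epoch_repeats = 1, seed = 3)
  pred <- factor(ifelse(mlp_predict(net, unclass(te$x)) >= 0.5,
                        "high", "weak"), levels = c("high", "weak"))
  expect_gte(mcc(confusion(te$y, pred)), 0.9)
})

test_that("MLP epoch selection is deterministic and patience bounds epochs", {
  dat <- make_separable(n = 60, d = 6, seed = 53)
  n1 <- mlp_fit(unclass(dat$x), dat$y, hidden = c(8, 4, 4, 2),
                learning_rate = 1e-3, patience = 5, max_epochs = 40,
                epoch_repeats = 1, seed = 9)
  n2 <- mlp_fit(unclass(dat$x), dat$y, hidden = c(8, 4, 4, 2),
                learning_rate = 1e-3, patience = 5, max_epochs = 40,
                epoch_repeats = 1, seed = 9)
  expect_identical(n1$epochs, n2$epochs)
  expect_identical(n1$weights, n2$weights)
  # frozen optimizer: the validation metric never improves, so patience
  # stops training immediately and the minimal epoch count is used
  nc <- mlp_fit(unclass(dat$x), rnorm(60), hidden = c(4, 2, 2, 2),
                learning_rate = 0, patience = 3, max_epochs = 50,
                epoch_repeats = 1, seed = 4)
  expect_equal(nc$epochs, 1L)
})

test_that("the dnn family plugs into the tuner", {
  dat <- make_separable(n = 120, d = 8, seed = 59)
  m <- qsar_fit(dat$x, dat$y, "dnn",
                grid = expand.grid(learning_rate = 5e-3),
                cv_repeats = 1, cv_folds = 3, seed = 2,
                dnn_control = list(hidden = c(16, 8, 8, 4), patience = 10,
                                   max_epochs = 200, epoch_repeats = 1))
  te <- make_separable(n = 50, d = 8, seed = 60)
  cc <- confusion(te$y, predict(m, te$x, type = "class"))
  expect_gte(mcc(cc), 0.9)
})
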