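test_that("labeling schemes apply printed comparator semantics exactly", {
  s <- builtin_schemes()
  # gapped scheme: <0.1 high, >10 weak, in-between excluded
  expect_equal(as.character(label_activity(c(0.05, 5, 50), s$strict_gap)),
               c("high", "excluded", "weak"))
  expect_equal(as.character(label_activity(0.1, s$strict_gap)), "excluded")
  # total scheme at 1 uM: <= 1 is high (boundary inclusive)
  expect_equal(as.character(label_activity(1.0, s$potency_1um)), "high")
  expect_equal(as.character(label_activity(1.0001, s$potency_1um)), "weak")
  # gapped at 0.6/10
  expect_equal(as.character(label_activity(c(0.5, 0.6, 10.5), s$gap_0.6_10)),
               c("high", "excluded", "weak"))
  # total at 10: >= 10 weak (boundary weak)
  expect_equal(as.character(label_activity(c(10, 9.999), s$cut_10um)),
               c("weak", "high"))
  expect_error(label_activity(-1, s$cut_10um), "positive")
  expect_error(activity_scheme("<=", 10, ">=", 10), "overlap")
})

test_that("total schemes label every positive IC50; gapped schemes exclude", {
  s <- builtin_schemes()
  set.seed(8)
  ic <- 10^runif(200, -4, 4)
  expect_false(any(label_activity(ic, s$potency_1um) == "excluded"))
  expect_false(any(label_activity(ic, s$cut_10um) == "excluded"))
  gap <- label_activity(ic, s$strict_gap)
  expect_true(all(gap[ic > 0.1 & ic < 10] == "excluded"))
})

test_that("pIC50 conversion uses micromolar units", {
  expect_equal(pic50_from_ic50(10), 5)
  expect_equal(pic50_from_ic50(1), 6)
  expect_equal(pic50_from_ic50(0.1), 7)
  expect_equal(ic50_from_pic50(pic50_from_ic50(3.7)), 3.7)
  expect_error(pic50_from_ic50(0), "positive")
})

test_that("split sizes reproduce all six printed train:test pairs", {
  printed <- list(
    list(n = 1630, frac = 0.20, train = 1304, test = 326),
    list(n = 2925, frac = 0.20, train = 2340, test = 585),
    list(n = 1511, frac = 0.20, train = 1209, test = 302),
    list(n = 3179, frac = 0.25, train = 2384, test = 795),
    list(n = 3455, frac = 0.25, train = 2591, test = 864),
    list(n = 735,  frac = 0.25, train = 551,  test = 184))
  for (p in printed) {
    y <- factor(rep(c("high", "weak"), length.out = p$n),
                levels = c("high", "weak"))
    sp <- stratified_split(y, p$frac, seed = 1)
    expect_equal(length(sp$test), p$test)
    expect_equal(length(sp$train), p$train)
  }
})

test_that("stratified splits partition the data and preserve class balance", {
  set.seed(4)
  y <- factor(sample(rep(c("high", "weak"), c(120, 280))),
              levels = c("high", "weak"))
  sp <- stratified_split(y, 0.25, seed = 2)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  # per-class test counts deviate from exact proportionality by < 1
  for (cl in levels(y)) {
    exact <- sum(y == cl) * 100 / 400
    expect_lt(abs(sum(y[sp$test] == cl) - exact), 1)
  }
  tiny <- factor(c("high", "high", "weak", "weak"),
                 levels = c("high", "weak"))
  sp4 <- stratified_split(tiny, 0.25, seed = 1)
  expect_equal(length(sp4$test), 1L)
  expect_error(stratified_split(factor(c("high", "weak", "weak"),
                                       levels = c("high", "weak")), 0.2),
               "at least 2")
})

test_that("regression splits stratify by response quantiles", {
  set.seed(6)
  y <- rnorm(200)
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_equal(length(sp$test), 40L)
  # test-set response distribution resembles the full one
  expect_lt(abs(median(y[sp$test]) - median(y)), 0.35)
  expect_error(stratified_split(rnorm(4), 0.25), "n >= 5")
})

test_that("repeated splits are seeded, distinct and reduce to single splits", {
  y <- factor(rep(c("high", "weak"), 50), levels = c("high", "weak"))
  ss <- repeated_splits(y, n_repeats = 10, test_fraction = 0.2, base_seed = 7)
  expect_length(ss$splits, 10L)
  expect_equal(ss$seeds, 7:16)
  tests <- vapply(ss$splits, function(s) paste(s$test, collapse = ","), "")
  expect_gt(length(unique(tests)), 1L)
  ss2 <- repeated_splits(y, n_repeats = 10, test_fraction = 0.2, base_seed = 7)
  expect_identical(ss, ss2)
  one <- repeated_splits(y, n_repeats = 1, test_fraction = 0.2, base_seed = 3)
  expect_identical(one$splits[[1]], stratified_split(y, 0.2, seed = 3))
})

test_that("activity datasets drop the exclusion gap before splitting", {
  rec <- molecule_records(rep("c1ccccc1", 6), id = paste0("m", 1:6),
                          ic50_um = c(0.01, 0.05, 5, 20, 30, 0.02))
  ds <- activity_dataset(rec, task = "classification",
                         scheme = builtin_schemes()$strict_gap)
  expect_equal(nrow(ds), 5L)  # the 5 uM molecule is excluded
  expect_equal(sum(ds$label == "high"), 3L)
  expect_error(activity_dataset(
    molecule_records("C", ic50_um = 0.01), task = "classification",
    scheme = builtin_schemes()$strict_gap), "both classes")
})
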