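test_that("fingerprint widths and determinism match the contract", {
  rec <- molecule_records(
    standardize_smiles(c("c1ccccc1", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"))$smiles)
  for (kind in c("maccs166", "path1024", "ecfp4_1024")) {
    fm <- fingerprints(rec, kind)
    expect_equal(ncol(fm), if (kind == "maccs166") 166L else 1024L)
    expect_true(all(unclass(fm) %in% c(0L, 1L)))
    expect_equal(unname(unclass(fm)[1, ]), unname(unclass(fm)[2, ]))
  }
  expect_error(fingerprints(rec, "morgan3"))
})

test_that("ECFP4 bits agree with an independent toolkit computation", {
  smis <- c("c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O")
  fm <- fingerprints(molecule_records(smis), "ecfp4_1024")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smis))
  raw <- ChemmineOB::fingerprint_OB(ChemmineR::obmol(sdf), "ECFP4")
  for (i in 1:2) {
    folded <- as.integer(colSums(matrix(raw[i, ], nrow = 4, byrow = TRUE)) > 0)
    expect_equal(unname(unclass(fm)[i, ]), folded)
  }
})

test_that("physchem descriptors hit formula-mass and graph oracles", {
  rec <- molecule_records(standardize_smiles(c("CCO", "c1ccccc1"))$smiles,
                          id = c("ethanol", "benzene"))
  d <- descriptors(rec, "physchem_2d")
  expect_equal(unclass(d)["ethanol", "MW"], 46.07, tolerance = 1e-3)
  expect_equal(unname(unclass(d)["ethanol", "n_heavy"]), 3)
  expect_equal(unname(unclass(d)["benzene", "n_rings"]), 1)
  expect_equal(unname(unclass(d)["benzene", "n_aromatic_atoms"]), 6)
  # identical molecules give identical rows
  rec2 <- molecule_records(c("CCO", "CCO"))
  d2 <- descriptors(rec2, "physchem_2d")
  expect_equal(unname(unclass(d2)[1, ]), unname(unclass(d2)[2, ]))
})

test_that("fragment counts match ring/group perception", {
  rec <- molecule_records(
    standardize_smiles(c("c1ccccc1", "NS(=O)(=O)c1ccccc1", "OC(=O)CC"))$smiles)
  fc <- unclass(descriptors(rec, "fragment_counts"))
  expect_equal(unname(fc[1, "benzene_ring"]), 1)
  expect_equal(unname(fc[2, "sulfonamide"]), 1)
  expect_equal(unname(fc[3, "carboxylic_acid"]), 1)
  expect_equal(unname(fc[1, "sulfonamide"]), 0)
})

test_that("descriptor providers are pluggable", {
  register_descriptor_provider("heavy_only", function(records)
    cbind(n_heavy = vapply(records$smiles, function(s)
      nchar(gsub("[^A-Za-z]", "", s)), 0)))
  d <- descriptors(molecule_records(c("CCO", "CCCC")), "heavy_only")
  expect_equal(colnames(d), "n_heavy")
})

test_that("variance filter drops the bottom quartile with index tie-breaks", {
  # 8 columns with variances (0,0,.1,.1,.2,.2,.3,.3)-ordered pattern
  set.seed(1)
  make_col <- function(v) if (v == 0) rep(1, 8) else {
    x <- rep(c(0, 1), 4) * sqrt(v / var(rep(c(0, 1), 4))); x
  }
  vals <- cbind(make_col(0), make_col(0), make_col(.1), make_col(.1),
                make_col(.2), make_col(.2), make_col(.3), make_col(.3))
  colnames(vals) <- paste0("f", 1:8)
  fm <- feature_matrix(vals, "descriptor")
  out <- variance_filter(fm, 0.25)
  expect_equal(colnames(out), paste0("f", 3:8))  # the two var-0 columns go

  # all-equal variances: exactly floor(d/4) lowest-index columns dropped
  vals2 <- matrix(rep(c(0, 1, 0, 1), 4), 4, 4,
                  dimnames = list(NULL, paste0("g", 1:4)))
  out2 <- variance_filter(feature_matrix(vals2, "fingerprint"), 0.25)
  expect_equal(colnames(out2), paste0("g", 2:4))
  expect_error(variance_filter(fm, 0), "quartile")
  expect_error(variance_filter(fm, 1), "quartile")
})

test_that("variance filter never drops a column more variable than a kept one", {
  set.seed(7)
  for (rep in 1:5) {
    vals <- matrix(rbinom(20 * 30, 1, runif(1, 0.1, 0.9)), 20, 30,
                   dimnames = list(NULL, paste0("b", 1:30)))
    fm <- feature_matrix(vals, "fingerprint")
    out <- variance_filter(fm, 0.25)
    v <- apply(vals, 2, var)
    dropped <- setdiff(colnames(vals), colnames(out))
    expect_lte(max(v[dropped]), min(v[colnames(out)]))
  }
})

test_that("pcc filter removes correlated members, keeping the response-relevant one", {
  set.seed(3)
  x1 <- rnorm(50); y <- x1 + rnorm(50, 0, 0.1)
  vals <- cbind(a = x1, a_dup = x1, b = rnorm(50), c = rnorm(50))
  fm <- feature_matrix(vals, "descriptor")
  out <- pcc_filter(fm, y, r_cut = 0.95)
  expect_equal(sum(c("a", "a_dup") %in% colnames(out)), 1L)
  expect_true(all(c("b", "c") %in% colnames(out)))
  # post-condition by brute force: no surviving pair above the cut
  cm <- cor(unclass(out))
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.95))
  # d = 1 unchanged
  one <- feature_matrix(vals[, 1, drop = FALSE], "descriptor")
  expect_equal(colnames(pcc_filter(one, y)), "a")
})

test_that("RF-RFE ranks a planted signal first and is seed-deterministic", {
  set.seed(11)
  vals <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- vals[, 4]  # y exactly equals feature 4
  fm <- feature_matrix(vals, "descriptor")
  r1 <- rfrfe_rank(fm, y, seed = 5, num_trees = 200)
  r2 <- rfrfe_rank(fm, y, seed = 5, num_trees = 200)
  expect_equal(r1[1], "v4")
  expect_identical(r1, r2)
  expect_setequal(r1, colnames(vals))
  expect_equal(rfrfe_rank(fm_select(fm, "v2"), y, seed = 1), "v2")
})

test_that("autoscaling maps the training range onto [0.1, 0.9] without clipping", {
  vals <- cbind(a = c(0, 5, 10), b = c(3, 3, 3))
  fm <- feature_matrix(vals, "descriptor")
  sc <- autoscale_fit(fm)
  out <- autoscale_apply(fm, sc)
  expect_equal(unname(unclass(out)[, "a"]), c(0.1, 0.5, 0.9))
  expect_equal(unname(unclass(out)[, "b"]), c(0.5, 0.5, 0.5))
  # out-of-range test value scales past 0.9: train 0..10, value 20 -> 1.7
  newv <- feature_matrix(cbind(a = 20, b = 3), "descriptor")
  expect_equal(unname(unclass(autoscale_apply(newv, sc))[, "a"]), 1.7)
  wrong <- feature_matrix(cbind(z = 1:3), "descriptor")
  expect_error(autoscale_apply(wrong, sc), "feature names")
})

test_that("autoscale endpoints property holds on random matrices", {
  set.seed(21)
  vals <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("r", 1:4)))
  fm <- feature_matrix(vals, "descriptor")
  out <- unclass(autoscale_apply(fm, autoscale_fit(fm)))
  expect_equal(unname(apply(out, 2, min)), rep(0.1, 4))
  expect_equal(unname(apply(out, 2, max)), rep(0.9, 4))
})
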