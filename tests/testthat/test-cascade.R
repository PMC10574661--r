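test_that("model selection by external validation is deterministic", {
  reports <- data.frame(model_id = c("b", "a", "c", "d"),
                        metric = c(0.7, 0.7, 0.5, 0.9))
  expect_equal(select_models(reports, "top_k", k = 1), "d")
  # ties broken by model id
  expect_equal(select_models(reports, "top_k", k = 3), c("d", "a", "b"))
  expect_equal(select_models(reports, "threshold", cutoff = 0.7),
               c("d", "a", "b"))
  # k equal to the number of models selects all of them
  expect_setequal(select_models(reports, "top_k", k = 4), reports$model_id)
  expect_error(select_models(reports, "threshold", cutoff = 0.95),
               "empty selection")
  # RMSE-like metrics select the smallest values
  expect_equal(select_models(reports, "top_k", k = 1,
                             higher_is_better = FALSE), "c")
})

test_that("consensus classification applies the vote fraction rule", {
  kit <- test_kit()
  cand <- kit$bench$screen[1:30, ]
  cc1 <- consensus_classify(kit$classifiers, cand, consensus_fraction = 1.0)
  expect_equal(cc1$n_classifiers, rep(2L, 30))
  expect_equal(cc1$keep, cc1$n_positive == 2L)
  cc2 <- consensus_classify(kit$classifiers, cand, consensus_fraction = 0.5)
  expect_equal(cc2$keep, cc2$n_positive >= 1L)
  # looser fraction keeps a superset
  expect_true(all(which(cc1$keep) %in% which(cc2$keep)))
})

test_that("potency averaging converts mean pIC50 with a strict cut", {
  kit <- test_kit()
  cand <- kit$bench$screen[1:20, ]
  ap <- average_potency(list(kit$regressor), cand, potency_cut_um = 10)
  expect_equal(ap$pred_ic50_um, 10^(6 - ap$mean_pic50))
  expect_equal(ap$keep, ap$pred_ic50_um < 10)
  # a molecule at exactly the cut is dropped (strict "below")
  fake <- ap; boundary <- 10^(6 - 5)
  expect_false(boundary < 10)
})

test_that("the cascade recovers planted actives and blocks planted inactives", {
  kit <- test_kit()
  res <- run_cascade(kit$bench$screen, kit$classifiers,
                     list(kit$regressor), som = kit$som,
                     aggregators = kit$aggs, config = cascade_config())
  expect_s3_class(res, "screening_result")
  # audit-trail completeness: every molecule exactly once
  expect_setequal(res$id, kit$bench$screen$id)
  expect_equal(nrow(res), nrow(kit$bench$screen))
  truth <- kit$bench$truth
  passed <- res$id[res$status == "passed"]
  inact <- truth$id[truth$true_label == "weak"]
  act <- truth$id[truth$true_label == "high"]
  # no planted inactive survives; most planted actives do
  expect_length(intersect(passed, inact), 0)
  expect_gte(length(intersect(passed, act)) / length(act), 0.5)
  # failed@stage k implies later stage fields are unevaluated
  f1 <- res[res$status == "failed@classification", ]
  expect_true(all(is.na(f1$mean_pic50)))
  expect_true(all(is.na(f1$som_hp)))
  # kept candidates all satisfy the HP rule
  expect_true(all(res$som_hp[res$status == "passed"] >= 0.8))
  # ranking follows ascending predicted potency
  ic <- res$pred_ic50_um[res$status == "passed"]
  expect_false(is.unsorted(ic))
})

test_that("stricter thresholds pass a subset (monotone filtering)", {
  kit <- test_kit()
  loose <- run_cascade(kit$bench$screen, kit$classifiers,
                       list(kit$regressor), som = kit$som,
                       config = cascade_config(potency_cut_um = 10,
                                               hp_threshold = 0.6))
  strict <- run_cascade(kit$bench$screen, kit$classifiers,
                        list(kit$regressor), som = kit$som,
                        config = cascade_config(potency_cut_um = 2,
                                                hp_threshold = 0.9))
  p_loose <- loose$id[loose$status == "passed"]
  p_strict <- strict$id[strict$status == "passed"]
  expect_true(all(p_strict %in% p_loose))
})

test_that("stacked classifiers work inside the cascade", {
  kit <- test_kit()
  ds <- kit$ds
  x_list <- lapply(stats::setNames(nm = c("maccs166", "ecfp4_1024")),
                   function(k) {
    fm <- fingerprints(ds, k)
    feature_matrix(unclass(fm)[, kit$classifiers[[k]]$features,
                               drop = FALSE], "fingerprint")
  })
  st <- qsar_stack(kit$classifiers, x_list, ds$label, seed = 3)
  res <- run_cascade(kit$bench$screen[1:40, ], list(stack = st),
                     list(kit$regressor), som = NULL, aggregators = NULL)
  expect_equal(nrow(res), 40L)
  expect_setequal(res$id, kit$bench$screen$id[1:40])
  expect_true(all(res$status %in%
                  c("passed", "failed@classification", "failed@potency")))
})

test_that("an empty library yields an empty result", {
  kit <- test_kit()
  res <- run_cascade(kit$bench$screen[0, ], kit$classifiers,
                     list(kit$regressor))
  expect_equal(nrow(res), 0L)
})

test_that("the classification stage is consistent with consensus_classify", {
  kit <- test_kit()
  cand <- kit$bench$screen[1:25, ]
  res <- run_cascade(cand, kit$classifiers, list(kit$regressor),
                     som = NULL, aggregators = NULL)
  cc <- consensus_classify(kit$classifiers, cand)
  res_o <- res[match(cc$id, res$id), ]
  expect_equal(res_o$n_positive, cc$n_positive)
  expect_equal(res_o$status == "failed@classification", !cc$keep)
})
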