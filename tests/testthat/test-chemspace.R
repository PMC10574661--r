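test_that("tanimoto matches hand-computed and symmetric cases", {
  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)  # both empty
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
  set.seed(2)
  for (i in 1:10) {
    a <- rbinom(16, 1, 0.5); b <- rbinom(16, 1, 0.5)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("exact diversity statistics match a brute-force double loop", {
  set.seed(5)
  vals <- matrix(rbinom(5 * 32, 1, 0.4), 5, 32,
                 dimnames = list(NULL, paste0("b", 1:32)))
  fm <- feature_matrix(vals, "fingerprint")
  rep <- diversity_stats(fm, cut = 0.6, mode = "exact")
  # oracle loop
  tcs <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    tcs <- c(tcs, tanimoto(vals[i, ], vals[j, ]))
  }
  expect_equal(rep$mean_tc, mean(tcs))
  expect_equal(rep$frac_below, mean(tcs < 0.6))
  expect_equal(rep$n_pairs_evaluated, 10)
  expect_error(diversity_stats(fm[1, , drop = FALSE]))
})

test_that("identical molecules give mean TC 1 and nothing below the cut", {
  vals <- matrix(rep(c(1, 0, 1, 1), each = 2), 2, 4,
                 dimnames = list(NULL, paste0("b", 1:4)))
  rep <- diversity_stats(feature_matrix(vals, "fingerprint"), mode = "exact")
  expect_equal(rep$mean_tc, 1)
  expect_equal(rep$frac_below, 0)
})

test_that("sampled diversity is seeded and converges to exact on n = 50", {
  set.seed(9)
  vals <- matrix(rbinom(50 * 64, 1, 0.3), 50, 64,
                 dimnames = list(NULL, paste0("b", 1:64)))
  fm <- feature_matrix(vals, "fingerprint")
  s1 <- diversity_stats(fm, mode = "sampled", max_pairs = 200, seed = 4)
  s2 <- diversity_stats(fm, mode = "sampled", max_pairs = 200, seed = 4)
  expect_identical(s1, s2)
  ex <- diversity_stats(fm, mode = "exact")
  # sampling all pairs reproduces the exact statistics
  all_pairs <- diversity_stats(fm, mode = "sampled", max_pairs = 50 * 49 / 2)
  expect_equal(all_pairs$mean_tc, ex$mean_tc)
  # a large sample is close to the exact value
  s3 <- diversity_stats(fm, mode = "sampled", max_pairs = 1000, seed = 1)
  expect_lt(abs(s3$mean_tc - ex$mean_tc), 0.02)
})

test_that("murcko scaffolds match toolkit-oracle expectations and are idempotent", {
  benzene <- standardize_smiles("c1ccccc1")$smiles
  out <- murcko_scaffold(c("c1ccccc1", "Cc1ccccc1", "CCC",
                           "c1ccc(CCc2ccncc2)cc1"))
  expect_equal(out[1], benzene)   # scaffold of a ring is itself
  expect_equal(out[2], benzene)   # toluene side chain removed
  expect_equal(out[3], "")        # acyclic -> empty scaffold
  # idempotence on ring-linker systems
  expect_equal(murcko_scaffold(out[4]), out[4])
  expect_error(murcko_scaffold("not_a_smiles"))
})

test_that("top scaffolds tally counts and percents", {
  rec <- molecule_records(standardize_smiles(
    c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1", "Cc1ccncc1", "CCCC"))$smiles)
  tab <- top_scaffolds(rec)
  expect_equal(tab$count, c(3L, 1L))
  expect_equal(tab$percent, c(75, 25))
  expect_equal(tab$scaffold[1], standardize_smiles("c1ccccc1")$smiles)
  acyclic <- molecule_records(c("CCO", "CCC"))
  expect_equal(nrow(top_scaffolds(acyclic)), 0L)
})

test_that("scaffold clustering separates planted families and is seeded", {
  # two well-separated scaffold families (distinct scaffolds per molecule:
  # aromatic polycyclics vs saturated amine rings)
  fam1 <- c("c1ccc2ccccc2c1", "c1ccc(-c2ccccc2)cc1", "c1ccc(Cc2ccccc2)cc1",
            "c1ccc(CCc2ccccc2)cc1", "c1ccc2cc3ccccc3cc2c1",
            "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1")
  fam2 <- c("C1CCNCC1", "C1CCC(CC1)C1CCNCC1", "C1CCN(CC1)C1CCNCC1",
            "C1CCC(CC1)CC1CCNCC1", "C1CCCCC1", "C1CCC(CC1)C1CCCCC1")
  rec <- molecule_records(standardize_smiles(c(fam1, fam2))$smiles)
  cl <- cluster_scaffolds(rec, k = 2, seed = 3, embed = "pcoa")
  g1 <- cl$cluster[1:6]; g2 <- cl$cluster[7:12]
  expect_equal(length(unique(g1)), 1L)
  expect_equal(length(unique(g2)), 1L)
  expect_false(g1[1] == g2[1])
  cl2 <- cluster_scaffolds(rec, k = 2, seed = 3, embed = "pcoa")
  expect_identical(cl$cluster, cl2$cluster)
  expect_true(all(cl$cluster %in% 0:1))
  expect_error(cluster_scaffolds(rec, k = 50), "fewer distinct scaffolds")
})
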