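# Metric suite: closed-form examples plus independent oracles.

# Independent MCC oracle: Pearson correlation between the reconstructed
# binary prediction and truth vectors (phi coefficient).
oracle_mcc <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  if (length(unique(pred)) < 2 || length(unique(truth)) < 2) return(0)
  suppressWarnings(stats::cor(pred, truth))
}

# Independent EF oracle evaluated on the reconstructed vectors.
oracle_ef <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  if (sum(pred) == 0) return(NA_real_)
  mean(truth[pred == 1]) / mean(truth)
}

test_that("mcc matches its closed-form examples and conventions", {
  expect_equal(mcc(confusion_counts(10, 0, 90, 0)), 1)
  expect_equal(mcc(confusion_counts(25, 25, 25, 25)), 0)
  expect_equal(mcc(confusion_counts(3, 1, 5, 1)), 14 / 24)
  expect_equal(mcc(confusion_counts(0, 5, 0, 5)), -1)  # total disagreement
  expect_equal(mcc(confusion_counts(0, 0, 5, 5)), 0)   # zero-factor rule
})

test_that("enrichment factor matches the prevalence-adjusted precision", {
  expect_equal(enrichment_factor(confusion_counts(8, 2, 88, 2)), 8)
  # precision equal to prevalence -> EF 1
  expect_equal(enrichment_factor(confusion_counts(1, 9, 81, 9)), 1)
  # perfect precision attains the bound N / (TP + FN)
  cc <- confusion_counts(10, 0, 90, 0)
  expect_equal(enrichment_factor(cc), 100 / 10)
  # no predicted positives: undefined, not zero
  expect_true(is.na(enrichment_factor(confusion_counts(0, 0, 90, 10))))
})

test_that("mcc and EF agree with vector-level oracles on random matrices", {
  set.seed(31)
  for (i in 1:40) {
    cts <- sample(0:6, 4, replace = TRUE)
    if (sum(cts) == 0) next
    cc <- confusion_counts(cts[1], cts[2], cts[3], cts[4])
    expect_equal(mcc(cc), oracle_mcc(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-12)
    if (cts[1] + cts[4] > 0) {
      expect_equal(enrichment_factor(cc),
                   oracle_ef(cts[1], cts[2], cts[3], cts[4]),
                   tolerance = 1e-12)
    }
  }
})

test_that("imbalance rate reflects class skew", {
  expect_equal(imbalance_rate(50, 50), 0)
  expect_equal(imbalance_rate(0, 100), 1)
  expect_equal(imbalance_rate(811, 3035), 2224 / 3846)
})

test_that("internal diversity matches pair enumeration and is order-invariant", {
  f <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0), 2, 4, byrow = TRUE)
  expect_equal(internal_diversity(f, p = 1), 0.5)
  expect_equal(internal_diversity(f, p = 2), 1 - sqrt(0.5))
  same <- rep("c1ccccc1", 4)
  expect_equal(internal_diversity(same), 0)
  set <- fix_fixture_pool()$smiles[1:12]
  d1 <- internal_diversity(set)
  d2 <- internal_diversity(rev(set))
  expect_equal(d1, d2)
  expect_gte(d1, 0); expect_lte(d1, 1)
  expect_error(internal_diversity(character(0)), class = "qsiraug_contract")
})

test_that("PAINS counting is per-molecule with known hitters and decoys", {
  expect_identical(count_pains(c("C", "CCO")), 0L)
  quin <- "O=C1C=CC(=O)C=C1"
  expect_gte(count_pains(c(quin, "CCO")), 1)
  # duplicates each count once
  expect_identical(count_pains(c(quin, quin)),
                   2L * count_pains(quin))
  flags <- pains_flags(c(quin, "CCO", "Oc1ccccc1O"))
  expect_identical(flags, c(TRUE, FALSE, TRUE))
})

test_that("scaffold similarity aggregates per-molecule maxima", {
  ref <- c("Cc1ccccc1", "CC1CCNCC1")          # benzene + piperidine
  new_in <- c("CCc1ccccc1", "Fc1ccccc1")      # scaffolds subset of ref
  expect_equal(as.numeric(scaffold_similarity(new_in, ref)), 1)
  # hand-built 2x2 case equals brute-force max-mean
  new2 <- c("Cc1ccncc1", "C1CCOC1")
  scaf_new <- murcko_scaffold(new2)
  scaf_ref <- unique(murcko_scaffold(ref))
  fp_n <- morgan_fingerprint(scaf_new, radius = 2)
  fp_r <- morgan_fingerprint(scaf_ref, radius = 2)
  brute <- mean(c(
    max(tanimoto(fp_n[1, ], fp_r[1, ]), tanimoto(fp_n[1, ], fp_r[2, ])),
    max(tanimoto(fp_n[2, ], fp_r[1, ]), tanimoto(fp_n[2, ], fp_r[2, ]))))
  expect_equal(as.numeric(scaffold_similarity(new2, ref)), brute)
  # acyclic molecules are excluded and counted
  mixed <- scaffold_similarity(c("CCO", "CCc1ccccc1"), ref)
  expect_identical(attr(mixed, "n_acyclic"), 1L)
  all_acyclic <- scaffold_similarity(c("CCO", "CCC"), ref)
  expect_true(is.na(as.numeric(all_acyclic)))
})

test_that("qed is bounded, deterministic, and ranks drug-like higher", {
  mols <- c("CC(=O)Oc1ccccc1C(=O)O", "CCO",
            "c1ccc2cc3cc4ccccc4cc3cc2c1CCCCCCCCCCCCCCCCCCCC")
  q <- qed_score(mols)
  expect_true(all(q$qed > 0 & q$qed < 1))
  expect_identical(q, qed_score(mols))
  expect_gt(q$qed[1], q$qed[3])
  qs <- qed_and_summary(mols)
  expect_equal(qs$mean_qed, mean(q$qed))
})

test_that("classification reports combine threshold and ranking metrics", {
  perfect <- classification_report(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$pr_auc, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  # random scores: PR-AUC concentrates near prevalence
  set.seed(8)
  labels <- rep(c(1, 0), c(30, 270))
  aucs <- replicate(40, pr_auc(runif(300), labels))
  expect_lt(abs(mean(aucs) - 0.1), 0.03)
  expect_error(classification_report(c(0.2, 0.8), c(1, 1)),
               class = "qsiraug_contract")
})

test_that("strategy comparison is a Welch t-test with its symmetries", {
  r <- compare_strategies(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  r_swap <- compare_strategies(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r_swap$statistic, -r$statistic)
  expect_equal(r_swap$p_value, r$p_value)
  same <- compare_strategies(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_strategies(c(1, 1), c(3, 3)),
               class = "qsiraug_contract")
})
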