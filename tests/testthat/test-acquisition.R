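# Acquisition strategies and the EPIG estimator.

toy_pool <- function(n = 12) {
  fx <- fix_fixture_pool()[seq_len(n), ]
  tibble::tibble(smiles = fx$smiles, m = seq(0.9, 0.1, length.out = n),
                 in_test = FALSE)
}

test_that("the combined score is the weighted sum of its components", {
  expect_equal(combined_score(0.7, 0.2, 1, 1), 0.9)
  expect_equal(combined_score(0.7, 0.9, 1, 0), 0.7)  # beta = 0: predictor only
  expect_equal(combined_score(0, 0, 1, 1), 0)
})

test_that("random acquisition is uniform, seeded and bounded by the pool", {
  pool <- toy_pool(8)
  all8 <- acquire_random(pool, 8, seed = 1)
  expect_setequal(all8$smiles, pool$smiles)
  expect_error(acquire_random(pool, 9, seed = 1),
               class = "qsiraug_contract")
  expect_identical(acquire_random(pool, 3, seed = 5)$smiles,
                   acquire_random(pool, 3, seed = 5)$smiles)
  # uniformity over a 4-molecule pool, k = 1, many seeds
  small <- toy_pool(4)
  draws <- vapply(1:2000, function(s)
    acquire_random(small, 1, seed = s)$smiles, character(1))
  chi <- chisq.test(table(factor(draws, levels = small$smiles)))
  expect_gt(chi$p.value, 0.01)
})

test_that("greedy acquisition takes the top-k with the canonical tie rule", {
  pool <- toy_pool(6)
  sel <- acquire_greedy(pool, 2)
  expect_identical(sel$smiles, pool$smiles[1:2])
  expect_identical(nrow(acquire_greedy(pool, 0)), 0L)
  tied <- pool; tied$m <- rep(0.5, 6)
  sel_tied <- acquire_greedy(tied, 2)
  expect_identical(sel_tied$smiles,
                   sort(tied$smiles, method = "radix")[1:2])
})

test_that("EPIG matches hand-enumerated two-tree cases", {
  # candidate votes (1,0) with tree-aligned target votes (1,0):
  # joint {(1,1): .5, (0,0): .5}, marginals .5/.5 -> KL = ln 2
  cand <- matrix(c(1L, 0L), 1)
  tgt_aligned <- matrix(c(1L, 0L), 1)
  expect_equal(epig_scores(cand, tgt_aligned, pair_samples = Inf),
               log(2))
  # target votes (1,1): joint factorizes -> 0
  tgt_const <- matrix(c(1L, 1L), 1)
  expect_equal(epig_scores(cand, tgt_const, pair_samples = Inf), 0)
  # deterministic ensemble: all trees agree everywhere -> EPIG 0 exactly
  votes <- matrix(1L, 5, 8)
  expect_identical(epig_scores(votes, votes, pair_samples = Inf),
                   rep(0, 5))
})

test_that("EPIG is non-negative and invariant to tree reordering", {
  m <- fix_model()
  pool <- fix_fixture_pool()$smiles[1:30]
  votes <- qsir_votes(m, pool)
  tgt <- votes[1:10, ]
  ep <- epig_scores(votes, tgt, pair_samples = Inf)
  expect_true(all(ep >= 0))
  perm <- sample(ncol(votes))
  ep_perm <- epig_scores(votes[, perm], tgt[, perm], pair_samples = Inf)
  expect_equal(ep, ep_perm)
})

test_that("sampled EPIG converges to the exhaustive average", {
  m <- fix_model()
  pool <- fix_fixture_pool()$smiles[1:40]
  votes <- qsir_votes(m, pool)
  tgt <- votes
  exact <- epig_scores(votes, tgt, pair_samples = Inf)
  est <- epig_scores(votes, tgt, pair_samples = 35, seed = 2)
  expect_lt(max(abs(est - exact)), 0.15)
  full <- epig_scores(votes, tgt, pair_samples = 40, seed = 2)
  expect_equal(full, exact)  # sampling everything is the exact average
})

test_that("epig acquisition delegates to the scores with the shared tie rule", {
  m <- fix_model()
  fx <- fix_fixture_pool()[1:25, ]
  pr <- predict(m, fx$smiles)
  pool <- tibble::tibble(smiles = fx$smiles, m = pr$m, in_test = FALSE)
  cfg <- acquisition_config("epig", k = 5, epig_target_size = 10,
                            epig_pair_samples = Inf)
  sel <- acquire_epig(pool, m, cfg, seed = 1)
  expect_identical(nrow(sel), 5L)
  votes <- qsir_votes(m, pool$smiles)
  tgt <- order(-pool$m, pool$smiles, method = "radix")[1:10]
  ep <- epig_scores(votes, votes[tgt, ], pair_samples = Inf)
  expect_identical(sel$smiles,
                   pool$smiles[order(-ep, pool$smiles,
                                     method = "radix")][1:5])
})

test_that("skill variants reduce to their components in degenerate cases", {
  pool <- toy_pool(10)
  m <- fix_model()
  cfg <- acquisition_config("greedy_skill", k = 4)
  const_expert <- function(smiles) rep(1, length(smiles))
  sel_const <- acquire_with_skill(pool, m, const_expert, cfg)
  expect_identical(sel_const$smiles, acquire_greedy(pool, 4)$smiles)

  flat <- pool; flat$m <- rep(0.5, 10)
  len_expert <- function(smiles) nchar(smiles)
  sel_expert <- acquire_with_skill(flat, m, len_expert, cfg)
  raw <- nchar(flat$smiles)
  want <- flat$smiles[order(-normalize_preferences(raw, "higher"),
                            flat$smiles, method = "radix")][1:4]
  expect_identical(sel_expert$smiles, want)
})

test_that("a five-molecule pool matches brute-force combined scoring", {
  pool <- toy_pool(5)
  m <- fix_model()
  expert <- function(smiles) vapply(smiles, function(s)
    sum(utf8ToInt(s)), numeric(1))
  cfg <- acquisition_config("greedy_skill", k = 2)
  sel <- acquire_with_skill(pool, m, expert, cfg)
  a_pred <- normalize_preferences(pool$m, "higher")
  a_human <- normalize_preferences(expert(pool$smiles), "higher")
  a <- a_pred + a_human
  want <- pool$smiles[order(-a, pool$smiles, method = "radix")][1:2]
  expect_identical(sel$smiles, want)
  expect_equal(sel$a_combined,
               sort(a, decreasing = TRUE)[1:2], tolerance = 1e-12)
})

test_that("acquisition never returns test molecules or duplicates", {
  fx <- fix_fixture_pool()[1:20, ]
  pool <- tibble::tibble(
    smiles = rep(fx$smiles, 2),                 # duplicated pool
    m = rep(seq(1, 0.05, length.out = 20), 2),
    in_test = rep(c(rep(TRUE, 5), rep(FALSE, 15)), 2))
  sel <- acquire_greedy(pool, 10)
  expect_identical(anyDuplicated(sel$smiles), 0L)
  expect_true(all(!sel$smiles %in% fx$smiles[1:5]))
})
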