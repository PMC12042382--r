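# Reward shaping and the stub generators.

test_that("the molecular-weight trapezoid matches its declared shape", {
  expect_equal(mw_desirability(c(160, 300, 480)), c(1, 1, 1))
  expect_equal(mw_desirability(c(100, 120, 520, 600)), c(0, 0, 0, 0))
  expect_equal(mw_desirability(c(140, 500)), c(0.5, 0.5))  # ramp midpoints
})

test_that("the reward is the normalized convex combination", {
  expect_equal(reward(1, 1), 1)
  expect_equal(reward(0.5, 1), 0.6)     # 0.8*0.5 + 0.2*1
  expect_equal(reward(1, 0), 0.8)
  # explicit weights are normalized to sum to one
  w <- reward_weights(4, 1)
  expect_equal(w$w1, 0.8)
  expect_equal(reward(0.5, 1, w), 0.6)
  expect_error(reward_weights(0, 0), class = "qsiraug_contract")
})

test_that("reward is monotone in each component", {
  set.seed(7)
  m <- runif(30); wt <- runif(30)
  base <- reward(m, wt)
  expect_true(all(reward(pmin(m + 0.1, 1), wt) >= base))
  expect_true(all(reward(m, pmin(wt + 0.1, 1)) >= base))
})

test_that("a generation stage yields the scheduled pool with bounded scores", {
  sc <- qsir_scorer(fix_model())
  gen <- stub_resampling_generator(fix_fixture_pool())
  pool <- run_generation_stage(gen, sc, generation_schedule(2, 5), seed = 1)
  expect_identical(nrow(pool), 10L)
  expect_true(all(is.finite(pool$reward)))
  expect_true(all(pool$reward >= 0 & pool$reward <= 1))
  expect_true(all(c("m", "wt", "step", "in_train", "in_test") %in%
                    names(pool)))
})

test_that("generated duplicates of train/test molecules are flagged", {
  sc <- qsir_scorer(fix_model())
  gen <- stub_resampling_generator(fix_fixture_pool())
  tr <- fix_fixture_pool()$smiles[1:50]
  te <- fix_fixture_pool()$smiles[51:100]
  pool <- run_generation_stage(gen, sc, generation_schedule(8, 25), seed = 2,
                               train_smiles = tr, test_smiles = te)
  expect_identical(pool$in_train, pool$smiles %in% tr)
  expect_identical(pool$in_test, pool$smiles %in% te)
})

test_that("the resampler is near-uniform at high temperature and peaked at low", {
  fx <- fix_fixture_pool()[1:40, ]
  sc <- qsir_scorer(fix_model())
  hot <- stub_resampling_generator(fx, tau_start = 1e6, tau_end = 1e6)
  prop <- propose_molecules(hot, sc, generation_schedule(40, 25), seed = 3)
  counts <- table(factor(prop$smiles, levels = fx$smiles))
  chi <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(chi$p.value, 0.01)

  cold <- stub_resampling_generator(fx, tau_start = 1e-4, tau_end = 1e-4)
  prop_cold <- propose_molecules(cold, sc, generation_schedule(40, 1),
                                 seed = 3)
  scored <- sc(fx$smiles)
  best <- fx$smiles[which.max(scored$reward)]
  expect_gt(mean(prop_cold$smiles == best), 0.9)

  expect_identical(propose_molecules(hot, sc, generation_schedule(3, 5), 9),
                   propose_molecules(hot, sc, generation_schedule(3, 5), 9))
})

test_that("the GA increases planted-rule content under a rule scorer", {
  rule_scorer <- function(smiles) {
    hit <- smarts_match_any(smiles, planted_rules())
    tibble::tibble(smiles = smiles, m = as.numeric(hit), wt = 1,
                   reward = as.numeric(hit))
  }
  wins <- 0
  for (s in 1:5) {
    gen <- stub_ga_generator()
    prop <- propose_molecules(gen, rule_scorer, generation_schedule(12, 25),
                              seed = 100 + s)
    early <- smarts_match_any(prop$smiles[prop$step <= 3],
                              planted_rules())
    late <- smarts_match_any(prop$smiles[prop$step >= 10],
                             planted_rules())
    if (mean(late) > mean(early)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("a constant scorer applies no selection pressure to the GA", {
  const_scorer <- function(smiles) {
    tibble::tibble(smiles = smiles, m = 0.5, wt = 0.5, reward = 0.5)
  }
  gen <- stub_ga_generator()
  prop <- propose_molecules(gen, const_scorer, generation_schedule(10, 30),
                            seed = 5)
  # under a flat landscape rule content stays near the grammar base rate
  early <- mean(smarts_match_any(prop$smiles[prop$step <= 2],
                                 planted_rules()))
  late <- mean(smarts_match_any(prop$smiles[prop$step >= 9],
                                planted_rules()))
  expect_lt(abs(late - early), 0.25)
})

test_that("the scaffold cap bounds per-scaffold occurrences in the pool", {
  const_scorer <- function(smiles) {
    tibble::tibble(smiles = smiles, m = 0.5, wt = 0.5, reward = 0.5)
  }
  gen <- stub_ga_generator(scaffold_cap = 10)
  prop <- propose_molecules(gen, const_scorer, generation_schedule(12, 25),
                            seed = 6)
  counts <- attr(prop, "scaffold_counts")
  expect_lte(max(counts), 10)
  # the filter costs pool rows once every scaffold is saturated
  expect_lte(nrow(prop), 12 * 25)
})
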