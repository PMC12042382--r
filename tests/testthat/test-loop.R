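# The self-distillation loop: labeling, augmentation, iteration contract.

test_that("pseudo-labeling applies the threshold inclusively", {
  expect_identical(pseudo_label(c(0.9, 0.5, 0.49), 0.5), c(1L, 1L, 0L))
  expect_identical(pseudo_label(numeric(0)), integer(0))
})

test_that("augmentation grows the set, keeps measured labels and guards the test set", {
  train <- tibble::tibble(smiles = c("CCO", "CCC"), label = c(0L, 1L),
                          provenance = "original")
  acq <- tibble::tibble(smiles = c("CCN", "CCF"))
  out <- augment_training_set(train, acq, c(1L, 0L), iteration = 2)
  expect_identical(nrow(out), 4L)
  expect_identical(out$provenance[3:4], rep("generated-iteration-2", 2))
  # collision: existing label wins
  coll <- tibble::tibble(smiles = "CCO")
  expect_message(
    out2 <- augment_training_set(train, coll, 1L),
    "already in training set")
  expect_identical(out2$label[out2$smiles == "CCO"], 0L)
  expect_identical(nrow(out2), 2L)
  # empty acquisition leaves the set unchanged
  empty <- tibble::tibble(smiles = character(0))
  expect_identical(augment_training_set(train, empty, integer(0)), train)
  # leakage guard
  expect_error(
    augment_training_set(train, acq, c(1L, 0L), test_smiles = "CCN"),
    class = "qsiraug_leakage")
})

test_that("one iteration acquires k molecules and yields finite metrics", {
  sp <- fix_split()
  cfg <- loop_config(acquisition = acquisition_config("greedy", k = 10),
                     schedule = generation_schedule(4, 20),
                     n_iterations = 1, n_repetitions = 1, master_seed = 7)
  state <- init_distillation(sp$train, sp$test, cfg,
                             stub_ga_generator(),
                             qsir_hyperparams(n_estimators = 80),
                             run_seed = 7)
  state2 <- run_iteration(state)
  rec <- state2$records[state2$records$iteration == 1, ]
  expect_identical(rec$n_acquired, 10L)
  expect_identical(nrow(state2$train), nrow(sp$train) + 10L -
                     sum(state2$acquired[[1]]$smiles %in% sp$train$smiles))
  for (col in c("ir", "mcc", "ef", "balanced_accuracy", "pr_auc",
                "acquired_intdiv", "cka_vs_teacher")) {
    expect_true(is.finite(rec[[col]]), info = col)
  }
  # training set growth is monotone and bounded by k
  expect_gte(nrow(state2$train), nrow(sp$train))
  expect_lte(nrow(state2$train), nrow(sp$train) + 10L)
  # no test molecule ever enters training
  expect_identical(intersect(state2$train$smiles, sp$test$smiles),
                   character(0))
})

test_that("runs are reproducible and experiments have the declared shape", {
  ds <- fix_benchmark()
  cfg <- loop_config(acquisition = acquisition_config("greedy", k = 10),
                     schedule = generation_schedule(4, 15),
                     n_iterations = 2, n_repetitions = 2,
                     hyperparams = qsir_hyperparams(n_estimators = 60),
                     master_seed = 31)
  e1 <- run_experiment(cfg, ds, stub_ga_generator())
  e2 <- run_experiment(cfg, ds, stub_ga_generator())
  expect_identical(e1$summary, e2$summary)
  expect_identical(length(e1$runs), 2L)
  expect_identical(nrow(e1$summary), 2L * 3L)  # runs x (baseline + 2 iters)
  expect_identical(unique(e1$summary$strategy), "greedy")
  gl <- generics::glance(e1$runs[[1]])
  expect_identical(gl$n_iterations, 2L)
  td <- generics::tidy(e1$runs[[1]])
  expect_true(all(c("iteration", "metric", "value") %in% names(td)))
})

test_that("random and skill strategies run end to end", {
  sp <- fix_split()
  for (strat in c("random", "greedy_skill")) {
    cfg <- loop_config(acquisition = acquisition_config(strat, k = 8),
                       schedule = generation_schedule(3, 15),
                       n_iterations = 1, n_repetitions = 1, master_seed = 3)
    run <- run_self_distillation(sp$train, sp$test, cfg,
                                 stub_resampling_generator(fix_fixture_pool()),
                                 qsir_hyperparams(n_estimators = 50),
                                 expert = expert_heuristic_proxy(),
                                 run_seed = 3)
    expect_identical(max(run$records$iteration), 1L)
    expect_identical(run$records$n_acquired[2], 8L)
  }
})
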