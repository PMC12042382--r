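# The self-distillation loop: teacher -> goal-directed generation ->
# acquisition -> pseudo-labeling -> augmentation -> student retraining,
# repeated for a fixed number of iterations and replicated over seeded
# independent runs.

# Deterministic seed stream: master seed -> run/iteration seeds, all kept
# inside the 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + i * 7919 + 1) %%
               2147483629)
}

#' Loop configuration
#'
#' Defaults mirror the study design: five iterations, ten repetitions,
#' 250 molecules acquired per iteration out of a 250 x 100 generation
#' stage, reward weights 0.8/0.2, pseudo-label threshold 0.5.
#'
#' @param acquisition An [acquisition_config()].
#' @param schedule A [generation_schedule()].
#' @param weights A [reward_weights()].
#' @param n_iterations Distillation iterations per run (default 5).
#' @param n_repetitions Independent runs (default 10).
#' @param pseudo_label_threshold Probability cut for pseudo-labels,
#'   in (0, 1).
#' @param hyperparams A frozen [qsir_hyperparams()], or `NULL` to run the
#'   cross-validated search once before the first iteration.
#' @param n_trials,n_folds Search budget when `hyperparams` is `NULL`.
#' @param test_fraction Held-out fraction of the data set.
#' @param master_seed Seed from which all run/iteration seeds derive.
#' @param keep_models Keep every student model in the run records (needed
#'   for inter-student CKA; costly at full scale).
#' @return A `loop_config` list.
#' @export
loop_config <- function(acquisition = acquisition_config("greedy"),
                        schedule = generation_schedule(),
                        weights = reward_weights(),
                        n_iterations = 5, n_repetitions = 10,
                        pseudo_label_threshold = 0.5,
                        hyperparams = NULL, n_trials = 50, n_folds = 5,
                        test_fraction = 0.25,
                        master_seed = 1, keep_models = FALSE) {
  stopifnot(inherits(acquisition, "acquisition_config"),
            inherits(schedule, "generation_schedule"),
            inherits(weights, "reward_weights"),
            n_iterations >= 1, n_repetitions >= 1,
            pseudo_label_threshold > 0, pseudo_label_threshold < 1)
  structure(
    list(acquisition = acquisition, schedule = schedule, weights = weights,
         n_iterations = as.integer(n_iterations),
         n_repetitions = as.integer(n_repetitions),
         pseudo_label_threshold = pseudo_label_threshold,
         hyperparams = hyperparams, n_trials = n_trials, n_folds = n_folds,
         test_fraction = test_fraction,
         master_seed = as.integer(master_seed),
         keep_models = keep_models),
    class = "loop_config"
  )
}

#' Pseudo-label probabilities
#'
#' Label 1 if and only if the predicted probability reaches the threshold.
#'
#' @param probs Probabilities in \[0, 1\].
#' @param threshold Cut point (default 0.5; the boundary itself labels 1).
#' @return Integer 0/1 labels.
#' @export
pseudo_label <- function(probs, threshold = 0.5) {
  stopifnot(all(probs >= 0 & probs <= 1))
  as.integer(probs >= threshold)
}

#' Augment a training set with pseudo-labeled molecules
#'
#' Union by canonical SMILES: molecules already in the training set keep
#' their existing label (measured labels beat pseudo-labels; collisions are
#' messaged), new molecules enter with their pseudo-label and a provenance
#' tag. Any overlap with the test set is an error.
#'
#' @param train Tibble with `smiles`, `label`, `provenance`.
#' @param acquired Tibble with `smiles` (canonical).
#' @param labels Integer pseudo-labels aligned with `acquired`.
#' @param test_smiles Canonical test-set SMILES (leakage guard).
#' @param iteration Iteration index recorded in the provenance tag.
#' @return The augmented training tibble.
#' @export
augment_training_set <- function(train, acquired, labels,
                                 test_smiles = character(0), iteration = 1) {
  stopifnot(nrow(acquired) == length(labels))
  if (any(acquired$smiles %in% test_smiles)) {
    rlang::abort("acquired molecules overlap the test set",
                 class = "qsiraug_leakage")
  }
  dup <- acquired$smiles %in% train$smiles
  n_coll <- sum(dup)
  if (n_coll > 0) {
    coll <- acquired$smiles[dup]
    changed <- sum(train$label[match(coll, train$smiles)] != labels[dup])
    rlang::inform(sprintf(
      "%d acquired molecules already in training set (kept existing labels; %d pseudo-labels disagreed)",
      n_coll, changed))
  }
  if (all(dup)) return(train)
  new_rows <- tibble::tibble(
    smiles = acquired$smiles[!dup],
    label = as.integer(labels[!dup]),
    provenance = paste0("generated-iteration-", iteration)
  )
  dplyr::bind_rows(train, new_rows)
}

evaluate_iteration <- function(model, train, test, acquired, initial_model,
                               initial_scaffold_fps, iteration) {
  pr <- predict(model, test)
  rep <- classification_report(pr$m, test$label)
  acq_smiles <- acquired$smiles
  intdiv <- if (length(acq_smiles) > 0) internal_diversity(acq_smiles)
            else NA_real_
  pains <- if (length(acq_smiles) > 0) count_pains(acq_smiles) else NA_integer_
  qed_mean <- if (length(acq_smiles) > 0) mean(qed_score(acq_smiles)$qed)
              else NA_real_
  scaf_sim <- if (length(acq_smiles) > 0 && !is.null(initial_scaffold_fps)) {
    scaf <- murcko_scaffold(acq_smiles)
    cyc <- nzchar(scaf) & !is.na(scaf)
    if (any(cyc)) {
      fp_new <- morgan_fingerprint(scaf[cyc], radius = 2, nbits = 2048)
      mean(apply(tanimoto_matrix(fp_new, initial_scaffold_fps), 1, max))
    } else NA_real_
  } else NA_real_
  cka_val <- if (!is.null(initial_model)) {
    model_cka(initial_model, model, test$smiles)
  } else NA_real_
  tibble::tibble(
    iteration = iteration,
    n_train = nrow(train),
    n_pos = sum(train$label == 1),
    n_neg = sum(train$label == 0),
    ir = imbalance_rate(sum(train$label == 1), sum(train$label == 0)),
    n_acquired = nrow(acquired),
    n_pseudo_pos = if (nrow(acquired)) sum(acquired$pseudo_label == 1)
                   else NA_integer_,
    acquired_intdiv = intdiv,
    acquired_pains = pains,
    acquired_mean_qed = qed_mean,
    scaffold_similarity = scaf_sim,
    mcc = rep$mcc, ef = rep$ef,
    balanced_accuracy = rep$balanced_accuracy, pr_auc = rep$pr_auc,
    cka_vs_teacher = cka_val
  )
}

#' Run one distillation iteration
#'
#' Executes a full cycle against the current state: generation stage under
#' the current teacher's reward, acquisition, pseudo-labeling, training-set
#' augmentation, student retraining with the frozen hyperparameters, and
#' metric evaluation.
#'
#' @param state A loop state as produced by [init_distillation()] or a
#'   previous `run_iteration()` call.
#' @return The updated state; the new iteration record is appended to
#'   `state$records`.
#' @export
run_iteration <- function(state) {
  t <- state$iteration + 1L
  seed_gen <- derive_seed(state$run_seed, 3L * t)
  seed_acq <- derive_seed(state$run_seed, 3L * t + 1L)
  seed_fit <- derive_seed(state$run_seed, 3L * t + 2L)

  scorer <- qsir_scorer(state$model, state$cfg$weights)
  pool <- run_generation_stage(state$generator, scorer, state$cfg$schedule,
                               seed = seed_gen,
                               train_smiles = state$train$smiles,
                               test_smiles = state$test$smiles)
  acq <- acquire(pool, state$model, state$cfg$acquisition,
                 expert = state$expert, seed = seed_acq)
  probs <- predict(state$model, acq$smiles)$m
  labels <- pseudo_label(probs, state$cfg$pseudo_label_threshold)
  acq$pseudo_label <- labels
  train2 <- suppressMessages(
    augment_training_set(state$train, acq, labels,
                         test_smiles = state$test$smiles, iteration = t))
  model2 <- qsir_train(train2, state$hyperparams, seed = seed_fit)

  rec <- evaluate_iteration(model2, train2, state$test, acq,
                            state$initial_model, state$initial_scaffold_fps,
                            iteration = t)
  state$model <- model2
  state$train <- train2
  state$iteration <- t
  state$records <- dplyr::bind_rows(state$records, rec)
  state$acquired[[t]] <- acq
  if (isTRUE(state$cfg$keep_models)) state$models[[t]] <- model2
  state
}

#' Initialize a distillation run
#'
#' Trains the initial teacher and evaluates the iteration-0 baseline.
#'
#' @param train,test Tibbles with `smiles`, `label` (and `provenance`).
#' @param cfg A [loop_config()].
#' @param generator A generator implementing [propose_molecules()].
#' @param hyperparams Frozen [qsir_hyperparams()].
#' @param expert Optional expert scorer (required for Skill strategies).
#' @param run_seed Seed of this repetition.
#' @return A loop state list.
#' @export
init_distillation <- function(train, test, cfg, generator, hyperparams,
                              expert = NULL, run_seed = 1) {
  if (!"provenance" %in% names(train)) train$provenance <- "original"
  model <- qsir_train(train, hyperparams, seed = derive_seed(run_seed, 0L))
  scaf <- murcko_scaffold(train$smiles)
  scaf <- unique(scaf[nzchar(scaf) & !is.na(scaf)])
  scaf_fps <- if (length(scaf)) morgan_fingerprint(scaf, radius = 2,
                                                   nbits = 2048) else NULL
  state <- list(
    cfg = cfg, generator = generator, expert = expert,
    hyperparams = hyperparams, run_seed = run_seed,
    train = train, test = test,
    model = model, initial_model = model, initial_scaffold_fps = scaf_fps,
    iteration = 0L, acquired = list(), models = list()
  )
  empty_acq <- tibble::tibble(smiles = character(0),
                              pseudo_label = integer(0))
  state$records <- evaluate_iteration(model, train, test, empty_acq,
                                      NULL, NULL, iteration = 0L)
  state$records$cka_vs_teacher <- 1
  state
}

#' Run one repetition of the self-distillation loop
#'
#' @inheritParams init_distillation
#' @return A `distill_run` object: the per-iteration record tibble plus
#'   the acquired sets and (optionally) the student models.
#' @export
run_self_distillation <- function(train, test, cfg, generator, hyperparams,
                                  expert = NULL, run_seed = 1) {
  state <- init_distillation(train, test, cfg, generator, hyperparams,
                             expert = expert, run_seed = run_seed)
  for (t in seq_len(cfg$n_iterations)) {
    state <- run_iteration(state)
  }
  structure(
    list(records = state$records, acquired = state$acquired,
         models = state$models, final_model = state$model,
         initial_model = state$initial_model,
         config = cfg, run_seed = run_seed),
    class = "distill_run"
  )
}

#' @export
print.distill_run <- function(x, ...) {
  cat("<distill_run> seed", x$run_seed, "-",
      x$config$acquisition$strategy, "acquisition,",
      x$config$n_iterations, "iterations\n")
  print(x$records[, c("iteration", "n_train", "ir", "mcc", "ef",
                      "balanced_accuracy", "pr_auc")])
  invisible(x)
}

#' Run a replicated distillation experiment
#'
#' Generates (or accepts) a benchmark data set, splits it once, freezes
#' hyperparameters once, and executes `n_repetitions` independent seeded
#' runs of the loop.
#'
#' @param cfg A [loop_config()].
#' @param data A labeled tibble (`smiles`, `label`), or a
#'   [benchmark_config()] to generate one.
#' @param generator A generator object (shared across runs).
#' @param expert Optional expert scorer.
#' @return A `distill_experiment`: list of `distill_run`s plus the shared
#'   split and a long summary tibble.
#' @export
run_experiment <- function(cfg, data, generator, expert = NULL) {
  stopifnot(inherits(cfg, "loop_config"))
  if (inherits(data, "benchmark_config")) data <- generate_benchmark(data)
  split <- stratified_split(data, test_fraction = cfg$test_fraction,
                            n_folds = cfg$n_folds,
                            seed = derive_seed(cfg$master_seed, 0L))
  hp <- cfg$hyperparams
  if (is.null(hp)) {
    hp <- optimize_hyperparams(split$train, n_trials = cfg$n_trials,
                               n_folds = cfg$n_folds,
                               seed = derive_seed(cfg$master_seed, 1L))
  }
  runs <- vector("list", cfg$n_repetitions)
  for (r in seq_len(cfg$n_repetitions)) {
    runs[[r]] <- run_self_distillation(
      split$train, split$test, cfg, generator, hp, expert = expert,
      run_seed = derive_seed(cfg$master_seed, 100L + r))
  }
  summary <- dplyr::bind_rows(lapply(seq_along(runs), function(r) {
    dplyr::mutate(runs[[r]]$records, run = r,
                  strategy = cfg$acquisition$strategy,
                  .before = 1)
  }))
  structure(
    list(runs = runs, summary = summary, split = split,
         hyperparams = hp, config = cfg),
    class = "distill_experiment"
  )
}

#' @export
print.distill_experiment <- function(x, ...) {
  cat("<distill_experiment>", length(x$runs), "runs x",
      x$config$n_iterations, "iterations,",
      x$config$acquisition$strategy, "acquisition\n")
  agg <- dplyr::summarise(
    dplyr::group_by(x$summary, iteration),
    mcc = mean(mcc), ef = mean(ef), ir = mean(ir), .groups = "drop")
  print(agg)
  invisible(x)
}

#' Tidy a distillation run
#'
#' @param x A `distill_run`.
#' @param ... Unused.
#' @return Long tibble: one row per iteration and metric.
#' @export
#' @method tidy distill_run
tidy.distill_run <- function(x, ...) {
  tidyr::pivot_longer(x$records, -iteration, names_to = "metric",
                      values_to = "value",
                      values_transform = as.numeric)
}

#' One-row summary of a distillation run
#'
#' @param x A `distill_run`.
#' @param ... Unused.
#' @return One-row tibble: baseline and final MCC/EF/IR.
#' @export
#' @method glance distill_run
glance.distill_run <- function(x, ...) {
  r0 <- x$records[x$records$iteration == 0, ]
  rT <- x$records[which.max(x$records$iteration), ]
  tibble::tibble(
    n_iterations = max(x$records$iteration),
    strategy = x$config$acquisition$strategy,
    mcc_baseline = r0$mcc, mcc_final = rT$mcc,
    ef_baseline = r0$ef, ef_final = rT$ef,
    ir_baseline = r0$ir, ir_final = rT$ir,
    run_seed = x$run_seed
  )
}

#' Tidy a distillation experiment
#'
#' @param x A `distill_experiment`.
#' @param ... Unused.
#' @return The long summary tibble (run x iteration x metrics).
#' @export
#' @method tidy distill_experiment
tidy.distill_experiment <- function(x, ...) {
  tidyr::pivot_longer(x$summary, -c(run, strategy, iteration),
                      names_to = "metric", values_to = "value",
                      values_transform = as.numeric)
}

#' Experiment summary table
#'
#' Wide per-run, per-iteration metric table suitable for CSV export; the
#' table is a pure function of (config, data, master seed).
#'
#' @param x A `distill_experiment`.
#' @return Tibble.
#' @export
experiment_summary <- function(x) {
  stopifnot(inherits(x, "distill_experiment"))
  x$summary
}
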