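# YAML configuration surface and the three command entry points used by
# the inst/scripts/qsiraug launcher. The commands do no computation of
# their own: they validate a config, call the package functions, and lay
# out a run directory.

config_schema <- function() {
  list(
    dataset = c("file", "benchmark"),
    benchmark = c("n_compounds", "positive_rate", "label_noise", "seed"),
    loop = c("strategy", "k", "n_iterations", "n_repetitions", "n_steps",
             "batch_size", "w1", "w2", "pseudo_label_threshold",
             "test_fraction", "alpha", "beta", "epig_target_size",
             "epig_pair_samples", "n_trials", "n_folds", "keep_models"),
    generator = c("type", "pool_size", "pool_seed", "mutation_rate",
                  "tournament_k", "scaffold_cap", "tau_start", "tau_end"),
    expert = c("type"),
    model = c("n_estimators", "max_depth", "min_samples_split",
              "max_features"),
    master_seed = NULL,
    output_dir = NULL
  )
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    rlang::abort(sprintf("unknown configuration key%s in '%s': %s",
                         if (length(extra) > 1) "s" else "", where,
                         paste(extra, collapse = ", ")),
                 class = "qsiraug_config_error")
  }
}

#' Read and validate an experiment configuration
#'
#' The YAML schema is strict: unknown keys anywhere are an error naming the
#' offending key, and the strategy name is validated against the five
#' acquisition strategies.
#'
#' @param path Path to a YAML file.
#' @return A validated `experiment_config` list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "qsiraug_config_error")
  }
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  check_keys(raw, names(schema), "top level")
  for (section in c("dataset", "benchmark", "loop", "generator", "expert",
                    "model")) {
    if (!is.null(raw[[section]])) {
      check_keys(raw[[section]], schema[[section]], section)
    }
  }
  loop_raw <- raw$loop %||% list()
  strategy <- loop_raw$strategy %||% "greedy"
  if (!strategy %in% c("random", "greedy", "epig", "greedy_skill",
                       "epig_skill")) {
    rlang::abort(sprintf(
      "loop.strategy: unknown strategy '%s' (expected random, greedy, epig, greedy_skill or epig_skill)",
      strategy), class = "qsiraug_config_error")
  }
  gen_raw <- raw$generator %||% list()
  gen_type <- gen_raw$type %||% "ga"
  if (!gen_type %in% c("ga", "resampling")) {
    rlang::abort(sprintf("generator.type: unknown generator '%s'", gen_type),
                 class = "qsiraug_config_error")
  }
  structure(list(raw = raw, path = path), class = "experiment_config")
}

build_from_config <- function(cfg) {
  raw <- cfg$raw
  master_seed <- raw$master_seed %||% 1L
  loop_raw <- raw$loop %||% list()
  acq <- acquisition_config(
    strategy = loop_raw$strategy %||% "greedy",
    k = loop_raw$k %||% 250,
    alpha = loop_raw$alpha, beta = loop_raw$beta,
    epig_target_size = loop_raw$epig_target_size %||% 1000,
    epig_pair_samples = loop_raw$epig_pair_samples %||% 100
  )
  hp <- if (!is.null(raw$model)) {
    qsir_hyperparams(
      n_estimators = raw$model$n_estimators %||% 300,
      max_depth = raw$model$max_depth %||% 0,
      min_samples_split = raw$model$min_samples_split %||% 2,
      max_features = raw$model$max_features %||% "sqrt"
    )
  } else NULL
  lc <- loop_config(
    acquisition = acq,
    schedule = generation_schedule(loop_raw$n_steps %||% 250,
                                   loop_raw$batch_size %||% 100),
    weights = reward_weights(loop_raw$w1 %||% 0.8, loop_raw$w2 %||% 0.2),
    n_iterations = loop_raw$n_iterations %||% 5,
    n_repetitions = loop_raw$n_repetitions %||% 10,
    pseudo_label_threshold = loop_raw$pseudo_label_threshold %||% 0.5,
    hyperparams = hp,
    n_trials = loop_raw$n_trials %||% 50,
    n_folds = loop_raw$n_folds %||% 5,
    test_fraction = loop_raw$test_fraction %||% 0.25,
    master_seed = master_seed,
    keep_models = isTRUE(loop_raw$keep_models)
  )
  data <- if (!is.null(raw$dataset$file)) {
    read_compound_csv(raw$dataset$file)
  } else {
    b <- raw$benchmark %||% list()
    generate_benchmark(benchmark_config(
      n_compounds = b$n_compounds %||% 4000,
      positive_rate = b$positive_rate %||% 0.05,
      label_noise = b$label_noise %||% 0,
      seed = b$seed %||% master_seed
    ))
  }
  gen_raw <- raw$generator %||% list()
  generator <- if (identical(gen_raw$type %||% "ga", "resampling")) {
    stub_resampling_generator(
      fixture_pool(gen_raw$pool_size %||% 2000,
                   seed = gen_raw$pool_seed %||% master_seed),
      tau_start = gen_raw$tau_start %||% 1.0,
      tau_end = gen_raw$tau_end %||% 0.2)
  } else {
    stub_ga_generator(
      mutation_rate = gen_raw$mutation_rate %||% 0.3,
      tournament_k = gen_raw$tournament_k %||% 3,
      scaffold_cap = gen_raw$scaffold_cap %||% Inf)
  }
  expert <- if (identical(raw$expert$type %||% "heuristic", "none")) NULL
            else expert_heuristic_proxy()
  list(loop = lc, data = data, generator = generator, expert = expert,
       output_dir = raw$output_dir %||% "qsiraug-run")
}

#' Read a compound CSV
#'
#' Reads a `smiles,label` CSV, canonicalizes, drops invalid molecules with
#' a message and deduplicates by canonical SMILES.
#'
#' @param path CSV path with columns `smiles` and `label`.
#' @return Tibble with `smiles` (canonical), `label`, `provenance`.
#' @export
read_compound_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "label") %in% names(raw)))
  parsed <- parse_and_canonicalize(raw$smiles)
  keep <- parsed$valid & !duplicated(parsed$canonical_smiles)
  tibble::tibble(smiles = parsed$canonical_smiles[keep],
                 label = as.integer(raw$label[keep]),
                 provenance = "original")
}

#' Write a labeled compound set to CSV
#'
#' @param ds Tibble with `smiles` and `label`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_compound_csv <- function(ds, path) {
  utils::write.csv(ds[, intersect(c("smiles", "label", "provenance"),
                                  names(ds))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run an experiment from a configuration file
#'
#' Executes the configured experiment and lays out a run directory:
#' `config.yaml` (copy), `summary.csv`, `iter_<t>/acquired.csv` and
#' `iter_<t>/metrics.json` per run/iteration, and `ttest.csv` placeholder
#' tables from [cmd_report()].
#'
#' @param config_path Path to a YAML configuration.
#' @param output_dir Overrides the configured output directory.
#' @return The run directory path, invisibly.
#' @export
cmd_run <- function(config_path, output_dir = NULL) {
  cfg <- read_experiment_config(config_path)
  built <- build_from_config(cfg)
  out_dir <- output_dir %||% built$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(config_path, file.path(out_dir, "config.yaml"),
            overwrite = TRUE)
  exp <- run_experiment(built$loop, built$data, built$generator,
                        expert = built$expert)
  utils::write.csv(experiment_summary(exp),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  for (r in seq_along(exp$runs)) {
    run <- exp$runs[[r]]
    run_dir <- file.path(out_dir, sprintf("run_%02d", r))
    for (t in seq_along(run$acquired)) {
      it_dir <- file.path(run_dir, sprintf("iter_%d", t))
      dir.create(it_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(run$acquired[[t]],
                       file.path(it_dir, "acquired.csv"), row.names = FALSE)
      rec <- run$records[run$records$iteration == t, ]
      jsonlite::write_json(as.list(rec), file.path(it_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  rlang::inform(paste0("run complete: ", out_dir))
  invisible(out_dir)
}

#' Generate a benchmark data set from a configuration file
#'
#' @param config_path Path to a YAML configuration with a `benchmark`
#'   section.
#' @param out Output CSV path.
#' @return The output path, invisibly.
#' @export
cmd_benchmark <- function(config_path, out = "benchmark.csv") {
  cfg <- read_experiment_config(config_path)
  b <- cfg$raw$benchmark %||% list()
  ds <- generate_benchmark(benchmark_config(
    n_compounds = b$n_compounds %||% 4000,
    positive_rate = b$positive_rate %||% 0.05,
    label_noise = b$label_noise %||% 0,
    seed = b$seed %||% (cfg$raw$master_seed %||% 1L)
  ))
  write_compound_csv(ds, out)
  rlang::inform(paste0("benchmark written: ", out))
  invisible(out)
}

#' Summarize a completed run directory
#'
#' Rebuilds the per-iteration aggregate table from `summary.csv` and, when
#' several strategies' run directories are given, the Welch t-test
#' comparison table at the final iteration.
#'
#' @param run_dir Run directory (from [cmd_run()]), or several.
#' @param metric Metric column to compare across strategies.
#' @return List with `aggregate` (tibble) and `ttests` (tibble or NULL).
#' @export
cmd_report <- function(run_dir, metric = "mcc") {
  summaries <- lapply(run_dir, function(d) {
    f <- file.path(d, "summary.csv")
    if (!file.exists(f)) {
      rlang::abort(paste0("incomplete run directory (no summary.csv): ", d),
                   class = "qsiraug_config_error")
    }
    tibble::as_tibble(utils::read.csv(f))
  })
  all <- dplyr::bind_rows(summaries)
  aggregate <- dplyr::summarise(
    dplyr::group_by(all, strategy, iteration),
    dplyr::across(dplyr::all_of(c("mcc", "ef", "ir", "balanced_accuracy",
                                  "pr_auc")),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~stats::sd(.x, na.rm = TRUE))),
    .groups = "drop")
  ttests <- NULL
  strategies <- unique(all$strategy)
  if (length(strategies) >= 2) {
    last_iter <- max(all$iteration)
    final <- all[all$iteration == last_iter, ]
    pairs <- utils::combn(strategies, 2, simplify = FALSE)
    ttests <- dplyr::bind_rows(lapply(pairs, function(p) {
      a <- final[[metric]][final$strategy == p[1]]
      b <- final[[metric]][final$strategy == p[2]]
      out <- compare_strategies(a, b, metric = metric)
      out$strategy_a <- p[1]; out$strategy_b <- p[2]
      out
    }))
  }
  list(aggregate = aggregate, ttests = ttests)
}
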