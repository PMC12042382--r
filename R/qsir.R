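# The teacher/student classifier: a balanced random forest (every tree is
# grown on a bootstrap holding equally many positives and negatives) over
# Morgan-3/2048 fingerprints, trained with ranger. Probabilities are the
# fraction of per-tree votes for the interference class, which keeps
# predict_proba, the EPIG vote matrix and the leaf kernel consistent with
# one fitted forest.

#' Hyperparameters for the balanced random forest
#'
#' @param n_estimators Number of trees (100-1000).
#' @param max_depth Maximum tree depth; `0` means unlimited.
#' @param min_samples_split Minimum node size eligible for splitting (2-16).
#' @param max_features Features tried per split: `"sqrt"`, `"log2"` or a
#'   fraction in (0, 1\].
#' @return A `qsir_hyperparams` list.
#' @export
qsir_hyperparams <- function(n_estimators = 300, max_depth = 0,
                             min_samples_split = 2, max_features = "sqrt") {
  stopifnot(n_estimators >= 1, max_depth >= 0, min_samples_split >= 2)
  if (is.character(max_features)) {
    stopifnot(max_features %in% c("sqrt", "log2"))
  } else {
    stopifnot(is.numeric(max_features), max_features > 0, max_features <= 1)
  }
  structure(
    list(n_estimators = as.integer(n_estimators),
         max_depth = as.integer(max_depth),
         min_samples_split = as.integer(min_samples_split),
         max_features = max_features),
    class = "qsir_hyperparams"
  )
}

resolve_mtry <- function(max_features, n_features) {
  m <- if (identical(max_features, "sqrt")) {
    sqrt(n_features)
  } else if (identical(max_features, "log2")) {
    log2(n_features)
  } else {
    max_features * n_features
  }
  max(1L, min(n_features, floor(m)))
}

fingerprint_features <- function(smiles, radius = 3, nbits = 2048) {
  X <- morgan_fingerprint(smiles, radius = radius, nbits = nbits)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  X
}

#' Train a balanced random forest QSIR model
#'
#' Each tree is grown on a bootstrap drawn with replacement containing
#' `n_min` compounds of each class, where `n_min` is the minority-class
#' count; the per-tree class balance is retained (`keep.inbag`) and can be
#' audited with [bootstrap_class_counts()].
#'
#' @param train Tibble with `smiles` and `label` (0/1) columns; both
#'   classes must be present.
#' @param hp A [qsir_hyperparams()].
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `qsir_model` object.
#' @export
qsir_train <- function(train, hp = qsir_hyperparams(), seed = 1) {
  stopifnot(is.data.frame(train), all(c("smiles", "label") %in% names(train)),
            inherits(hp, "qsir_hyperparams"))
  y <- factor(train$label, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) {
    rlang::abort("training set contains a single class",
                 class = "qsiraug_contract")
  }
  X <- fingerprint_features(train$smiles)
  n_min <- min(table(y))
  frac <- n_min / length(y)
  forest <- ranger::ranger(
    x = X, y = y,
    num.trees = hp$n_estimators,
    max.depth = hp$max_depth,
    min.node.size = hp$min_samples_split,
    mtry = resolve_mtry(hp$max_features, ncol(X)),
    replace = TRUE,
    sample.fraction = c(frac, frac),
    keep.inbag = TRUE,
    seed = seed,
    num.threads = 1
  )
  structure(
    list(forest = forest, hyperparams = hp,
         fp_config = list(radius = 3L, nbits = 2048L),
         train_seed = as.integer(seed),
         n_train = nrow(train),
         class_counts = c(neg = sum(train$label == 0),
                          pos = sum(train$label == 1)),
         train_labels = as.integer(train$label)),
    class = "qsir_model"
  )
}

#' @export
print.qsir_model <- function(x, ...) {
  cat("<qsir_model> balanced random forest\n")
  cat("  trees:", x$hyperparams$n_estimators,
      " fingerprints: Morgan radius", x$fp_config$radius,
      "/", x$fp_config$nbits, "bits\n")
  cat("  training compounds:", x$n_train,
      sprintf(" (pos %d / neg %d)", x$class_counts[["pos"]],
              x$class_counts[["neg"]]), "\n")
  invisible(x)
}

model_features <- function(model, smiles) {
  fingerprint_features(smiles, radius = model$fp_config$radius,
                       nbits = model$fp_config$nbits)
}

#' Per-tree votes for the interference class
#'
#' @param model A fitted `qsir_model`.
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Integer 0/1 matrix, molecules by trees.
#' @export
qsir_votes <- function(model, smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  X <- model_features(model, smiles)
  pr <- stats::predict(model$forest, X, predict.all = TRUE, num.threads = 1)
  # ranger codes factor levels 1 (label 0) and 2 (label 1)
  votes <- pr$predictions - 1L
  storage.mode(votes) <- "integer"
  votes
}

#' Predicted interference probabilities
#'
#' The probability m(x) is the fraction of trees voting for the
#' interference class.
#'
#' @param object A fitted `qsir_model`.
#' @param new_data Character vector of SMILES or tibble with a `smiles`
#'   column.
#' @param ... Unused.
#' @return Tibble with `smiles` and `m` (probability in \[0, 1\]).
#' @export
predict.qsir_model <- function(object, new_data, ...) {
  smiles <- if (is.data.frame(new_data)) new_data$smiles else new_data
  votes <- qsir_votes(object, smiles)
  tibble::tibble(smiles = smiles, m = rowMeans(votes))
}

#' Leaf assignments of each molecule in each tree
#'
#' @param model A fitted `qsir_model`.
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Integer matrix (molecules x trees) of terminal-node ids.
#' @export
leaf_assignments <- function(model, smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  X <- model_features(model, smiles)
  pr <- stats::predict(model$forest, X, type = "terminalNodes",
                       num.threads = 1)
  out <- pr$predictions
  storage.mode(out) <- "integer"
  out
}

#' Audit per-tree bootstrap class counts
#'
#' @param model A fitted `qsir_model`.
#' @return Tibble with one row per tree: inbag counts of each class.
#' @export
bootstrap_class_counts <- function(model) {
  inbag <- simplify2array(model$forest$inbag.counts)
  lab <- model$train_labels
  tibble::tibble(
    tree = seq_len(ncol(inbag)),
    n_neg = colSums(inbag[lab == 0, , drop = FALSE]),
    n_pos = colSums(inbag[lab == 1, , drop = FALSE])
  )
}

# --- hyperparameter search -------------------------------------------------

sample_hyperparams <- function() {
  mf <- switch(sample.int(3, 1),
               "sqrt", "log2", stats::runif(1, 0.1, 1))
  qsir_hyperparams(
    n_estimators = sample(100:1000, 1),
    max_depth = sample(c(0L, 4:32), 1),
    min_samples_split = sample(2:16, 1),
    max_features = mf
  )
}

#' Cross-validated random search over hyperparameters
#'
#' Seeded random search (`n_trials` draws from the declared space:
#' n_estimators 100-1000, max_depth unlimited or 4-32, min_samples_split
#' 2-16, max_features sqrt/log2/fraction 0.1-1) maximizing the mean
#' cross-validated MCC over stratified folds. The winning configuration is
#' intended to be frozen for all subsequent retraining.
#'
#' @param train Tibble with `smiles` and `label`.
#' @param n_trials Number of sampled configurations (default 50).
#' @param n_folds Stratified folds (default 5).
#' @param seed Integer seed; the search is fully deterministic.
#' @return The winning `qsir_hyperparams`, with the trial table in
#'   attribute `trials` and the best mean CV MCC in attribute `cv_mcc`.
#' @export
optimize_hyperparams <- function(train, n_trials = 50, n_folds = 5,
                                 seed = 1) {
  stopifnot(n_trials >= 1)
  sp <- stratified_split(train, test_fraction = 0, n_folds = n_folds,
                         seed = seed)
  folds <- sp$folds
  for (f in seq_len(n_folds)) {
    if (length(unique(train$label[folds != f])) < 2) {
      rlang::abort("a cross-validation fold has a single training class",
                   class = "qsiraug_contract")
    }
  }
  # fingerprints computed once, reused across trials
  X <- fingerprint_features(train$smiles)
  y <- factor(train$label, levels = c(0, 1))

  set.seed(seed)
  hps <- replicate(n_trials, sample_hyperparams(), simplify = FALSE)
  scores <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    hp <- hps[[t]]
    fold_mcc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      ytr <- y[tr]
      n_min <- min(table(ytr))
      frac <- n_min / sum(tr)
      fit <- ranger::ranger(
        x = X[tr, , drop = FALSE], y = ytr,
        num.trees = hp$n_estimators, max.depth = hp$max_depth,
        min.node.size = hp$min_samples_split,
        mtry = resolve_mtry(hp$max_features, ncol(X)),
        replace = TRUE, sample.fraction = c(frac, frac),
        seed = seed + 131L * t + f, num.threads = 1
      )
      pred <- stats::predict(fit, X[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
      pred <- as.integer(pred) - 1L
      truth <- as.integer(y[!tr]) - 1L
      fold_mcc[f] <- mcc(confusion_counts(
        tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
        tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1)))
    }
    scores[t] <- mean(fold_mcc)
  }
  best <- which.max(scores)
  out <- hps[[best]]
  attr(out, "cv_mcc") <- scores[best]
  attr(out, "trials") <- tibble::tibble(
    trial = seq_len(n_trials),
    n_estimators = vapply(hps, `[[`, integer(1), "n_estimators"),
    max_depth = vapply(hps, `[[`, integer(1), "max_depth"),
    min_samples_split = vapply(hps, `[[`, integer(1), "min_samples_split"),
    max_features = vapply(hps, function(h) paste(h$max_features),
                          character(1)),
    cv_mcc = scores
  )
  out
}

# --- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the hyperparameters of a QSIR model
#'
#' @param x A `qsir_model`.
#' @param ... Unused.
#' @return Long tibble of hyperparameter names and values.
#' @method tidy qsir_model
#' @export
tidy.qsir_model <- function(x, ...) {
  hp <- x$hyperparams
  tibble::tibble(
    term = c("n_estimators", "max_depth", "min_samples_split",
             "max_features", "fp_radius", "fp_nbits"),
    value = c(hp$n_estimators, hp$max_depth, hp$min_samples_split,
              paste(hp$max_features), x$fp_config$radius, x$fp_config$nbits)
  )
}

#' One-row model summary
#'
#' @param x A `qsir_model`.
#' @param ... Unused.
#' @return One-row tibble: training size, class counts, imbalance rate,
#'   out-of-bag error.
#' @method glance qsir_model
#' @export
glance.qsir_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_pos = x$class_counts[["pos"]],
    n_neg = x$class_counts[["neg"]],
    imbalance_rate = imbalance_rate(x$class_counts[["pos"]],
                                    x$class_counts[["neg"]]),
    n_trees = x$hyperparams$n_estimators,
    oob_error = x$forest$prediction.error,
    train_seed = x$train_seed
  )
}
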