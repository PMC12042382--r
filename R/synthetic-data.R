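# Synthetic benchmark generator.
#
# Molecules are assembled from a fixed fragment grammar: ring scaffolds with
# one or two attachment sites crossed with substituent fragments. Labels are
# driven by planted reactive substructures (thiol-reactive Michael
# acceptors, redox-active quinones, a luciferin-like benzothiazole) so that
# a substructure search can reconstruct the noise-free labels exactly. The
# grammar also contains near-miss decoys (saturated carbonyls, benzoxazoles,
# hydroquinones) so the classification task is not linearly trivial.

grammar_scaffolds <- function() {
  c(
    benzene_p      = "c1cc({R2})ccc1{R1}",
    benzene_m      = "c1cc({R1})cc({R2})c1",
    pyridine       = "c1cc({R2})cnc1{R1}",
    pyrimidine     = "c1nc({R2})ccc1{R1}",
    pyrazine       = "c1nc({R2})cnc1{R1}",
    furan          = "c1c({R2})c(o1){R1}",
    thiophene      = "c1c({R2})c(s1){R1}",
    pyrrole        = "c1c({R2})c([nH]1){R1}",
    imidazole      = "c1nc({R2})c(n1C){R1}",
    cyclohexane    = "C1CC({R2})CC({R1})C1",
    cyclopentane   = "C1CC({R2})C({R1})C1",
    piperidine     = "C1CC({R2})CCN1{R1}",
    piperazine     = "C1CN({R2})CCN1{R1}",
    morpholine     = "C1COC({R2})CN1{R1}",
    naphthalene    = "c1ccc2cc({R1})c({R2})cc2c1",
    quinoline      = "c1ccc2nc({R1})cc({R2})c2c1",
    indole         = "c1ccc2c(c1)c({R1})c(n2{R2})",
    benzimidazole  = "c1ccc2c(c1)nc({R1})n2{R2}",
    benzofuran     = "c1ccc2c(c1)c({R2})c(o2){R1}",
    benzoxazole    = "c1cc({R2})c2oc({R1})nc2c1",
    hydroquinone   = "Oc1cc({R2})c(O)c({R1})c1",
    tetralin       = "c1ccc2c(c1)CCC({R1})C2{R2}",
    benzothiazole  = "c1cc({R2})c2sc({R1})nc2c1",
    quinone        = "O=C1C=C({R1})C(=O)C({R2})=C1"
  )
}

grammar_substituents <- function() {
  c(
    "", "C", "CC", "CCC", "CCCC", "C(C)C", "O", "OC", "OCC", "CCOC",
    "N", "NC", "N(C)C", "Cl", "F", "Br", "C(F)(F)F", "C#N",
    "C(=O)N", "C(=O)OC", "C(=O)C", "C(N)=O",
    "S(=O)(=O)C", "S(=O)(=O)N", "SC", "CO", "CN", "CCN", "CCO", "OCCO",
    "c1ccccc1", "c1ccncc1", "Oc1ccccc1", "Nc1ccccc1",
    "N1CCOCC1", "N1CCCCC1",
    # near-miss decoys: carbonyls without conjugated unsaturation
    "CC(C)=O", "NC(=O)CC", "C(=O)NC", "CNC(C)=O",
    # planted reactive fragments (Michael acceptors)
    "C=CC(C)=O", "NC(=O)C=C", "C(=O)C=C", "C=CC(=O)OC"
  )
}

#' Planted interference rules
#'
#' SMARTS patterns that define the positive class of the synthetic
#' benchmark: an alpha,beta-unsaturated carbonyl (thiol-reactive Michael
#' acceptor), a para-quinone (redox cycling) and a 2-substituted
#' benzothiazole (luciferin-like detection-system chemotype).
#'
#' @return Named character vector of SMARTS.
#' @export
planted_rules <- function() {
  c(
    michael_acceptor = "[CX3]=[CX3]-[CX3]=[OX1]",
    quinone          = "[OX1]=C1C=CC(=[OX1])C=C1",
    benzothiazole    = "c1ccc2scnc2c1"
  )
}

fill_template <- function(scaffold, r1, r2 = "") {
  s <- scaffold
  s <- if (nzchar(r1)) sub("{R1}", r1, s, fixed = TRUE) else
    sub("({R1})", "", sub("{R1}", "", s, fixed = TRUE), fixed = TRUE)
  s <- if (nzchar(r2)) sub("{R2}", r2, s, fixed = TRUE) else
    sub("({R2})", "", sub("{R2}", "", s, fixed = TRUE), fixed = TRUE)
  s
}

# Assemble n random grammar molecules (canonical, unique, valid). Returns a
# tibble with canonical smiles and the scaffold name used.
sample_grammar <- function(n, seed, mw_range = NULL, oversample = 4) {
  scaffolds <- grammar_scaffolds()
  subs <- grammar_substituents()
  seen <- character(0)
  rows <- list()
  attempt <- 0
  set.seed(seed)
  while (length(seen) < n && attempt < 12) {
    attempt <- attempt + 1
    m <- max(n * oversample, 200)
    si <- sample(length(scaffolds), m, replace = TRUE)
    r1 <- sample(subs, m, replace = TRUE)
    r2 <- sample(subs, m, replace = TRUE)
    # single-site scaffolds ignore R2 by construction
    smi <- mapply(fill_template, scaffolds[si], r1, r2, USE.NAMES = FALSE)
    parsed <- parse_and_canonicalize(smi, quiet = TRUE)
    ok <- parsed$valid
    if (!is.null(mw_range)) {
      ok <- ok & !is.na(parsed$mw) &
        parsed$mw >= mw_range[1] & parsed$mw <= mw_range[2]
    }
    new <- ok & !duplicated(parsed$canonical_smiles) &
      !(parsed$canonical_smiles %in% seen)
    if (any(new)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        smiles = parsed$canonical_smiles[new],
        scaffold = names(scaffolds)[si[new]],
        mw = parsed$mw[new]
      )
      seen <- c(seen, parsed$canonical_smiles[new])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) < n) {
    rlang::abort(paste0("fragment grammar exhausted: only ", nrow(out),
                        " unique molecules reachable (requested ", n, ")"),
                 class = "qsiraug_grammar_exhausted")
  }
  out[seq_len(n), ]
}

#' Benchmark configuration
#'
#' @param n_compounds Number of unique molecules in the set.
#' @param positive_rate Target fraction of interference-positive compounds
#'   (the study's endpoints range from 1.5% to 20% positives).
#' @param label_noise Probability that a label is flipped after rule
#'   assignment.
#' @param rules Named character vector of planted SMARTS rules.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_compounds = 4000, positive_rate = 0.05,
                             label_noise = 0, rules = planted_rules(),
                             seed = 1) {
  stopifnot(n_compounds > 0, positive_rate > 0, positive_rate < 1,
            label_noise >= 0, label_noise < 0.5, length(rules) >= 1)
  structure(
    list(n_compounds = as.integer(n_compounds),
         positive_rate = positive_rate,
         label_noise = label_noise,
         rules = rules,
         seed = as.integer(seed)),
    class = "benchmark_config"
  )
}

#' Generate a synthetic interference benchmark
#'
#' Emulates the statistical structure of experimental assay-interference
#' sets: a few thousand unique compounds with a small positive class whose
#' membership is determined by reactive substructures. With
#' `label_noise = 0`, a substructure search against the planted rules
#' reconstructs the labels exactly.
#'
#' @param cfg A [benchmark_config()].
#' @return A tibble with columns `smiles` (canonical), `label` (0/1) and
#'   `provenance` ("original").
#' @export
generate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  n_pos <- round(cfg$n_compounds * cfg$positive_rate)
  n_neg <- cfg$n_compounds - n_pos
  if (n_pos == 0) {
    rlang::abort("positive_rate unreachable: zero positives at this n",
                 class = "qsiraug_contract")
  }
  # oversample the grammar, split by rule matching, then take exact counts
  pool <- sample_grammar(min(3 * cfg$n_compounds, 9000), seed = cfg$seed)
  hits <- smarts_match_any(pool$smiles, cfg$rules)
  pos_pool <- pool$smiles[hits]
  neg_pool <- pool$smiles[!hits]
  if (length(pos_pool) < n_pos || length(neg_pool) < n_neg) {
    max_rate <- length(pos_pool) /
      (length(pos_pool) + max(length(neg_pool), 1))
    rlang::abort(
      sprintf(paste0("positive_rate %.3f unreachable at n=%d; the grammar ",
                     "supports roughly %d positives and %d negatives ",
                     "(achievable rate up to ~%.3f)"),
              cfg$positive_rate, cfg$n_compounds,
              length(pos_pool), length(neg_pool), max_rate),
      class = "qsiraug_unreachable_rate"
    )
  }
  set.seed(cfg$seed + 1L)
  smiles <- c(sample(pos_pool, n_pos), sample(neg_pool, n_neg))
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  flip <- stats::rbinom(length(label), 1, cfg$label_noise) == 1
  label[flip] <- 1L - label[flip]
  ord <- sample.int(length(smiles))
  tibble::tibble(
    smiles = smiles[ord],
    label = label[ord],
    provenance = "original"
  )
}

#' Stratified train/test split with cross-validation folds
#'
#' The test fraction and each fold preserve the class distribution of the
#' input to within one compound. Remainder compounds during rounding are
#' assigned deterministically (classes ordered by the fractional part of
#' their ideal allocation, ties by label); which compounds land where is
#' decided by the seeded shuffle.
#'
#' @param ds Tibble with `smiles` and `label` columns.
#' @param test_fraction Fraction held out (default 0.25).
#' @param n_folds Number of cross-validation folds over the training part
#'   (default 5).
#' @param seed Integer seed.
#' @return List with `train`, `test` (tibbles) and `folds` (integer vector
#'   aligned with `train`).
#' @export
stratified_split <- function(ds, test_fraction = 0.25, n_folds = 5, seed = 1) {
  stopifnot(is.data.frame(ds), all(c("smiles", "label") %in% names(ds)),
            test_fraction >= 0, test_fraction < 1, n_folds >= 1)
  labs <- sort(unique(ds$label))
  if (test_fraction > 0 && length(labs) < 2) {
    rlang::abort("both classes must be present to split",
                 class = "qsiraug_contract")
  }
  set.seed(seed)
  n_test_total <- round(nrow(ds) * test_fraction)
  ideal <- vapply(labs, function(l) sum(ds$label == l) * test_fraction,
                  numeric(1))
  base <- floor(ideal)
  rem <- n_test_total - sum(base)
  extra <- rep(0L, length(labs))
  if (rem > 0) {
    ord <- order(ideal - base, labs, decreasing = TRUE)
    extra[ord[seq_len(rem)]] <- 1L
  }
  test_idx <- integer(0)
  for (j in seq_along(labs)) {
    idx <- which(ds$label == labs[j])
    idx <- idx[sample.int(length(idx))]
    test_idx <- c(test_idx, idx[seq_len(base[j] + extra[j])])
  }
  test <- ds[sort(test_idx), , drop = FALSE]
  train <- ds[setdiff(seq_len(nrow(ds)), test_idx), , drop = FALSE]

  folds <- integer(nrow(train))
  for (l in labs) {
    idx <- which(train$label == l)
    if (length(idx) > 0 && length(idx) < n_folds && n_folds > 1) {
      rlang::abort(sprintf("class %s has %d members, fewer than n_folds=%d",
                           l, length(idx), n_folds),
                   class = "qsiraug_contract")
    }
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  list(train = tibble::as_tibble(train),
       test = tibble::as_tibble(test),
       folds = folds)
}

#' Unlabeled fixture pool of grammar molecules
#'
#' Source material for the resampling stub generator: unique, valid grammar
#' molecules spanning both rule-matching and rule-free chemotypes, with
#' molecular weight confined to 120-600 Da.
#'
#' @param n Pool size.
#' @param seed Integer seed.
#' @return Tibble with `smiles` and `mw`.
#' @export
fixture_pool <- function(n, seed = 1) {
  stopifnot(n > 0)
  out <- sample_grammar(n, seed = seed, mw_range = c(120, 600))
  tibble::tibble(smiles = out$smiles, mw = out$mw)
}
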