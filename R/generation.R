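# Goal-directed molecule generation behind a pluggable interface. The
# production-scale generative model is replaced by two desk-scale stubs that
# honor the same protocol: a temperature-controlled resampling generator
# over a fixture pool, and a fragment-grammar genetic algorithm. A
# generation stage runs a generator against a reward scorer built from the
# current teacher model and returns the scored candidate pool U_r.

#' Reward weights
#'
#' Weights of the interference score and the molecular-weight score in the
#' generation reward. Normalized to sum to one.
#'
#' @param w1 Weight on the predicted interference probability (default 0.8).
#' @param w2 Weight on the molecular-weight desirability (default 0.2).
#' @return A `reward_weights` list.
#' @export
reward_weights <- function(w1 = 0.8, w2 = 0.2) {
  stopifnot(w1 >= 0, w2 >= 0)
  if (w1 + w2 == 0) {
    rlang::abort("reward weights cannot both be zero",
                 class = "qsiraug_contract")
  }
  s <- w1 + w2
  structure(list(w1 = w1 / s, w2 = w2 / s), class = "reward_weights")
}

#' Generation schedule
#'
#' @param n_steps Optimization steps (default 250).
#' @param batch_size Molecules proposed per step (default 100). A full
#'   stage therefore yields `n_steps * batch_size` molecules (25,000 at the
#'   defaults) before any deduplication.
#' @return A `generation_schedule` list.
#' @export
generation_schedule <- function(n_steps = 250, batch_size = 100) {
  stopifnot(n_steps >= 1, batch_size >= 1)
  structure(list(n_steps = as.integer(n_steps),
                 batch_size = as.integer(batch_size)),
            class = "generation_schedule")
}

#' Molecular-weight desirability
#'
#' 1 on the 160-480 Da window favored for small-molecule drug discovery,
#' with linear 40 Da ramps outside (0 at or below 120 Da and at or above
#' 520 Da). The trapezoid keeps the score continuous and leaves a nonzero
#' gradient for optimizing generators just outside the window.
#'
#' @param mw Molecular weight(s) in Da.
#' @return Score(s) in \[0, 1\].
#' @export
mw_desirability <- function(mw) {
  stopifnot(all(mw > 0))
  pmin(1, pmax(0, pmin((mw - 120) / 40, (520 - mw) / 40)))
}

#' Generation reward
#'
#' Convex combination `f(x) = w1 * m(x) + w2 * wt(x)` of the teacher's
#' interference probability and the molecular-weight desirability.
#'
#' @param m Interference probabilities in \[0, 1\].
#' @param wt Molecular-weight scores in \[0, 1\].
#' @param w A [reward_weights()].
#' @return Rewards in \[0, 1\].
#' @export
reward <- function(m, wt, w = reward_weights()) {
  stopifnot(inherits(w, "reward_weights"),
            all(m >= 0 & m <= 1), all(wt >= 0 & wt <= 1))
  w$w1 * m + w$w2 * wt
}

#' Reward scorer wrapping a QSIR teacher model
#'
#' @param model A fitted `qsir_model`.
#' @param weights A [reward_weights()].
#' @return A function mapping a character vector of valid canonical SMILES
#'   to a tibble with `smiles`, `m`, `wt`, `reward`.
#' @export
qsir_scorer <- function(model, weights = reward_weights()) {
  force(model); force(weights)
  function(smiles) {
    stopifnot(is.character(smiles))
    m <- predict(model, smiles)$m
    mw <- ob_descriptors(smiles, fields = "MW")$MW
    wt <- mw_desirability(mw)
    tibble::tibble(smiles = smiles, m = m, wt = wt,
                   reward = reward(m, wt, weights))
  }
}

#' Propose molecules from a generator
#'
#' Generic of the generator protocol: every generator takes the reward
#' scorer, a schedule and a seed, and returns one proposed molecule per
#' pool slot with its generation step.
#'
#' @param generator A generator object.
#' @param scorer A scorer function as built by [qsir_scorer()].
#' @param schedule A [generation_schedule()].
#' @param seed Integer seed.
#' @return Tibble with `smiles` (canonical) and `step`.
#' @export
propose_molecules <- function(generator, scorer, schedule, seed = 1) {
  UseMethod("propose_molecules")
}

#' Run one generation stage
#'
#' Executes a generator under the current teacher's reward, scores every
#' proposed molecule, and flags overlaps with the training and test sets.
#' The pool holds exactly `n_steps * batch_size` rows; duplicates are kept
#' (deduplication happens at acquisition). If fewer than 90% of proposals
#' are valid molecules the stage refills, then errors if the generator
#' persistently emits junk.
#'
#' @param generator A generator implementing [propose_molecules()].
#' @param scorer A scorer function from [qsir_scorer()].
#' @param schedule A [generation_schedule()].
#' @param seed Integer seed.
#' @param train_smiles,test_smiles Canonical SMILES of the current training
#'   and test sets (for overlap flags).
#' @return A `candidate_pool` tibble: `smiles`, `step`, `m`, `wt`,
#'   `reward`, `in_train`, `in_test`.
#' @export
run_generation_stage <- function(generator, scorer, schedule, seed = 1,
                                 train_smiles = character(0),
                                 test_smiles = character(0)) {
  stopifnot(inherits(schedule, "generation_schedule"))
  n_total <- schedule$n_steps * schedule$batch_size
  prop <- propose_molecules(generator, scorer, schedule, seed = seed)
  parsed <- parse_and_canonicalize(prop$smiles, quiet = TRUE)
  valid <- parsed$valid
  attempts <- 0
  while (mean(valid) < 0.9 && attempts < 3) {
    attempts <- attempts + 1
    rlang::warn(sprintf("generator yielded %.0f%% valid molecules; refilling",
                        100 * mean(valid)))
    prop2 <- propose_molecules(generator, scorer, schedule,
                               seed = seed + 7919L * attempts)
    parsed2 <- parse_and_canonicalize(prop2$smiles, quiet = TRUE)
    bad <- which(!valid)
    take <- which(parsed2$valid)[seq_len(min(length(bad),
                                             sum(parsed2$valid)))]
    parsed[bad[seq_along(take)], ] <- parsed2[take, ]
    prop$step[bad[seq_along(take)]] <- prop2$step[take]
    valid <- parsed$valid
  }
  if (mean(valid) < 0.9) {
    rlang::abort("generator persistently yields < 90% valid molecules",
                 class = "qsiraug_generator_error")
  }
  keep <- which(valid)[seq_len(min(n_total, sum(valid)))]
  smiles <- parsed$canonical_smiles[keep]
  uniq <- unique(smiles)
  scored <- scorer(uniq)
  idx <- match(smiles, scored$smiles)
  tibble::tibble(
    smiles = smiles,
    step = prop$step[keep],
    m = scored$m[idx],
    wt = scored$wt[idx],
    reward = scored$reward[idx],
    in_train = smiles %in% train_smiles,
    in_test = smiles %in% test_smiles
  )
}

# --- resampling stub -------------------------------------------------------

#' Resampling stub generator
#'
#' Samples molecules from a fixed pool with probability proportional to
#' `exp(f(x) / tau)`. The temperature decays geometrically from `tau_start`
#' to `tau_end` across the schedule, so later batches concentrate on
#' high-reward molecules — a controlled analogue of the diversity decay
#' (mode collapse) seen when a generative model exploits its reward.
#'
#' @param pool Tibble with a `smiles` column (e.g. [fixture_pool()]), or a
#'   character vector.
#' @param tau_start,tau_end Temperature schedule endpoints.
#' @return A `resampling_generator`.
#' @export
stub_resampling_generator <- function(pool, tau_start = 1.0, tau_end = 0.2) {
  smiles <- if (is.data.frame(pool)) pool$smiles else pool
  stopifnot(is.character(smiles), tau_start > 0, tau_end > 0)
  if (length(smiles) == 0) {
    rlang::abort("empty fixture pool", class = "qsiraug_contract")
  }
  structure(list(pool = unique(smiles), tau_start = tau_start,
                 tau_end = tau_end),
            class = c("resampling_generator", "molecule_generator"))
}

#' @export
propose_molecules.resampling_generator <- function(generator, scorer,
                                                   schedule, seed = 1) {
  pool <- generator$pool
  scored <- scorer(pool)
  f <- scored$reward
  n_steps <- schedule$n_steps
  taus <- if (n_steps == 1) generator$tau_start else
    generator$tau_start *
      (generator$tau_end / generator$tau_start)^((seq_len(n_steps) - 1) /
                                                   (n_steps - 1))
  set.seed(seed)
  out <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    w <- exp((f - max(f)) / taus[s])
    idx <- sample.int(length(pool), schedule$batch_size, replace = TRUE,
                      prob = w)
    # prefer distinct molecules within a batch, topping up with weighted
    # duplicates when the pool is effectively exhausted
    if (anyDuplicated(idx)) {
      for (r in 1:20) {
        dup <- duplicated(idx)
        if (!any(dup)) break
        idx[dup] <- sample.int(length(pool), sum(dup), replace = TRUE,
                               prob = w)
      }
    }
    out[[s]] <- tibble::tibble(smiles = pool[idx], step = s)
  }
  dplyr::bind_rows(out)
}

# --- genetic-algorithm stub ------------------------------------------------

#' Fragment-grammar genetic algorithm generator
#'
#' Evolves a population of grammar genotypes (scaffold plus substituents)
#' under the reward: tournament selection, single-gene mutation and
#' uniform crossover. Each step emits one batch of offspring into the
#' candidate pool; selection pressure makes the mean pool reward
#' non-decreasing in expectation. An optional per-scaffold occurrence cap
#' acts as a diversity filter on the emitted pool.
#'
#' @param mutation_rate Probability that a mutated child changes each gene.
#' @param tournament_k Tournament size for parent selection.
#' @param scaffold_cap Maximum number of pool molecules per grammar
#'   scaffold (`Inf` disables the filter).
#' @return A `ga_generator`.
#' @export
stub_ga_generator <- function(mutation_rate = 0.3, tournament_k = 3,
                              scaffold_cap = Inf) {
  stopifnot(mutation_rate > 0, mutation_rate <= 1, tournament_k >= 1)
  structure(list(mutation_rate = mutation_rate, tournament_k = tournament_k,
                 scaffold_cap = scaffold_cap,
                 scaffolds = grammar_scaffolds(),
                 substituents = grammar_substituents()),
            class = c("ga_generator", "molecule_generator"))
}

ga_assemble <- function(gen, geno) {
  vapply(seq_len(nrow(geno)), function(i) {
    fill_template(gen$scaffolds[[geno$sc[i]]],
                  gen$substituents[[geno$r1[i]]],
                  gen$substituents[[geno$r2[i]]])
  }, character(1))
}

ga_random_geno <- function(gen, n) {
  tibble::tibble(
    sc = sample.int(length(gen$scaffolds), n, replace = TRUE),
    r1 = sample.int(length(gen$substituents), n, replace = TRUE),
    r2 = sample.int(length(gen$substituents), n, replace = TRUE)
  )
}

#' @export
propose_molecules.ga_generator <- function(generator, scorer, schedule,
                                           seed = 1) {
  gen <- generator
  set.seed(seed)
  pop_n <- schedule$batch_size
  pop <- ga_random_geno(gen, pop_n)
  scaffold_emitted <- integer(length(gen$scaffolds))
  out <- vector("list", schedule$n_steps)

  score_geno <- function(geno) {
    smi <- ga_assemble(gen, geno)
    parsed <- parse_and_canonicalize(smi, quiet = TRUE)
    canon <- parsed$canonical_smiles
    fit <- rep(0, nrow(geno))
    ok <- parsed$valid
    if (any(ok)) fit[ok] <- scorer(canon[ok])$reward
    list(canon = canon, fitness = fit, valid = ok)
  }

  cur <- score_geno(pop)
  for (s in seq_len(schedule$n_steps)) {
    # emit current offspring batch, applying the scaffold diversity cap:
    # a genotype whose scaffold already reached the cap is re-rooted onto a
    # random scaffold still under the cap (and rescored) before emission
    if (is.finite(gen$scaffold_cap)) {
      emit <- rep(FALSE, pop_n)
      for (i in seq_len(pop_n)) {
        if (scaffold_emitted[pop$sc[i]] >= gen$scaffold_cap) {
          open <- which(scaffold_emitted < gen$scaffold_cap)
          if (length(open) == 0) next
          pop$sc[i] <- open[sample.int(length(open), 1)]
          resc <- score_geno(pop[i, , drop = FALSE])
          cur$canon[i] <- resc$canon
          cur$fitness[i] <- resc$fitness
          cur$valid[i] <- resc$valid
        }
        if (cur$valid[i]) {
          scaffold_emitted[pop$sc[i]] <- scaffold_emitted[pop$sc[i]] + 1L
          emit[i] <- TRUE
        }
      }
    } else {
      emit <- cur$valid
      scaffold_emitted <- scaffold_emitted +
        tabulate(pop$sc[emit], nbins = length(gen$scaffolds))
    }
    out[[s]] <- tibble::tibble(smiles = cur$canon[emit], step = s)

    if (s == schedule$n_steps) break
    # tournament selection + variation
    parents <- vapply(seq_len(pop_n), function(i) {
      cand <- sample.int(pop_n, gen$tournament_k, replace = TRUE)
      cand[which.max(cur$fitness[cand])]
    }, integer(1))
    mates <- vapply(seq_len(pop_n), function(i) {
      cand <- sample.int(pop_n, gen$tournament_k, replace = TRUE)
      cand[which.max(cur$fitness[cand])]
    }, integer(1))
    child <- pop[parents, ]
    # uniform crossover
    take <- matrix(stats::runif(pop_n * 3) < 0.5, pop_n, 3)
    child$sc[take[, 1]] <- pop$sc[mates][take[, 1]]
    child$r1[take[, 2]] <- pop$r1[mates][take[, 2]]
    child$r2[take[, 3]] <- pop$r2[mates][take[, 3]]
    # mutation
    mut <- matrix(stats::runif(pop_n * 3) < gen$mutation_rate, pop_n, 3)
    child$sc[mut[, 1]] <- sample.int(length(gen$scaffolds), sum(mut[, 1]),
                                     replace = TRUE)
    child$r1[mut[, 2]] <- sample.int(length(gen$substituents), sum(mut[, 2]),
                                     replace = TRUE)
    child$r2[mut[, 3]] <- sample.int(length(gen$substituents), sum(mut[, 3]),
                                     replace = TRUE)
    nxt <- score_geno(child)
    if (!any(nxt$valid)) {
      rlang::warn("all GA offspring invalid; keeping parents")
    } else {
      pop <- child
      cur <- nxt
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "scaffold_counts") <- stats::setNames(scaffold_emitted,
                                                  names(gen$scaffolds))
  res
}
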