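# Acquisition: selecting the k most useful molecules from a generated
# candidate pool. Five strategies: uniform random, greedy (highest
# predicted interference), EPIG (expected predictive information gain over
# a high-scoring target set), and the two expert-combined variants that add
# a normalized preference score.

#' Acquisition configuration
#'
#' @param strategy One of `"random"`, `"greedy"`, `"epig"`,
#'   `"greedy_skill"`, `"epig_skill"`.
#' @param k Batch size: molecules acquired per iteration (default 250).
#' @param alpha,beta Weights of the predictor and expert components of the
#'   combined score. Defaults follow the strategy: the expert-free
#'   strategies use `beta = 0`, the Skill variants `alpha = beta = 1`.
#' @param epig_target_size Size of the high-scoring target set (default
#'   1000).
#' @param epig_pair_samples Number of target molecules sampled per EPIG
#'   estimate (default 100); set to `Inf` for the exact all-pairs average.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(strategy = c("random", "greedy", "epig",
                                            "greedy_skill", "epig_skill"),
                               k = 250, alpha = NULL, beta = NULL,
                               epig_target_size = 1000,
                               epig_pair_samples = 100) {
  strategy <- match.arg(strategy)
  skill <- strategy %in% c("greedy_skill", "epig_skill")
  alpha <- alpha %||% 1
  beta <- beta %||% (if (skill) 1 else 0)
  stopifnot(k >= 0, alpha >= 0, beta >= 0, epig_target_size >= 1,
            epig_pair_samples >= 1)
  structure(list(strategy = strategy, k = as.integer(k), alpha = alpha,
                 beta = beta, epig_target_size = as.integer(epig_target_size),
                 epig_pair_samples = epig_pair_samples),
            class = "acquisition_config")
}

#' Combined acquisition score
#'
#' `A(x) = alpha * A_predictor(x) + beta * A_human(x)`.
#'
#' @param a_pred,a_human Component scores in \[0, 1\].
#' @param alpha,beta Non-negative weights.
#' @return Combined scores.
#' @export
combined_score <- function(a_pred, a_human, alpha = 1, beta = 1) {
  stopifnot(all(a_pred >= 0 & a_pred <= 1), all(a_human >= 0 & a_human <= 1),
            alpha >= 0, beta >= 0)
  alpha * a_pred + beta * a_human
}

# Deduplicate a candidate pool by canonical SMILES (first occurrence wins)
# and drop exact test-set matches (leakage guard).
prepare_pool <- function(pool) {
  stopifnot(is.data.frame(pool), "smiles" %in% names(pool))
  out <- pool[!duplicated(pool$smiles), , drop = FALSE]
  if ("in_test" %in% names(out)) out <- out[!out$in_test, , drop = FALSE]
  tibble::as_tibble(out)
}

# Top-k with the package-wide deterministic tie rule: score descending,
# ties broken by canonical SMILES in C-locale lexicographic order.
top_k_by <- function(pool, score, k) {
  ord <- order(-score, pool$smiles, method = "radix")
  take <- ord[seq_len(min(k, nrow(pool)))]
  tied <- duplicated(signif(score, 12)) | duplicated(signif(score, 12),
                                                     fromLast = TRUE)
  out <- pool[take, , drop = FALSE]
  attr(out, "tie_broken") <- sum(tied[take])
  out
}

new_acquisition_result <- function(selected, strategy) {
  structure(tibble::as_tibble(selected),
            class = c("acquisition_result", class(tibble::tibble())),
            strategy = strategy)
}

#' Random acquisition
#'
#' Uniform sample of `k` distinct pool molecules.
#'
#' @param pool A candidate pool tibble (deduplicated internally).
#' @param k Batch size.
#' @param seed Integer seed.
#' @return An acquisition result: the selected rows with an `a_pred`
#'   column.
#' @export
acquire_random <- function(pool, k, seed = 1) {
  pool <- prepare_pool(pool)
  if (k > nrow(pool)) {
    rlang::abort(sprintf("k=%d exceeds pool size %d", k, nrow(pool)),
                 class = "qsiraug_contract")
  }
  set.seed(seed)
  sel <- pool[sample.int(nrow(pool), k), , drop = FALSE]
  sel$a_pred <- NA_real_
  sel$a_human <- NA_real_
  sel$a_combined <- NA_real_
  new_acquisition_result(sel, "random")
}

#' Greedy acquisition
#'
#' Top-k pool molecules by predicted interference probability m(x); ties
#' are broken deterministically by canonical SMILES order (the number of
#' tie-broken selections is recorded in the `tie_broken` attribute).
#'
#' @param pool A candidate pool tibble with an `m` column.
#' @param k Batch size.
#' @return An acquisition result.
#' @export
acquire_greedy <- function(pool, k) {
  pool <- prepare_pool(pool)
  stopifnot("m" %in% names(pool))
  sel <- top_k_by(pool, pool$m, k)
  tie <- attr(sel, "tie_broken")
  sel$a_pred <- sel$m
  sel$a_human <- NA_real_
  sel$a_combined <- sel$m
  out <- new_acquisition_result(sel, "greedy")
  attr(out, "tie_broken") <- tie
  out
}

#' Expected predictive information gain (EPIG) scores
#'
#' For each candidate x, the expected mutual information between its
#' predicted label and the predicted label of a random target molecule x*
#' drawn from the high-scoring target set: the expected KL divergence
#' between the joint predictive distribution p(y, y* | x, x*) and the
#' product of the marginals. The forest supplies the distributions: each
#' tree is one joint posterior sample, so the joint is the fraction of
#' trees voting each (y, y*) combination and the marginals are the vote
#' fractions. Scores are non-negative and are exactly 0 when the ensemble
#' is deterministic.
#'
#' @param votes_pool Integer 0/1 matrix (candidates x trees).
#' @param votes_target Integer 0/1 matrix (target molecules x trees),
#'   tree-aligned with `votes_pool`.
#' @param pair_samples Targets sampled per candidate (one shared draw);
#'   `Inf` averages over every target.
#' @param seed Integer seed for the target draw.
#' @return Numeric vector of EPIG scores (nats), one per candidate row.
#' @export
epig_scores <- function(votes_pool, votes_target, pair_samples = 100,
                        seed = 1) {
  stopifnot(is.matrix(votes_pool), is.matrix(votes_target),
            ncol(votes_pool) == ncol(votes_target))
  if (nrow(votes_target) == 0) {
    rlang::abort("empty EPIG target set", class = "qsiraug_contract")
  }
  n_t <- nrow(votes_target)
  if (is.finite(pair_samples) && pair_samples < n_t) {
    set.seed(seed)
    votes_target <- votes_target[sample.int(n_t, pair_samples), ,
                                 drop = FALSE]
  }
  Tn <- ncol(votes_pool)
  A <- votes_pool          # candidate votes for class 1
  B <- votes_target        # target votes for class 1
  n11 <- A %*% t(B)
  n10 <- A %*% t(1 - B)
  n01 <- (1 - A) %*% t(B)
  n00 <- (1 - A) %*% t(1 - B)
  pa1 <- rowMeans(A); pa0 <- 1 - pa1
  pb1 <- rowMeans(B); pb0 <- 1 - pb1
  kl_term <- function(nab, pa, pb) {
    p <- nab / Tn
    prod_ab <- outer(pa, pb)
    out <- p * log(p / prod_ab)
    out[p == 0] <- 0
    out
  }
  kl <- kl_term(n11, pa1, pb1) + kl_term(n10, pa1, pb0) +
    kl_term(n01, pa0, pb1) + kl_term(n00, pa0, pb0)
  pmax(rowMeans(kl), 0)
}

# EPIG target set: the top high-scoring molecules of the pool by m(x).
epig_target_rows <- function(pool, target_size) {
  ord <- order(-pool$m, pool$smiles, method = "radix")
  ord[seq_len(min(target_size, nrow(pool)))]
}

#' EPIG acquisition
#'
#' Scores the deduplicated pool with [epig_scores()] against the top
#' `epig_target_size` molecules by m(x) and selects the top k.
#'
#' @param pool A candidate pool tibble with `m`.
#' @param model The current `qsir_model` (vote source).
#' @param cfg An [acquisition_config()].
#' @param seed Integer seed (target subsampling).
#' @return An acquisition result with an `epig` column.
#' @export
acquire_epig <- function(pool, model, cfg, seed = 1) {
  pool <- prepare_pool(pool)
  votes <- qsir_votes(model, pool$smiles)
  tgt <- epig_target_rows(pool, cfg$epig_target_size)
  ep <- epig_scores(votes, votes[tgt, , drop = FALSE],
                    pair_samples = cfg$epig_pair_samples, seed = seed)
  pool$epig <- ep
  sel <- top_k_by(pool, ep, cfg$k)
  sel$a_pred <- sel$epig
  sel$a_human <- NA_real_
  sel$a_combined <- sel$epig
  new_acquisition_result(sel, "epig")
}

#' Expert-combined acquisition (GreedySkill / EPIGSkill)
#'
#' Combines the predictor score (greedy m(x) or EPIG) with the expert
#' preference score: both components are min-max normalized over the
#' deduplicated pool, then summed with weights alpha and beta (1 and 1 by
#' default) and the top k are selected.
#'
#' @param pool A candidate pool tibble with `m`.
#' @param model The current `qsir_model` (needed for the EPIG variant).
#' @param expert An expert scorer (see [expert_score()]).
#' @param cfg An [acquisition_config()] with strategy `"greedy_skill"` or
#'   `"epig_skill"`.
#' @param seed Integer seed.
#' @return An acquisition result with `a_pred`, `a_human`, `a_combined`.
#' @export
acquire_with_skill <- function(pool, model, expert, cfg, seed = 1) {
  stopifnot(cfg$strategy %in% c("greedy_skill", "epig_skill"))
  pool <- prepare_pool(pool)
  raw_pred <- if (cfg$strategy == "greedy_skill") {
    pool$m
  } else {
    votes <- qsir_votes(model, pool$smiles)
    tgt <- epig_target_rows(pool, cfg$epig_target_size)
    epig_scores(votes, votes[tgt, , drop = FALSE],
                pair_samples = cfg$epig_pair_samples, seed = seed)
  }
  a_pred <- normalize_preferences(raw_pred, "higher")
  raw_expert <- expert_score(expert, pool$smiles)
  a_human <- normalize_preferences(raw_expert, expert_orientation(expert))
  a <- combined_score(a_pred, a_human, cfg$alpha, cfg$beta)
  sel_idx <- order(-a, pool$smiles, method = "radix")[seq_len(min(cfg$k,
                                                                  nrow(pool)))]
  sel <- pool[sel_idx, , drop = FALSE]
  sel$a_pred <- a_pred[sel_idx]
  sel$a_human <- a_human[sel_idx]
  sel$a_combined <- a[sel_idx]
  new_acquisition_result(sel, cfg$strategy)
}

#' Acquire a batch with the configured strategy
#'
#' Dispatcher over the five strategies. The pool is deduplicated by
#' canonical SMILES and exact test-set matches are removed before any
#' selection.
#'
#' @param pool A candidate pool tibble (from [run_generation_stage()]).
#' @param model The current `qsir_model`.
#' @param cfg An [acquisition_config()].
#' @param expert Expert scorer (required for the Skill strategies).
#' @param seed Integer seed.
#' @return An acquisition result tibble of `k` molecules.
#' @export
acquire <- function(pool, model, cfg, expert = NULL, seed = 1) {
  stopifnot(inherits(cfg, "acquisition_config"))
  switch(cfg$strategy,
    random = acquire_random(pool, cfg$k, seed = seed),
    greedy = acquire_greedy(pool, cfg$k),
    epig = acquire_epig(pool, model, cfg, seed = seed),
    greedy_skill = ,
    epig_skill = {
      if (is.null(expert)) {
        rlang::abort("the Skill strategies need an expert scorer",
                     class = "qsiraug_contract")
      }
      acquire_with_skill(pool, model, expert, cfg, seed = seed)
    }
  )
}
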