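# Shared fixtures, built once per test session and memoized. Everything is
# generated in code; no binary fixtures.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A perfectly separable toy set: positives carry an acrylamide Michael
# acceptor, negatives carry its saturated analogue, on the same scaffolds.
fix_separable_set <- function() {
  memo("separable", {
    scaffolds <- c("c1cc(%s)ccc1C", "c1cc(%s)ccc1OC", "c1cc(%s)cnc1",
                   "c1cc(%s)ccc1F", "c1cc(%s)ccc1Cl", "c1cc(%s)ccc1N",
                   "c1cc(%s)ccc1O", "c1cc(%s)ccc1CC", "c1ccc(%s)cc1",
                   "c1cc(%s)ccc1C#N", "c1cc(%s)ccc1C(F)(F)F",
                   "c1cc(%s)ccc1OCC", "c1cc(%s)ccc1CO", "c1cc(%s)ccc1CN",
                   "c1cc(%s)ccc1N(C)C")
    pos <- sprintf(scaffolds, "NC(=O)C=C")
    neg <- sprintf(scaffolds, "NC(=O)CC")
    parsed <- parse_and_canonicalize(c(pos, neg), quiet = TRUE)
    stopifnot(all(parsed$valid))
    tibble::tibble(
      smiles = parsed$canonical_smiles,
      label = rep(c(1L, 0L), each = length(scaffolds)),
      provenance = "original"
    )
  })
}

# Small noisy benchmark and its split, shared across model-level tests.
fix_benchmark <- function() {
  memo("benchmark", {
    generate_benchmark(benchmark_config(n_compounds = 800,
                                        positive_rate = 0.1,
                                        label_noise = 0.05, seed = 11))
  })
}

fix_split <- function() {
  memo("split", stratified_split(fix_benchmark(), 0.25, 5, seed = 12))
}

fix_model <- function() {
  memo("model", {
    qsir_train(fix_split()$train, qsir_hyperparams(n_estimators = 100),
               seed = 13)
  })
}

fix_fixture_pool <- function() {
  memo("pool", fixture_pool(300, seed = 14))
}

# Vote matrix helpers for EPIG tests.
votes_matrix <- function(rows) {
  do.call(rbind, rows)
}
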