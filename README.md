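# qsiraug

Iterative self-distillation and expert-guided data augmentation for
assay-interference classifiers.

## The problem

Compounds that corrupt high-throughput screens — thiol-reactive
electrophiles, redox cyclers, luciferase inhibitors — produce false
readouts without touching the target. Classifiers that flag them (QSIR
models: quantitative structure-interference relationship) must be trained
on small compound sets with positive rates as low as 1.5%, and the
scarcity of positives caps their performance.

`qsiraug` implements a teacher-student loop that manufactures its own
training signal. A balanced random forest m(x) over Morgan-3/2048
fingerprints steers a goal-directed molecule generator through the reward

    f(x) = w1 * m(x) + w2 * wt(x),       w1 = 0.8, w2 = 0.2

where wt(x) is a molecular-weight desirability equal to 1 on 160–480 Da.
From the generated pool U_r, an acquisition function

    A(x) = alpha * A_predictor(x) + beta * A_human(x)

selects k molecules (random, greedy, EPIG, or the expert-combined
GreedySkill/EPIGSkill variants; EPIG is the expected KL divergence between
the joint tree-vote distribution of a candidate and a high-scoring target
molecule and the product of their marginals). The selection is
pseudo-labeled by the teacher, merged into the training set, and a student
is retrained with frozen hyperparameters; the student becomes the next
teacher. Everything is evaluated with the interference-modeling metric
suite: MCC, enrichment factor (precision / prevalence), imbalance rate
|pos − neg|/(pos + neg), internal Tanimoto diversity, PAINS alerts, QED,
scaffold similarity, and centered kernel alignment between forests
(CKA on the leaf co-occurrence kernel).

Because the experimental interference datasets and the production
generator cannot be shipped, the package includes a synthetic benchmark
generator (planted reactive substructures: Michael acceptors, quinones,
benzothiazoles, plus near-miss decoys) and two desk-scale stub generators
(a temperature-annealed resampler and a fragment-grammar genetic
algorithm) behind the same generator protocol a production model would
use.

## Worked example

```r
library(qsiraug)

# a 2000-compound benchmark with 5% positives and 5% label noise
bench <- generate_benchmark(benchmark_config(
  n_compounds = 2000, positive_rate = 0.05, label_noise = 0.05, seed = 101))

cfg <- loop_config(
  acquisition  = acquisition_config("greedy", k = 50),
  schedule     = generation_schedule(20, 25),
  n_iterations = 5, n_repetitions = 10,
  hyperparams  = qsir_hyperparams(n_estimators = 300),
  master_seed  = 101)

exp <- run_experiment(cfg, bench, stub_ga_generator())
print(exp)
#> <distill_experiment> 10 runs x 5 iterations, greedy acquisition
#> # A tibble: 6 x 4
#>   iteration   mcc    ef    ir
#>       <int> <dbl> <dbl> <dbl>
#> 1         0 0.540  6.21 0.812
#> ...
#> 6         5 0.676 10.5  0.615
```

Reading the numbers: at iteration 0 the baseline forest, trained on 75
positives among 1500 compounds, reaches a mean test MCC of 0.54 and
enriches true positives 6.2-fold over random selection. Five greedy
augmentation rounds add 250 pseudo-labeled molecules per run; the training
set rebalances (imbalance rate 0.81 → 0.62) and the student improves to
MCC 0.68 and EF 10.5 — the enrichment factor improved in 10 of 10
repetitions of this configuration.

Single pieces compose with pipes and the usual generics:

```r
model <- qsir_train(bench, qsir_hyperparams(n_estimators = 300), seed = 1)
tidy(model); glance(model)
predict(model, "O=C1C=CC(=O)C=C1")      # tibble: smiles, m
count_pains(bench)                       # PAINS alerts in the set
autoplot(exp, metrics = c("mcc", "ef", "ir"))
```

A thin CLI wraps the same functions
(`inst/scripts/qsiraug run|benchmark|report` with YAML configs).

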