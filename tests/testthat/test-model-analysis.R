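# Random-forest kernel and centered kernel alignment.

test_that("the leaf kernel counts co-partitioning fractions", {
  # single-node trees: everyone shares the only leaf
  ones <- matrix(0L, 4, 3)
  expect_equal(rf_kernel(ones), matrix(1, 4, 4))
  # 2 trees, hand-counted co-occurrences
  leaves <- matrix(c(0L, 0L,
                     0L, 1L,
                     1L, 1L), 3, 2, byrow = TRUE)
  K <- rf_kernel(leaves)
  expect_equal(K[1, 2], 0.5)
  expect_equal(K[1, 3], 0)
  expect_equal(K[2, 3], 0.5)
  expect_equal(diag(K), rep(1, 3))
  expect_identical(K, t(K))
  expect_error(rf_kernel(matrix(integer(0), 3, 0)),
               class = "qsiraug_contract")
})

test_that("leaf kernels are positive semidefinite", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:15, 1); t <- sample(3:12, 1)
    leaves <- matrix(sample.int(4, n * t, replace = TRUE), n, t)
    ev <- eigen(rf_kernel(leaves), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("centering zeroes margins, kills constants and is idempotent", {
  K <- matrix(5, 4, 4)
  expect_equal(center_kernel(K), matrix(0, 4, 4))
  expect_equal(center_kernel(diag(2)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  set.seed(3)
  L <- matrix(sample.int(3, 18, replace = TRUE), 6, 3)
  Kc <- center_kernel(rf_kernel(L))
  expect_lt(max(abs(rowSums(Kc))), 1e-12)
  expect_equal(center_kernel(Kc), Kc, tolerance = 1e-12)
})

test_that("cka is a normalized alignment with its symmetries", {
  set.seed(5)
  L1 <- matrix(sample.int(3, 24, replace = TRUE), 8, 3)
  L2 <- matrix(sample.int(3, 24, replace = TRUE), 8, 3)
  K1 <- rf_kernel(L1); K2 <- rf_kernel(L2)
  expect_equal(cka(K1, K1), 1, tolerance = 1e-12)
  expect_equal(cka(K1, K2), cka(K2, K1))
  v <- cka(K1, K2)
  expect_gte(v, 0); expect_lte(v, 1)
  # simultaneous probe reordering leaves cka unchanged
  p <- sample(8)
  expect_equal(cka(K1[p, p], K2[p, p]), v, tolerance = 1e-12)
  # hand-built 3x3 oracle: direct Frobenius-ratio arithmetic
  A <- matrix(c(1, .5, 0, .5, 1, .5, 0, .5, 1), 3, 3)
  B <- matrix(c(1, 0, .5, 0, 1, 0, .5, 0, 1), 3, 3)
  H <- diag(3) - matrix(1 / 3, 3, 3)
  Ac <- H %*% A %*% H; Bc <- H %*% B %*% H
  want <- sum(Ac * Bc) / sqrt(sum(Ac * Ac) * sum(Bc * Bc))
  expect_equal(cka(A, B), min(max(want, 0), 1))
  # a constant kernel centers to zero: alignment undefined
  expect_true(is.na(cka(matrix(1, 3, 3), A)))
})

test_that("identically trained forests have cka 1 on any probe set", {
  tr <- fix_split()$train
  probe <- fix_split()$test$smiles[1:25]
  m1 <- qsir_train(tr, qsir_hyperparams(n_estimators = 40), seed = 7)
  m2 <- qsir_train(tr, qsir_hyperparams(n_estimators = 40), seed = 7)
  K1 <- rf_kernel(leaf_assignments(m1, probe))
  K2 <- rf_kernel(leaf_assignments(m2, probe))
  expect_equal(cka(K1, K2), 1, tolerance = 1e-12)
})

test_that("the similarity report covers every iteration and student pair", {
  tr <- fix_split()$train
  probe <- fix_split()$test[1:20, ]
  teacher <- fix_model()
  runs <- list(
    list(qsir_train(tr, qsir_hyperparams(n_estimators = 30), seed = 1),
         qsir_train(tr, qsir_hyperparams(n_estimators = 30), seed = 2)),
    list(qsir_train(tr, qsir_hyperparams(n_estimators = 30), seed = 3),
         qsir_train(tr, qsir_hyperparams(n_estimators = 30), seed = 4))
  )
  rep <- student_similarity_report(teacher, runs, probe)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$teacher_student_cka >= 0 &
                    rep$teacher_student_cka <= 1))
  # two runs: exactly one student pair per iteration
  expect_true(all(is.finite(rep$inter_student_cka)))
  # identical models everywhere: both series 1
  same <- list(list(teacher), list(teacher))
  rep_same <- student_similarity_report(teacher, same, probe)
  expect_equal(rep_same$teacher_student_cka, 1, tolerance = 1e-12)
  expect_equal(rep_same$inter_student_cka, 1, tolerance = 1e-12)
})
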