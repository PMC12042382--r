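# Centered kernel alignment with a random-forest kernel: two forests are
# compared by how similarly they partition a probe set across their trees.

#' Random-forest leaf co-occurrence kernel
#'
#' `K[i, j]` is the fraction of trees in which molecules i and j fall into
#' the same terminal node. The kernel is symmetric with unit diagonal and
#' positive semidefinite (it is an average of block-indicator kernels).
#'
#' @param leaves Integer matrix of leaf assignments (molecules x trees),
#'   as returned by [leaf_assignments()].
#' @return Square kernel matrix.
#' @export
rf_kernel <- function(leaves) {
  stopifnot(is.matrix(leaves))
  if (ncol(leaves) == 0) {
    rlang::abort("leaf matrix has zero trees", class = "qsiraug_contract")
  }
  n <- nrow(leaves)
  K <- matrix(0, n, n)
  for (t in seq_len(ncol(leaves))) {
    K <- K + outer(leaves[, t], leaves[, t], "==")
  }
  K / ncol(leaves)
}

#' Center a kernel matrix
#'
#' Double centering `H K H` with `H = I - (1/n) 11'`; rows and columns of
#' the result sum to zero. Centering is idempotent.
#'
#' @param K Square symmetric kernel matrix.
#' @return Centered kernel matrix.
#' @export
center_kernel <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% K %*% H
}

#' Centered kernel alignment
#'
#' `CKA(K1, K2) = <K1c, K2c>_F / (||K1c||_F ||K2c||_F)` on the centered
#' kernels (the biased HSIC estimator). For positive semidefinite kernels
#' over the same probe set the value lies in \[0, 1\], 1 meaning the two
#' models partition the probe set identically up to relabeling.
#'
#' @param K1,K2 Kernel matrices over the same probe molecules in the same
#'   order.
#' @return Similarity in \[0, 1\], or `NA` if a centered kernel vanishes
#'   (a constant kernel carries no alignment information).
#' @export
cka <- function(K1, K2) {
  stopifnot(is.matrix(K1), is.matrix(K2), all(dim(K1) == dim(K2)),
            nrow(K1) == ncol(K1))
  K1c <- center_kernel(K1)
  K2c <- center_kernel(K2)
  n1 <- sqrt(sum(K1c * K1c))
  n2 <- sqrt(sum(K2c * K2c))
  # constant kernels center to zero up to round-off; no alignment defined
  if (n1 < 1e-12 * nrow(K1) || n2 < 1e-12 * nrow(K1)) return(NA_real_)
  val <- sum(K1c * K2c) / (n1 * n2)
  min(max(val, 0), 1)
}

# CKA between two fitted models on a probe set.
model_cka <- function(model_a, model_b, probe_smiles) {
  Ka <- rf_kernel(leaf_assignments(model_a, probe_smiles))
  Kb <- rf_kernel(leaf_assignments(model_b, probe_smiles))
  cka(Ka, Kb)
}

#' Teacher-student and inter-student similarity report
#'
#' Given the per-iteration student models of several runs and the probe
#' set, computes, for every iteration: the mean CKA between the initial
#' teacher and each run's student, and the mean CKA over all pairs of
#' students from different runs.
#'
#' @param teacher The initial `qsir_model`.
#' @param students A list of runs, each a list of `qsir_model`s ordered by
#'   iteration (all runs must have equal length).
#' @param probe Tibble with a `smiles` column (typically the test set).
#' @return Tibble with `iteration`, `teacher_student_cka`,
#'   `inter_student_cka`.
#' @export
student_similarity_report <- function(teacher, students, probe) {
  stopifnot(length(students) >= 1)
  n_iter <- unique(vapply(students, length, integer(1)))
  if (length(n_iter) != 1) {
    rlang::abort("all runs must have the same number of iterations",
                 class = "qsiraug_contract")
  }
  smiles <- if (is.data.frame(probe)) probe$smiles else probe
  K_teacher <- rf_kernel(leaf_assignments(teacher, smiles))
  out <- vector("list", n_iter)
  for (t in seq_len(n_iter)) {
    Ks <- lapply(students, function(run)
      rf_kernel(leaf_assignments(run[[t]], smiles)))
    ts <- mean(vapply(Ks, function(K) cka(K_teacher, K), numeric(1)))
    pairs <- if (length(Ks) >= 2) utils::combn(length(Ks), 2) else NULL
    is_cka <- if (is.null(pairs)) NA_real_ else {
      mean(apply(pairs, 2, function(p) cka(Ks[[p[1]]], Ks[[p[2]]])))
    }
    out[[t]] <- tibble::tibble(iteration = t,
                               teacher_student_cka = ts,
                               inter_student_cka = is_cka)
  }
  dplyr::bind_rows(out)
}
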