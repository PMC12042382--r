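# Evaluation metrics: classifier performance (MCC, enrichment factor,
# balanced accuracy, PR-AUC), data-set composition (imbalance rate), and
# chemical characterization of molecule sets (internal diversity, PAINS
# alerts, QED, scaffold similarity), plus the strategy-comparison t-test.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

as_confusion <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  if (is.numeric(c) && length(c) == 4 &&
      all(c("tp", "fp", "tn", "fn") %in% names(c))) {
    return(confusion_counts(c[["tp"]], c[["fp"]], c[["tn"]], c[["fn"]]))
  }
  rlang::abort("expected confusion_counts or named tp/fp/tn/fn vector",
               class = "qsiraug_contract")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in \[-1, 1\].
#' If any factor of the denominator is zero the MCC is defined as 0 (the
#' usual convention for degenerate confusion matrices).
#'
#' @param c A [confusion_counts()] (or named vector tp/fp/tn/fn).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(c) {
  c <- as_confusion(c)
  num <- c$tp * c$tn - c$fp * c$fn
  fac <- c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)
  if (any(fac == 0)) return(0)
  # products can overflow integer range; work in double
  num / sqrt(prod(as.numeric(fac)))
}

#' Enrichment factor
#'
#' Precision divided by the positive-class prevalence:
#' `EF = (TP/(TP+FP)) / ((TP+FN)/N)`. EF > 1 means the classifier enriches
#' true positives relative to random selection; the maximum, reached at
#' precision 1, is `N/(TP+FN)`. With no predicted positives (TP+FP = 0)
#' precision is undefined and `NA` is returned rather than 0.
#'
#' @param c A [confusion_counts()] (or named vector tp/fp/tn/fn).
#' @return EF >= 0, or `NA` if no positives were predicted.
#' @export
enrichment_factor <- function(c) {
  c <- as_confusion(c)
  n <- c$tp + c$fp + c$tn + c$fn
  if (c$tp + c$fn == 0) {
    rlang::abort("no actual positives: EF undefined", class = "qsiraug_contract")
  }
  if (c$tp + c$fp == 0) return(NA_real_)
  precision <- c$tp / (c$tp + c$fp)
  prevalence <- (c$tp + c$fn) / n
  precision / prevalence
}

#' Imbalance rate
#'
#' `|positives - negatives| / (positives + negatives)`: 0 for a perfectly
#' balanced set, 1 when one class is absent.
#'
#' @param n_pos,n_neg Class counts.
#' @return IR in \[0, 1\].
#' @export
imbalance_rate <- function(n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (n_pos + n_neg == 0) {
    rlang::abort("empty set", class = "qsiraug_contract")
  }
  abs(n_pos - n_neg) / (n_pos + n_neg)
}

#' Internal diversity of a molecule set
#'
#' `IntDiv_p = 1 - (mean over all ordered pairs, self-pairs included, of
#' Tanimoto^p)^(1/p)`, computed on radius-2/2048 Morgan fingerprints.
#' Normalizing over all |G|^2 ordered pairs keeps the metric inside
#' \[0, 1\]; a set of identical molecules scores 0.
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column), or a precomputed 0/1 fingerprint matrix.
#' @param p Power mean order (default 1).
#' @return IntDiv_p in \[0, 1\].
#' @export
internal_diversity <- function(smiles, p = 1) {
  if (is.matrix(smiles)) {
    fps <- smiles
  } else {
    if (is.data.frame(smiles)) smiles <- smiles$smiles
    stopifnot(is.character(smiles))
    if (length(smiles) == 0) {
      rlang::abort("empty molecule set", class = "qsiraug_contract")
    }
    fps <- morgan_fingerprint(smiles, radius = 2, nbits = 2048)
  }
  sims <- tanimoto_matrix(fps, fps)
  1 - mean(sims^p)^(1 / p)
}

# PAINS catalog, lazily loaded and validated once per session.
pains_catalog <- function() {
  if (exists("pains", envir = .qsiraug_cache, inherits = FALSE)) {
    return(get("pains", envir = .qsiraug_cache))
  }
  path <- system.file("extdata", "pains_smarts.tsv", package = "qsiraug")
  if (!nzchar(path)) {
    rlang::abort("PAINS catalog not found in installed package")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  tab <- data.frame(
    id = vapply(parts, `[`, character(1), 1),
    smarts = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  assign("pains", tab, envir = .qsiraug_cache)
  tab
}

#' Count molecules matching PAINS alerts
#'
#' Number of molecules matching at least one pattern of the published
#' pan-assay interference (PAINS) substructure catalog (families A, B and
#' C; 480 SMARTS). Each molecule instance is counted at most once no matter
#' how many patterns it matches.
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Integer count.
#' @export
count_pains <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(0L)
  sum(pains_flags(smiles))
}

#' @rdname count_pains
#' @return `pains_flags()` returns the per-molecule logical vector.
#' @export
pains_flags <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  smarts_match_any(smiles, pains_catalog()$smarts)
}

#' Scaffold similarity to a reference set
#'
#' For each new molecule, the maximum Tanimoto similarity (radius-2/2048
#' Morgan fingerprints) between its Bemis-Murcko scaffold and the scaffolds
#' of the reference set; the mean of these maxima is reported. Acyclic
#' molecules carry no scaffold: they are excluded from the mean and counted
#' in the `n_acyclic` attribute. If every new molecule is acyclic the
#' similarity is undefined (`NA`).
#'
#' @param new_smiles,ref_smiles Character vectors of valid SMILES (or data
#'   frames with a `smiles` column).
#' @return Mean similarity in \[0, 1\] (or `NA`), with attribute
#'   `n_acyclic`.
#' @export
scaffold_similarity <- function(new_smiles, ref_smiles) {
  if (is.data.frame(new_smiles)) new_smiles <- new_smiles$smiles
  if (is.data.frame(ref_smiles)) ref_smiles <- ref_smiles$smiles
  stopifnot(length(new_smiles) > 0, length(ref_smiles) > 0)
  new_scaf <- murcko_scaffold(new_smiles)
  ref_scaf <- unique(murcko_scaffold(ref_smiles))
  ref_scaf <- ref_scaf[nzchar(ref_scaf) & !is.na(ref_scaf)]
  cyclic <- nzchar(new_scaf) & !is.na(new_scaf)
  n_acyclic <- sum(!cyclic)
  if (!any(cyclic) || length(ref_scaf) == 0) {
    return(structure(NA_real_, n_acyclic = n_acyclic))
  }
  fp_new <- morgan_fingerprint(new_scaf[cyclic], radius = 2, nbits = 2048)
  fp_ref <- morgan_fingerprint(ref_scaf, radius = 2, nbits = 2048)
  sims <- tanimoto_matrix(fp_new, fp_ref)
  structure(mean(apply(sims, 1, max)), n_acyclic = n_acyclic)
}

# --- QED -------------------------------------------------------------------

# Desirability parameters of the QED drug-likeness model (Bickerton et al.,
# Nature Chemistry 2012; the "average descriptor weights" parameterization).
# Each property d is mapped through an asymmetric double sigmoid
# ADS(x; a,b,c,d,e,f,dmax) and the weighted geometric mean of the eight
# desirabilities is the QED.
qed_ads_params <- function() {
  list(
    MW    = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
              49.22325677, 65.37051707, 104.9805561),
    ALOGP = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
              0.822739154, 0.576295591, 131.3186604),
    HBA   = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
              0.290141953, 1.300669958, 148.7763046),
    HBD   = c(1.618662227, 1010.051101, 0.985094388, 0.000000001,
              0.713820843, 0.920922555, 258.1632616),
    PSA   = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
              12.01999824, 28.51324732, 104.5686167),
    ROTB  = c(0.010000000, 272.4121427, 2.558379970, 1.565547684,
              1.271567166, 2.758063707, 105.4420403),
    AROM  = c(3.217788970, 957.7374108, 2.274627939, 0.000000001,
              1.317690384, 0.375760881, 312.3372610),
    ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001,
               0.185904477, 0.875193782, 417.7253140)
  )
}

qed_weights <- function() {
  c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
    ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)
}

ads <- function(x, p) {
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]
  dmax <- p[7]
  (a + b / (1 + exp(-(x - c + d / 2) / e)) *
     (1 - 1 / (1 + exp(-(x - c - d / 2) / f)))) / dmax
}

# Compact structural-alert list standing in for the QED "ALERTS" count
# (nitro/azo groups, aldehydes, acyl halides, epoxides, hydrazines,
# isocyanates, Michael acceptors, peroxides, long perhalogenation).
qed_alert_smarts <- function() {
  c("[N+](=O)[O-]", "N=[N]", "[CX3H1]=O", "C(=O)[Cl,Br,I]",
    "C1OC1", "[NX3][NX3]", "N=C=O", "[CX3]=[CX3]-[CX3]=[OX1]",
    "OO", "[SX2][SX2]", "C(F)(F)C(F)(F)C(F)(F)", "[Cl,Br,I][CX4][Cl,Br,I]")
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted-geometric-mean desirability over eight physicochemical
#' properties (molecular weight, logP, H-bond acceptors/donors, polar
#' surface area, rotatable bonds, aromatic rings, structural alerts),
#' using the published desirability parameterization. Descriptors are
#' computed with Open Babel, so values track but do not exactly reproduce
#' implementations built on other toolkits. Scores lie in (0, 1); higher is
#' more drug-like.
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Tibble with `smiles` and `qed`.
#' @export
qed_score <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(tibble::tibble(smiles = character(0),
                                                 qed = numeric(0)))
  desc <- ob_descriptors(smiles, fields = c("MW", "logP", "TPSA", "HBD",
                                            "HBA1", "rotors", "abonds"))
  # aromatic ring count approximated from aromatic bond count (6 bonds per
  # isolated benzenoid ring; fused systems share bonds, ~5 per ring)
  arom_rings <- round(desc$abonds / 5.5)
  alert_hits <- vapply(qed_alert_smarts(),
                       function(p) smarts_match_any(smiles, p),
                       logical(length(smiles)))
  alerts <- rowSums(matrix(alert_hits, nrow = length(smiles)))
  props <- cbind(MW = desc$MW, ALOGP = desc$logP, HBA = desc$HBA1,
                 HBD = desc$HBD, PSA = desc$TPSA, ROTB = desc$rotors,
                 AROM = arom_rings, ALERTS = alerts)
  pars <- qed_ads_params()
  w <- qed_weights()
  d <- vapply(names(pars), function(nm) {
    pmax(ads(props[, nm], pars[[nm]]), 1e-6)
  }, numeric(length(smiles)))
  if (length(smiles) == 1) d <- matrix(d, nrow = 1,
                                       dimnames = list(NULL, names(pars)))
  qed <- exp(as.vector(log(d) %*% w) / sum(w))
  tibble::tibble(smiles = smiles, qed = qed)
}

#' Per-molecule QED with summary
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return List with `scores` (tibble from [qed_score()]) and `mean_qed`.
#' @export
qed_and_summary <- function(smiles) {
  sc <- qed_score(smiles)
  list(scores = sc, mean_qed = mean(sc$qed))
}

# --- classifier report -----------------------------------------------------

# Average precision (step-interpolated PR-AUC): sum over the ranked list of
# (recall increment) x (precision at that cut).
pr_auc <- function(probs, labels) {
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]
  n_pos <- sum(y == 1)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Threshold and ranking metrics for a probability classifier
#'
#' @param probs Predicted interference probabilities.
#' @param labels True 0/1 labels (both classes must be present).
#' @param threshold Classification threshold (predicted positive iff
#'   `prob >= threshold`).
#' @return One-row tibble with `mcc`, `ef`, `balanced_accuracy`, `pr_auc`
#'   and the confusion counts.
#' @export
classification_report <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    rlang::abort("labels contain a single class", class = "qsiraug_contract")
  }
  pred <- as.integer(probs >= threshold)
  cc <- confusion_counts(
    tp = sum(pred == 1 & labels == 1),
    fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0),
    fn = sum(pred == 0 & labels == 1)
  )
  tpr <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  tnr <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
  tibble::tibble(
    mcc = mcc(cc),
    ef = enrichment_factor(cc),
    balanced_accuracy = (tpr + tnr) / 2,
    pr_auc = pr_auc(probs, labels),
    tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn
  )
}

#' Welch t-test between two strategies
#'
#' Two-sample Welch t-test on per-run metric values (fractional
#' Welch-Satterthwaite degrees of freedom).
#'
#' @param runs_a,runs_b Numeric vectors of per-run metric values (>= 2
#'   each).
#' @param metric Optional metric name carried into the output.
#' @return One-row tibble with `statistic`, `p_value`, `df`, means and
#'   sample sizes.
#' @export
compare_strategies <- function(runs_a, runs_b, metric = NA_character_) {
  stopifnot(length(runs_a) >= 2, length(runs_b) >= 2)
  if (stats::var(runs_a) == 0 && stats::var(runs_b) == 0) {
    if (identical(mean(runs_a), mean(runs_b))) {
      return(tibble::tibble(metric = metric, statistic = 0, p_value = 1,
                            df = NA_real_, mean_a = mean(runs_a),
                            mean_b = mean(runs_b), n_a = length(runs_a),
                            n_b = length(runs_b)))
    }
    rlang::abort("zero variance in both arms", class = "qsiraug_contract")
  }
  tt <- stats::t.test(runs_a, runs_b, var.equal = FALSE)
  tibble::tibble(
    metric = metric,
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    mean_a = mean(runs_a), mean_b = mean(runs_b),
    n_a = length(runs_a), n_b = length(runs_b)
  )
}
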