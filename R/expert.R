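# Pluggable expert-preference scorer. The production systems use a trained
# preference network distilled from medicinal chemists; here the default is
# a deterministic drug-likeness heuristic behind the same interface, and an
# adapter point is left for an external preference model.

#' Expert scorer protocol
#'
#' An expert scorer is any object for which [expert_score()] returns one
#' finite preference score per molecule, plus an `orientation` attribute
#' saying whether larger raw scores mean more preferred. Orientation is
#' explicit because preference models disagree on sign conventions; the
#' acquisition layer flips scores so 1 always means most preferred after
#' [normalize_preferences()].
#'
#' @param scorer An expert scorer object.
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Numeric vector of raw preference scores.
#' @export
expert_score <- function(scorer, smiles) {
  UseMethod("expert_score")
}

#' @export
expert_score.function <- function(scorer, smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  scorer(smiles)
}

#' Orientation of an expert scorer
#'
#' @param scorer An expert scorer object.
#' @return `"higher"` or `"lower"` (which raw direction means preferred).
#' @export
expert_orientation <- function(scorer) {
  attr(scorer, "orientation") %||% "higher"
}

#' Heuristic expert proxy
#'
#' A deterministic composite standing in for a learned chemist-preference
#' model: QED drug-likeness with penalties for excessive rotatable bonds
#' (beyond 8) and heavy halogenation (more than two Cl/Br/I). Larger is
#' preferred.
#'
#' @return An expert scorer (a function with orientation attribute).
#' @export
expert_heuristic_proxy <- function() {
  f <- function(smiles) {
    heuristic_proxy_score(smiles)
  }
  attr(f, "orientation") <- "higher"
  class(f) <- c("heuristic_expert", "function")
  f
}

#' @export
expert_score.heuristic_expert <- function(scorer, smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  heuristic_proxy_score(smiles)
}

#' Heuristic drug-likeness preference score
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Numeric scores (larger = preferred), finite for valid molecules.
#' @export
heuristic_proxy_score <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(numeric(0))
  q <- qed_score(smiles)$qed
  desc <- ob_descriptors(smiles, fields = c("rotors"))
  n_heavy_hal <- vapply(gregexpr("Cl|Br|I(?![a-z])", smiles, perl = TRUE),
                        function(m) sum(m > 0), numeric(1))
  q - 0.04 * pmax(desc$rotors - 8, 0) - 0.06 * pmax(n_heavy_hal - 2, 0)
}

#' Min-max normalize preference scores
#'
#' Rescales raw scores to \[0, 1\] within the current pool, flipping
#' orientation so that 1 always means most preferred. A degenerate pool
#' (all raw scores equal) maps to 0.5 everywhere.
#'
#' @param raw Numeric vector of raw scores.
#' @param orientation `"higher"` (larger raw = preferred) or `"lower"`.
#' @return Scores in \[0, 1\].
#' @export
normalize_preferences <- function(raw, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(0.5, length(raw)))
  x <- (raw - rng[1]) / (rng[2] - rng[1])
  if (orientation == "lower") 1 - x else x
}
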