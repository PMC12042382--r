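#' Parse and canonicalize SMILES strings
#'
#' Parses each SMILES with Open Babel, returning the canonical form and the
#' molecular weight. Invalid SMILES are never an error: they come back with
#' `valid = FALSE` and `NA` canonical form, and a message reports how many
#' were rejected (generators are allowed to emit junk; junk is dropped, not
#' imputed).
#'
#' @param smiles Character vector of SMILES strings, or a data frame with a
#'   `smiles` column (first-argument data frame for piping).
#' @param quiet Suppress the rejection message.
#' @return A tibble with columns `smiles` (input), `canonical_smiles`,
#'   `mw` (Da) and `valid`.
#' @examples
#' \dontrun{
#' parse_and_canonicalize(c("C1=CC=CC=C1", "CCO", "C1CC"))
#' }
#' @export
parse_and_canonicalize <- function(smiles, quiet = FALSE) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles))
  if (any(!nzchar(trimws(smiles)))) {
    rlang::abort("empty SMILES string", class = "qsiraug_contract")
  }
  canon <- ob_canonical(smiles)
  mw <- rep(NA_real_, length(smiles))
  ok <- !is.na(canon)
  if (any(ok)) {
    mw[ok] <- ob_descriptors(canon[ok], fields = "MW")$MW
  }
  n_bad <- sum(!ok)
  if (n_bad > 0 && !quiet) {
    rlang::inform(paste0(n_bad, " invalid SMILES rejected"))
  }
  tibble::tibble(
    smiles = smiles,
    canonical_smiles = canon,
    mw = mw,
    valid = ok
  )
}

#' Morgan (ECFP) fingerprints
#'
#' Circular fingerprints folded to a fixed bit length. "Morgan 3" means
#' radius 3 (ECFP6) and "Morgan 2" radius 2 (ECFP4). The fingerprint of a
#' molecule is invariant to the atom order of the input SMILES because it is
#' computed on the perceived molecular graph.
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @param radius Neighborhood radius, 2 or 3.
#' @param nbits Folded length (power of two, default 2048).
#' @return Integer 0/1 matrix, one row per molecule, `nbits` columns.
#' @export
morgan_fingerprint <- function(smiles, radius = 3, nbits = 2048) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles), radius %in% c(2, 3))
  canon <- ob_canonical(smiles)
  if (anyNA(canon)) {
    rlang::abort("morgan_fingerprint() requires valid SMILES; parse first",
                 class = "qsiraug_contract")
  }
  ob_ecfp(canon, radius = radius, nbits = nbits)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`. The degenerate 0/0 case (two empty fingerprints)
#' is defined as 1: two featureless molecules are treated as maximally
#' similar so trivial duplicates do not inflate diversity metrics.
#'
#' @param a,b Binary vectors of equal length (single fingerprints).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("fingerprint lengths differ", class = "qsiraug_contract")
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# All-pairs Tanimoto between rows of two 0/1 matrices (n x bits, m x bits).
tanimoto_matrix <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  A <- matrix(as.numeric(A), nrow(A), ncol(A))
  B <- matrix(as.numeric(B), nrow(B), ncol(B))
  inter <- A %*% t(B)
  pa <- rowSums(A)
  pb <- rowSums(B)
  un <- outer(pa, pb, "+") - inter
  out <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  out
}

#' Bemis-Murcko scaffold
#'
#' Reduces each molecule to its ring systems plus connecting linkers: side
#' chains are pruned atom by atom, then atoms double- or triple-bonded
#' directly to the retained framework (e.g. quinone oxygens) are restored.
#' Acyclic molecules have no scaffold and return the empty string.
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @return Character vector of canonical scaffold SMILES ("" for acyclic
#'   molecules).
#' @export
murcko_scaffold <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0) return(character(0))
  key <- paste0("murcko|", smiles)
  hit <- cache_get(key)
  out <- rep(NA_character_, n)
  for (i in which(!is.na(hit))) out[i] <- get(key[i], envir = .qsiraug_cache)
  todo <- which(is.na(hit))
  if (length(todo)) {
    out[todo] <- murcko_scaffold_impl(smiles[todo])
    for (i in todo) assign(key[i], out[i], envir = .qsiraug_cache)
  }
  out
}

murcko_scaffold_impl <- function(smiles) {
  sdf_lines <- ob_run_smiles(smiles, c("-osdf"))
  sdf_file <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf_file), add = TRUE)
  writeLines(sdf_lines, sdf_file)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(sdf_file))
  out <- rep(NA_character_, length(smiles))
  mol_blocks <- character(0)
  block_idx <- integer(0)
  titles <- vapply(ChemmineR::SDFset2SDF(sdfs), function(s)
    ChemmineR::header(s)[["Molecule_Name"]], character(1))
  for (j in seq_along(sdfs)) {
    i <- as.integer(sub("^q", "", titles[j]))
    if (is.na(i)) next
    sdf <- sdfs[[j]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    keep <- scaffold_atoms(nrow(ab), bb)
    if (length(keep) == 0) {
      out[i] <- ""
      next
    }
    mol_blocks <- c(mol_blocks, build_molblock(ab, bb, keep, paste0("q", i)))
    block_idx <- c(block_idx, i)
  }
  if (length(mol_blocks)) {
    scaf_file <- tempfile(fileext = ".sdf")
    on.exit(unlink(scaf_file), add = TRUE)
    writeLines(mol_blocks, scaf_file)
    lines <- suppressWarnings(system2(ob_path(), c(scaf_file, "-ocan"),
                                      stdout = TRUE, stderr = FALSE))
    canon <- ob_align(lines, max(block_idx))
    out[block_idx] <- canon[block_idx]
  }
  out
}

# Indices of framework atoms: iteratively strip degree-1 atoms, then restore
# atoms attached to the core by a double/triple bond.
scaffold_atoms <- function(n_atoms, bondblock) {
  if (n_atoms == 0 || is.null(nrow(bondblock)) || nrow(bondblock) == 0) {
    return(integer(0))
  }
  b1 <- as.integer(bondblock[, 1]); b2 <- as.integer(bondblock[, 2])
  ord <- as.integer(bondblock[, 3])
  alive <- rep(TRUE, n_atoms)
  repeat {
    deg <- tabulate(c(b1[alive[b1] & alive[b2]], b2[alive[b1] & alive[b2]]),
                    nbins = n_atoms)
    term <- which(alive & deg <= 1)
    if (length(term) == 0) break
    alive[term] <- FALSE
    if (!any(alive)) break
  }
  core <- which(alive)
  if (length(core) == 0) return(integer(0))
  # restore multiply-bonded attachments (e.g. exocyclic carbonyl oxygens)
  multi <- ord >= 2
  add <- unique(c(b2[multi & alive[b1] & !alive[b2]],
                  b1[multi & alive[b2] & !alive[b1]]))
  sort(c(core, add))
}

# Minimal V2000 molblock for an atom subset (coordinates are irrelevant for
# SMILES output; bond orders and elements are preserved).
build_molblock <- function(atomblock, bondblock, keep, title) {
  sym <- sub("_[0-9]+$", "", rownames(atomblock))
  map <- integer(nrow(atomblock))
  map[keep] <- seq_along(keep)
  b1 <- as.integer(bondblock[, 1]); b2 <- as.integer(bondblock[, 2])
  ord <- as.integer(bondblock[, 3])
  kb <- which(b1 %in% keep & b2 %in% keep)
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    sym[keep])
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        map[b1[kb]], map[b2[kb]], ord[kb])
  c(title, "  qsiraug", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(keep), length(kb)),
    atom_lines, bond_lines, "M  END", "$$$$")
}

#' Match molecules against SMARTS patterns
#'
#' Returns, for each molecule, whether it matches at least one of the given
#' SMARTS patterns. Matching is done with explicit hydrogens so patterns
#' using `[#1]` atoms behave as published.
#'
#' @param smiles Character vector of valid SMILES (or data frame with a
#'   `smiles` column).
#' @param patterns Character vector of SMARTS.
#' @return Logical vector aligned with `smiles`.
#' @export
smarts_match_any <- function(smiles, patterns) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles), is.character(patterns), length(patterns) > 0)
  ob_smarts_any(smiles, patterns)
}
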