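# Open Babel command-line backend.
#
# All molecule-level chemistry (canonicalization, fingerprints, descriptors,
# SMARTS matching) is delegated to the `obabel` executable in batch mode:
# one process call per vector of molecules, never one call per molecule.
# Results are cached per canonical SMILES in a package-local environment.

.qsiraug_cache <- new.env(parent = emptyenv())

ob_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    rlang::abort(
      "The 'obabel' executable (Open Babel) was not found on the PATH.",
      class = "qsiraug_missing_obabel"
    )
  }
  p
}

#' @noRd
ob_cache_reset <- function() {
  rm(list = ls(.qsiraug_cache, all.names = TRUE), envir = .qsiraug_cache)
  invisible(NULL)
}

cache_get <- function(keys) {
  vapply(keys, function(k) {
    if (exists(k, envir = .qsiraug_cache, inherits = FALSE)) k else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Run obabel on a SMILES vector. Molecules are tagged with positional titles
# (q<i>) so that output lines can be mapped back even when Open Babel drops
# unparseable inputs. Returns the raw stdout lines.
ob_run_smiles <- function(smiles, args) {
  stopifnot(is.character(smiles))
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste0(smiles, " q", seq_along(smiles)), infile)
  out <- suppressWarnings(system2(
    ob_path(), c(infile, "-e", args),
    stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    rlang::abort(paste0("obabel exited with status ", status),
                 class = "qsiraug_obabel_error")
  }
  out
}

# Parse "value<TAB or space>q<i>" style output into a vector aligned with the
# input; missing titles (molecules Open Babel rejected) become NA.
ob_align <- function(lines, n, n_fields = 1) {
  res <- rep(NA_character_, n)
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    idx_tok <- grep("^q[0-9]+$", parts)
    if (length(idx_tok) == 0) next
    i <- as.integer(sub("^q", "", parts[idx_tok[1]]))
    if (is.na(i) || i < 1 || i > n) next
    res[i] <- paste(parts[-idx_tok[1]], collapse = "\t")
  }
  res
}

# Canonical SMILES for a character vector; NA where the SMILES cannot be
# parsed. Vectorized, cached.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  key <- paste0("can|", smiles)
  hit <- cache_get(key)
  out <- rep(NA_character_, n)
  cached <- !is.na(hit)
  if (any(cached)) {
    out[cached] <- vapply(key[cached], get, character(1),
                          envir = .qsiraug_cache, USE.NAMES = FALSE)
  }
  todo <- which(!cached)
  if (length(todo)) {
    ok <- nzchar(trimws(smiles[todo]))
    res <- rep(NA_character_, length(todo))
    if (any(ok)) {
      lines <- ob_run_smiles(smiles[todo][ok], c("-ocan"))
      res[ok] <- ob_align(lines, sum(ok))
    }
    out[todo] <- res
    for (j in seq_along(todo)) {
      assign(key[todo[j]], out[todo[j]], envir = .qsiraug_cache)
    }
  }
  out
}

# Molecular descriptors from Open Babel, aligned with the input; rows of NA
# for invalid molecules.
ob_descriptors <- function(smiles,
                           fields = c("MW", "logP", "TPSA", "HBD", "HBA1",
                                      "rotors", "abonds")) {
  n <- length(smiles)
  empty <- matrix(NA_real_, n, length(fields),
                  dimnames = list(NULL, fields))
  if (n == 0) return(tibble::as_tibble(empty))
  lines <- ob_run_smiles(smiles, c("-otxt", "--append", paste(fields, collapse = " ")))
  vals <- ob_align(lines, n)
  for (i in seq_len(n)) {
    if (is.na(vals[i])) next
    parts <- strsplit(vals[i], "\t")[[1]]
    if (length(parts) == length(fields)) {
      empty[i, ] <- suppressWarnings(as.numeric(parts))
    }
  }
  tibble::as_tibble(empty)
}

# ECFP fingerprints via the fpt output format, folded by Open Babel to
# `nbits` (must be a power of two >= 32; the package default is 2048).
ob_ecfp <- function(smiles, radius = 3, nbits = 2048) {
  stopifnot(radius %in% c(2, 3), nbits >= 32)
  n <- length(smiles)
  fp_type <- paste0("ECFP", 2L * radius)
  out <- matrix(0L, n, nbits)
  if (n == 0) return(out)

  key <- paste0("fp", radius, "x", nbits, "|", smiles)
  hit <- cache_get(key)
  cached <- !is.na(hit)
  for (i in which(cached)) {
    out[i, ] <- get(key[i], envir = .qsiraug_cache)
  }
  todo <- which(!cached)
  if (!length(todo)) return(out)

  lines <- ob_run_smiles(smiles[todo],
                         c("-ofpt", paste0("-xf", fp_type), "-xh",
                           paste0("-xN", nbits)))
  # Records start with ">title   N bits set"; hex words follow.
  starts <- grep("^>", lines)
  for (s in seq_along(starts)) {
    hdr <- lines[starts[s]]
    title <- sub("^>\\s*(q[0-9]+).*$", "\\1", hdr)
    i_rel <- as.integer(sub("^q", "", title))
    if (is.na(i_rel)) next
    i <- todo[i_rel]
    end <- if (s < length(starts)) starts[s + 1] - 1 else length(lines)
    words <- unlist(strsplit(trimws(lines[(starts[s] + 1):end]), "\\s+"))
    # fpt interleaves annotation lines (e.g. "Possible superstructure of
    # ..."); only 8-digit hex words belong to the fingerprint
    words <- words[grepl("^[0-9a-fA-F]{8}$", words)]
    bits <- hex_words_to_bits(words)
    if (length(bits)) {
      folded <- unique(bits %% nbits) + 1L
      out[i, folded] <- 1L
    }
    assign(key[i], out[i, ], envir = .qsiraug_cache)
  }
  out
}

# Hex 32-bit words -> 0-based bit indices. Word w, bit b within the word
# maps to index 32*w + b; the mapping only needs to be a fixed bijection.
hex_words_to_bits <- function(words) {
  if (!length(words)) return(integer(0))
  vals <- strtoi(words, base = 16L)
  idx <- integer(0)
  nz <- which(vals != 0 & !is.na(vals))
  for (w in nz) {
    v <- vals[w]
    b <- which(bitwAnd(v, bitwShiftL(1L, 0:30)) != 0) - 1L
    if (v < 0) b <- c(b, 31L)  # strtoi wraps the top bit to negative
    idx <- c(idx, 32L * (w - 1L) + b)
  }
  idx
}

# Boolean SMARTS match (any of `patterns`) per molecule, with explicit
# hydrogens added (alert catalogs use [#1] atoms).
ob_smarts_any <- function(smiles, patterns) {
  n <- length(smiles)
  if (n == 0) return(logical(0))
  stopifnot(length(patterns) >= 1)
  expr <- paste(sprintf("s='%s'", patterns), collapse = " | ")
  lines <- ob_run_smiles(smiles, c("-osmi", "-h", "--filter", shQuote(expr)))
  hits <- ob_align(lines, n)
  !is.na(hits)
}
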