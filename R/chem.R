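# Chemical structure handling via Open Babel (ChemmineOB).
#
# Validity dialect: a SMILES is accepted when (a) it passes a structural
# well-formedness check (balanced parentheses, every ring-closure label
# opened and closed) and (b) Open Babel parses it to a molecule under its
# default valence model. The pre-check exists because Open Babel silently
# repairs some malformed strings (e.g. unbalanced parentheses) that should
# count as invalid generations.

.ring_labels <- function(tokens) {
  # ring-closure labels among chemical tokens: single digits and %NN
  toks <- tokens[!(tokens %in% unlist(special_tokens))]
  lab <- toks[grepl("^[0-9]$|^%[0-9]{2}$", toks)]
  sub("^%", "", lab)
}

#' Structural well-formedness of a SMILES string
#'
#' Checks tokenizability, balanced parentheses and matched ring-closure
#' labels. This is a purely syntactic screen applied before the chemistry
#' toolkit's own parse; it does not check valence.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @export
smiles_wellformed <- function(smiles) {
  vapply(smiles, function(s) {
    toks <- tryCatch(tokenize(s), error = function(e) NULL)
    if (is.null(toks)) return(FALSE)
    depth <- 0L
    for (t in toks) {
      if (t == "(") depth <- depth + 1L
      if (t == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
    }
    if (depth != 0L) return(FALSE)
    counts <- table(.ring_labels(toks))
    all(counts %% 2L == 0L)
  }, logical(1), USE.NAMES = FALSE)
}

# Batch canonicalization through Open Babel's command-line converter (the
# in-process bindings cannot silence Open Babel's per-molecule parse
# warnings). Titles carry the input index so molecules dropped by the parser
# can be realigned; invalid entries map to NA.
.ob_canonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  tf <- tempfile(fileext = ".smi")
  ef <- tempfile(fileext = ".err")
  on.exit(unlink(c(tf, ef)))
  writeLines(paste0(smiles, " m", seq_along(smiles)), tf)
  out <- suppressWarnings(
    system2("obabel", c("-ismi", shQuote(tf), "-ocan"),
            stdout = TRUE, stderr = ef))
  res <- rep(NA_character_, length(smiles))
  parts <- strsplit(out[nzchar(out)], "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2 && grepl("^m[0-9]+$", p[2])) {
      idx <- as.integer(sub("^m", "", p[2]))
      if (nzchar(p[1])) res[idx] <- p[1]
    }
  }
  # molecules whose aromatic system cannot be kekulized are "repaired" by
  # Open Babel into radicals; treat them as invalid instead
  if (file.exists(ef)) {
    err <- readLines(ef, warn = FALSE)
    kek <- grep("Failed to kekulize.*title is m[0-9]+", err, value = TRUE)
    if (length(kek)) {
      idx <- as.integer(sub(".*title is m([0-9]+).*", "\\1", kek))
      res[idx] <- NA_character_
    }
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Maps each string to its unique canonical SMILES, or `NA` if the string is
#' not a valid molecule under the package's validity dialect (see
#' [smiles_wellformed()] and the package vignette).
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  res <- rep(NA_character_, length(smiles))
  ok <- smiles_wellformed(smiles)
  if (any(ok)) res[ok] <- .ob_canonical(smiles[ok])
  res
}

#' Chemical validity of SMILES strings
#'
#' @param smiles Character vector.
#' @return Logical vector: `TRUE` where the string parses to a molecule.
#' @export
is_valid_smiles <- function(smiles) !is.na(canonical_smiles(smiles))

#' Morgan-type circular fingerprints
#'
#' Computes radius-`radius` circular substructure fingerprints (Open Babel's
#' ECFP family; `radius = 2` uses ECFP4) and folds them to `n_bits` bits by
#' modular OR, the standard folding scheme for fixed-length fingerprints.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Bond radius of the circular environments (default 2).
#' @param n_bits Folded fingerprint length (default 1024).
#' @return A logical matrix with one row per molecule and `n_bits` columns;
#'   row names are the input SMILES.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 1024) {
  stopifnot(length(smiles) >= 1, radius >= 0, n_bits >= 1)
  bad <- !is_valid_smiles(smiles)
  if (any(bad))
    stop(sprintf("invalid SMILES: %s", paste(smiles[bad], collapse = ", ")))
  fpname <- paste0("ECFP", 2L * radius)
  src <- paste0(smiles, "\n", collapse = "")
  raw <- ChemmineOB::forEachMol("SMILES", src, function(m)
    ChemmineOB::fingerprint_OB(list(m), fpname))
  if (length(raw) != length(smiles))
    stop("fingerprint computation dropped molecules; check input validity")
  fold <- function(bits) {
    on <- which(bits > 0) - 1L
    v <- logical(n_bits)
    v[(on %% n_bits) + 1L] <- TRUE
    v
  }
  m <- t(vapply(raw, fold, logical(n_bits)))
  rownames(m) <- smiles
  m
}

#' Tanimoto similarity of two bit fingerprints
#'
#' \eqn{T(a,b) = |a \cap b| / |a \cup b|}. Two all-zero fingerprints have an
#' undefined ratio; the package defines that case as 0.
#'
#' @param a,b Logical (or 0/1 numeric) vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# all pairwise Tanimoto similarities between the rows of two bit matrices
.tanimoto_cross <- function(A, B) {
  A <- A * 1; B <- B * 1
  inter <- A %*% t(B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  s <- inter / uni
  s[uni == 0] <- 0
  s
}

#' Nearest-reference Tanimoto similarity
#'
#' For each design, the maximum Tanimoto similarity over a reference set
#' (e.g. known actives), together with the closest reference.
#'
#' @param designs,references Character vectors of valid SMILES.
#' @param radius,n_bits Fingerprint parameters, see [morgan_fingerprint()].
#' @return A data.frame with columns `smiles`, `nearest_similarity`,
#'   `nearest_reference`.
#' @export
nearest_reference_similarity <- function(designs, references,
                                         radius = 2, n_bits = 1024) {
  if (!length(references)) stop("reference set is empty")
  fd <- morgan_fingerprint(designs, radius, n_bits)
  fr <- morgan_fingerprint(references, radius, n_bits)
  s <- .tanimoto_cross(fd, fr)
  j <- max.col(s, ties.method = "first")
  data.frame(smiles = designs,
             nearest_similarity = s[cbind(seq_along(designs), j)],
             nearest_reference = references[j],
             stringsAsFactors = FALSE)
}

#' Pairwise Tanimoto-distance distribution
#'
#' Tanimoto distance is `1 - similarity` on Morgan-type fingerprints. With
#' one set, all unordered pairs within the set are used; with two sets, all
#' cross pairs. The summary mirrors a boxplot: 25th/50th/75th percentiles,
#' mean, and whisker bounds at 1.5 times the interquartile range.
#'
#' @param set_a Character vector of valid SMILES (at least 2 for within-set
#'   mode, at least 1 with `set_b` given).
#' @param set_b Optional second set for cross-pair distances.
#' @param radius,n_bits Fingerprint parameters.
#' @return A list with `distances` (numeric vector) and `summary` (named
#'   vector: q25, median, q75, mean, whisker_low, whisker_high).
#' @export
distance_distribution <- function(set_a, set_b = NULL,
                                  radius = 2, n_bits = 1024) {
  if (is.null(set_b)) {
    if (length(set_a) < 2) stop("need at least 2 molecules for pairwise distances")
    f <- morgan_fingerprint(set_a, radius, n_bits)
    s <- .tanimoto_cross(f, f)
    d <- 1 - s[upper.tri(s)]
  } else {
    if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
    fa <- morgan_fingerprint(set_a, radius, n_bits)
    fb <- morgan_fingerprint(set_b, radius, n_bits)
    d <- as.vector(1 - .tanimoto_cross(fa, fb))
  }
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  list(distances = d,
       summary = c(q25 = q[1], median = q[2], q75 = q[3], mean = mean(d),
                   whisker_low = max(min(d), q[1] - 1.5 * iqr),
                   whisker_high = min(max(d), q[3] + 1.5 * iqr)))
}

#' Fraction of sp3-hybridized carbon atoms
#'
#' Fsp3 is the number of sp3 carbons divided by the total number of carbons.
#' A carbon is counted as sp3 when every bond it participates in is a single
#' bond in the kekulized structure (aromatic carbons therefore never count).
#' Higher values typify three-dimensional, natural-product-like molecules.
#'
#' @param smiles Character vector of valid SMILES, each with at least one
#'   carbon atom.
#' @return Numeric vector of Fsp3 values in `[0, 1]`.
#' @export
fsp3 <- function(smiles) {
  bad <- !is_valid_smiles(smiles)
  if (any(bad))
    stop(sprintf("invalid SMILES: %s", paste(smiles[bad], collapse = ", ")))
  src <- paste0(smiles, "\n", collapse = "")
  sdf_txt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", src))
  mols <- strsplit(sdf_txt, "\\$\\$\\$\\$\n?")[[1]]
  mols <- mols[grepl("V2000", mols)]
  if (length(mols) != length(smiles))
    stop("structure conversion dropped molecules")
  vapply(seq_along(smiles), function(i) {
    lines <- strsplit(mols[i], "\n", fixed = TRUE)[[1]]
    counts <- which(grepl("V2000", lines))[1]
    natoms <- as.integer(substr(lines[counts], 1, 3))
    nbonds <- as.integer(substr(lines[counts], 4, 6))
    atoms <- lines[counts + seq_len(natoms)]
    elems <- trimws(substr(atoms, 32, 34))
    carbons <- which(elems == "C")
    if (!length(carbons))
      stop(sprintf("'%s' contains no carbon atoms; Fsp3 is undefined", smiles[i]))
    non_single <- integer(0)
    if (nbonds > 0) {
      bonds <- lines[counts + natoms + seq_len(nbonds)]
      a1 <- as.integer(substr(bonds, 1, 3))
      a2 <- as.integer(substr(bonds, 4, 6))
      ord <- as.integer(substr(bonds, 7, 9))
      multi <- ord != 1L
      non_single <- unique(c(a1[multi], a2[multi]))
    }
    sum(!(carbons %in% non_single)) / length(carbons)
  }, numeric(1))
}
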