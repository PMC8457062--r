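# SMILES tokenization and vocabulary handling.
#
# Token granularity follows the common chemical-language-model convention:
# a bracket atom ("[nH]", "[C@@H]", ...) is one token, the two-letter
# organic-subset halogens "Cl" and "Br" are one token, a "%NN" two-digit
# ring-closure label is one token, and every other permitted character is a
# token of its own. Splitting bracket atoms or halogens into characters would
# make most generated strings invalid by construction.

#' Special tokens
#'
#' Sequence-delimiting tokens used by the tokenizer and the language model:
#' `BEGIN` opens every token sequence, `END` closes a complete sequence and
#' `PAD` is training-time padding. They are spelled with characters outside
#' the SMILES alphabet so they can never collide with a chemical token.
#'
#' @format A named list with elements `begin`, `end`, `pad`.
#' @export
special_tokens <- list(begin = "^", end = "$", pad = " ")

# single characters permitted outside bracket atoms
.smiles_single_chars <- c(
  "B", "C", "N", "O", "P", "S", "F", "I",      # organic subset (Cl/Br handled separately)
  "b", "c", "n", "o", "p", "s",                # aromatic organic subset
  as.character(0:9),                           # ring closures
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", "*", "@", ":"
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the lexical units a chemical language model
#' is trained on and wraps them in `BEGIN`/`END` markers. Bracket atoms,
#' the halogens `Cl`/`Br` and `%NN` ring labels are kept as single tokens.
#'
#' @param smiles A single non-empty SMILES string.
#' @return A character vector of tokens starting with `BEGIN` and ending
#'   with `END`; concatenating the interior tokens reproduces `smiles`.
#' @examples
#' tokenize("CC(=O)O")
#' tokenize("c1cc[nH]c1")
#' @export
tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (nchar(smiles) == 0L)
    stop("cannot tokenize an empty SMILES string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop(sprintf("unterminated bracket atom starting at position %d in '%s'",
                     i, smiles))
      out <- c(out, substr(smiles, i, j))
      i <- j + 1L
    } else if (ch == "%" ) {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L)))
        stop(sprintf("malformed %%NN ring label at position %d in '%s'", i, smiles))
      out <- c(out, substr(smiles, i, i + 2L))
      i <- i + 3L
    } else if ((ch == "C" || ch == "B") && i < n &&
               ((ch == "C" && chars[i + 1L] == "l") ||
                (ch == "B" && chars[i + 1L] == "r"))) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% .smiles_single_chars) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      stop(sprintf("character '%s' at position %d of '%s' is outside the SMILES alphabet",
                   ch, i, smiles))
    }
  }
  c(special_tokens$begin, out, special_tokens$end)
}

#' Reassemble a SMILES string from a token sequence
#'
#' Inverse of [tokenize()]: strips the `BEGIN`/`END` markers and concatenates
#' the chemical tokens. `detokenize(tokenize(s))` is the identity for every
#' string the tokenizer accepts.
#'
#' @param tokens A character vector starting with `BEGIN`; a trailing `END`
#'   is stripped if present.
#' @return A single SMILES string (possibly empty).
#' @export
detokenize <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  if (tokens[1] != special_tokens$begin)
    stop("token sequence must start with BEGIN")
  body <- tokens[-1]
  if (length(body) && body[length(body)] == special_tokens$end)
    body <- body[-length(body)]
  if (any(body == special_tokens$pad))
    stop("PAD token inside the sequence body")
  if (any(body == special_tokens$begin) || any(body == special_tokens$end))
    stop("BEGIN/END token inside the sequence body")
  paste(body, collapse = "")
}

#' Build a vocabulary from a SMILES corpus
#'
#' Collects the union of tokens over a corpus and fixes a deterministic
#' integer index for each. The special tokens `PAD`, `BEGIN`, `END` occupy
#' the first three slots; chemical tokens follow in sorted order, so two
#' builds from the same corpus are token-for-token identical.
#'
#' @param corpus Character vector of SMILES strings (may be empty).
#' @return An object of class `beamchem_vocab`: a list with `tokens`
#'   (ordered character vector) and `index` (named integer map, 1-based).
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus))
  toks <- character(0)
  for (i in seq_along(corpus)) {
    t <- tryCatch(tokenize(corpus[i]), error = function(e)
      stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE))
    toks <- union(toks, t)
  }
  chem <- sort(setdiff(toks, unlist(special_tokens)), method = "radix")
  tokens <- c(special_tokens$pad, special_tokens$begin, special_tokens$end, chem)
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens))
  class(vocab) <- "beamchem_vocab"
  vocab
}

#' @export
print.beamchem_vocab <- function(x, ...) {
  cat(sprintf("SMILES vocabulary: %d tokens (incl. PAD/BEGIN/END)\n",
              length(x$tokens)))
  cat(" ", paste(utils::head(setdiff(x$tokens, unlist(special_tokens)), 30),
                 collapse = " "), "\n")
  invisible(x)
}

#' Encode tokens as integer ids under a vocabulary
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `beamchem_vocab`.
#' @return Integer vector of 1-based ids.
#' @export
encode_tokens <- function(tokens, vocab) {
  ids <- vocab$index[tokens]
  if (anyNA(ids)) {
    bad <- unique(tokens[is.na(ids)])
    stop(sprintf("tokens not in vocabulary: %s", paste(bad, collapse = ", ")))
  }
  unname(ids)
}

#' Write / read a vocabulary as JSON
#'
#' The serialized form is the ordered token list only; the index is
#' reconstructed on read.
#'
#' @param vocab A `beamchem_vocab`.
#' @param path File path.
#' @return `read_vocabulary` returns a `beamchem_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens))
  class(vocab) <- "beamchem_vocab"
  vocab
}

#' Read a SMILES corpus file
#'
#' One SMILES per line, no header; blank lines are ignored.
#'
#' @param path File path.
#' @return Character vector of SMILES strings.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @rdname read_smiles_file
#' @param smiles Character vector to write.
#' @export
write_smiles_file <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
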