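# Synthetic inputs: small SMILES corpora with controllable structure, and
# explicit toy token-probability models whose sequence probabilities are
# available in closed form. These stand in for the large public corpora a
# full-scale run would use (hundreds of thousands of bioactive molecules for
# pre-training; a few hundred, then a handful, of target ligands for staged
# fine-tuning), so that every other module is testable offline and exactly.
#
# Fixture chemistry is deliberately simple (acyclic chains plus one
# benzene-scaffold family) so enumeration oracles stay exact; realism is not
# the goal.

# substituents used for the benzene-scaffold ("aromatics") narrow family
.aryl_substituents <- c(
  "C", "CC", "CCC", "CCCC", "CCCCC", "CO", "CCO", "CCCO", "OC", "OCC",
  "N", "CN", "CCN", "NC", "C(C)C", "CC(C)C", "C(C)CC", "OCC(C)", "CCOC",
  "COC", "CCCN", "OCCC", "C(C)O", "CC(C)O", "NCC", "CCCCO", "CCCCN",
  "C(C)(C)C", "OC(C)C", "COCC"
)

.enumerate_family <- function(family, max_heavy_atoms) {
  switch(family,
    alkanes = vapply(seq_len(max_heavy_atoms), function(n)
      paste(rep("C", n), collapse = ""), character(1)),
    alcohols = if (max_heavy_atoms < 2) character(0) else
      vapply(seq_len(max_heavy_atoms - 1L), function(n)
        paste0(paste(rep("C", n), collapse = ""), "O"), character(1)),
    ethers = {
      out <- character(0)
      for (tot in 3:max_heavy_atoms) for (n in 1:(tot - 2L)) {
        m <- tot - 1L - n
        if (m >= n) out <- c(out, paste0(strrep("C", n), "O", strrep("C", m)))
      }
      out
    },
    aromatics = {
      heavy <- function(s) nchar(gsub("[()]", "", s))
      subs <- Filter(function(s) heavy(s) + 6 <= max_heavy_atoms,
                     .aryl_substituents)
      mono <- c("c1ccccc1", paste0(subs, "c1ccccc1"))
      # para-disubstituted benzenes, appended after the mono-substituted
      # pool so small corpora stay within the shared-scaffold core family
      di <- character(0)
      for (s1 in subs) for (s2 in subs)
        if (heavy(s1) + heavy(s2) + 6 <= max_heavy_atoms)
          di <- c(di, paste0(s1, "c1ccc(", s2, ")cc1"))
      c(mono, unique(di))
    },
    stop(sprintf("unknown corpus family '%s'", family))
  )
}

#' Generate a synthetic SMILES corpus
#'
#' Deterministic generator for small, valid, unique SMILES corpora.
#' Enumerable families (`"alkanes"`, `"alcohols"`, `"ethers"`,
#' `"aromatics"`) are produced in a fixed enumeration order; the
#' `"aromatics"` family shares a benzene scaffold, making it a narrow
#' structural family suitable for transfer-learning experiments. The
#' `"mixed"` family draws random acyclic C/N/O chains (with optional methyl
#' branches) plus a fraction of benzene-scaffold molecules, canonicalizes
#' them and deduplicates, so the corpus covers the token alphabet of all
#' other families.
#'
#' @param family One of `"alkanes"`, `"alcohols"`, `"ethers"`,
#'   `"aromatics"`, `"mixed"`.
#' @param size Number of molecules requested.
#' @param max_heavy_atoms Heavy-atom budget per molecule (default 12).
#' @param seed Integer seed; only the `"mixed"` family is stochastic.
#' @return Character vector of `size` unique, valid SMILES strings.
#' @examples
#' make_corpus("alkanes", 5)
#' @export
make_corpus <- function(family, size, max_heavy_atoms = 12, seed = 1) {
  stopifnot(size >= 1, max_heavy_atoms >= 1)
  if (family != "mixed") {
    pool <- .enumerate_family(family, max_heavy_atoms)
    if (size > length(pool))
      stop(sprintf("family '%s' has only %d molecules within %d heavy atoms (%d requested)",
                   family, length(pool), max_heavy_atoms, size))
    return(pool[seq_len(size)])
  }
  # mixed: seeded random acyclic chains + ~15% aromatic-family molecules;
  # candidates are canonicalized in batches and deduplicated as molecules
  rng <- .lcg_new(seed)
  out <- character(0)
  arom <- .enumerate_family("aromatics", max_heavy_atoms = 16)
  rounds <- 0L
  while (length(out) < size && rounds < 50L) {
    rounds <- rounds + 1L
    batch <- vapply(seq_len(max(200L, size)), function(...) {
      if (.lcg_unif(rng) < 0.15 && length(arom))
        return(arom[.lcg_int(rng, length(arom))])
      n <- .lcg_int(rng, max_heavy_atoms)
      atoms <- character(n)
      prev_hetero <- TRUE  # no leading heteroatom
      for (i in seq_len(n)) {
        r <- .lcg_unif(rng)
        a <- if (prev_hetero || i == n) "C" else if (r < 0.15) "O" else if (r < 0.25) "N" else "C"
        prev_hetero <- a != "C"
        atoms[i] <- a
      }
      cand <- paste(atoms, collapse = "")
      # optional single methyl branch on an interior carbon
      if (n >= 4 && .lcg_unif(rng) < 0.35) {
        pos <- 1L + .lcg_int(rng, n - 2L)
        if (atoms[pos] == "C")
          cand <- paste0(substr(cand, 1, pos), "(C)", substr(cand, pos + 1, n))
      }
      cand
    }, character(1))
    can <- canonical_smiles(batch)
    can <- can[!is.na(can)]
    out <- c(out, setdiff(can, out))
  }
  if (length(out) < size)
    stop(sprintf("could not generate %d unique molecules (got %d)", size, length(out)))
  out[seq_len(size)]
}

# Minimal multiplicative-congruential generator so corpus generation is
# reproducible without touching R's global RNG stream.
.lcg_new <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- (as.numeric(seed) %% 2147483646) + 1
  e
}
.lcg_unif <- function(rng) {
  rng$state <- (rng$state * 48271) %% 2147483647
  rng$state / 2147483647
}
.lcg_int <- function(rng, n) 1L + as.integer(floor(.lcg_unif(rng) * n)) %% n

#' Construct a toy token-probability model
#'
#' An explicit table of conditional next-token probabilities over a small
#' symbol alphabet. Toy models expose the same decoding interface as a
#' trained checkpoint ([next_token_distribution()]), but their exact
#' sequence probabilities are computable in closed form, which makes them
#' exhaustive-enumeration oracles for the sampling module.
#'
#' @param symbols Character vector of emission symbols (END is implicit).
#' @param probs For `order = "iid"`, a named numeric vector over
#'   `c(symbols, "END")` summing to 1. For `order = "markov"`, a numeric
#'   matrix with one row per context (`"BEGIN"` plus each symbol) and one
#'   column per `c(symbols, "END")`; each row sums to 1.
#' @param order `"iid"` (context-free) or `"markov"` (first order).
#' @return An object of class `beamchem_toy` usable wherever a model
#'   checkpoint is accepted by the sampling functions.
#' @examples
#' make_toy_model(c("a", "b"), c(a = 0.5, b = 0.3, END = 0.2))
#' @export
make_toy_model <- function(symbols, probs, order = c("iid", "markov")) {
  order <- match.arg(order)
  stopifnot(is.character(symbols), length(symbols) >= 1)
  emit <- c(symbols, "END")
  if (order == "iid") {
    stopifnot(is.numeric(probs), !is.null(names(probs)))
    probs <- probs[emit]
    if (anyNA(probs) || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
      stop("iid probability vector must cover all symbols plus END and sum to 1")
    tab <- matrix(rep(probs, length(symbols) + 1L), byrow = TRUE,
                  nrow = length(symbols) + 1L,
                  dimnames = list(c("BEGIN", symbols), emit))
  } else {
    stopifnot(is.matrix(probs))
    tab <- probs[c("BEGIN", symbols), emit, drop = FALSE]
    if (anyNA(tab) || any(tab < 0) || any(abs(rowSums(tab) - 1) > 1e-9))
      stop("each context row must cover all symbols plus END and sum to 1")
  }
  vocab <- list(tokens = c(special_tokens$pad, special_tokens$begin,
                           special_tokens$end, symbols),
                index = NULL)
  vocab$index <- stats::setNames(seq_along(vocab$tokens), vocab$tokens)
  class(vocab) <- "beamchem_vocab"
  obj <- list(vocabulary = vocab, symbols = symbols, table = tab, order = order)
  class(obj) <- "beamchem_toy"
  obj
}

#' @export
next_token_distribution.beamchem_toy <- function(model, prefix, ...) {
  if (!length(prefix) || prefix[1] != special_tokens$begin)
    stop("prefix must start with BEGIN")
  if (any(prefix == special_tokens$end))
    stop("prefix must not contain END")
  last <- prefix[length(prefix)]
  ctx <- if (last == special_tokens$begin) "BEGIN" else last
  if (!(ctx %in% rownames(model$table)))
    stop(sprintf("token '%s' outside the toy model alphabet", ctx))
  row <- model$table[ctx, ]
  p <- stats::setNames(numeric(length(model$vocabulary$tokens)),
                       model$vocabulary$tokens)
  p[model$symbols] <- row[model$symbols]
  p[special_tokens$end] <- row["END"]
  p
}

#' Exhaustively enumerate completed sequences of a model
#'
#' Brute-force oracle: walks every token sequence up to `max_length`
#' emission steps, accumulating exact log-probabilities, and returns all
#' END-terminated sequences ranked by log score (ties broken
#' lexicographically by token-index sequence, matching the beam decoder's
#' tie policy). Feasible only for tiny alphabets; intended as the ground
#' truth against which beam pruning is checked.
#'
#' @param model Any model exposing [next_token_distribution()].
#' @param max_length Maximum number of emission steps (END included).
#' @return A data.frame with columns `string`, `log_score`, `probability`,
#'   sorted by decreasing `log_score`.
#' @export
enumerate_completions <- function(model, max_length) {
  vocab <- model$vocabulary
  begin <- special_tokens$begin; end <- special_tokens$end
  res_str <- character(0); res_lp <- numeric(0); res_key <- character(0)
  recurse <- function(prefix, lp, depth) {
    if (depth >= max_length) return(invisible())
    p <- next_token_distribution(model, prefix)
    for (tok in names(p)[p > 0]) {
      lp2 <- lp + log(p[[tok]])
      seq2 <- c(prefix, tok)
      if (tok == end) {
        res_str[[length(res_str) + 1L]] <<- detokenize(seq2)
        res_lp[[length(res_lp) + 1L]] <<- lp2
        res_key[[length(res_key) + 1L]] <<-
          paste(sprintf("%05d", encode_tokens(seq2, vocab)), collapse = ",")
      } else {
        recurse(seq2, lp2, depth + 1L)
      }
    }
  }
  recurse(begin, 0, 0L)
  ord <- order(-res_lp, res_key, method = "radix")
  data.frame(string = res_str[ord], log_score = res_lp[ord],
             probability = exp(res_lp[ord]), stringsAsFactors = FALSE)
}
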