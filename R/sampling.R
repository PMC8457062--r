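# Decoding: beam search (deterministic k-best generation with intrinsic
# scoring) and temperature sampling (the stochastic baseline).
#
# A hypothesis' score is the product of its stepwise conditional token
# probabilities, accumulated in log space (the raw product underflows at
# realistic SMILES lengths). No length normalization is applied by default:
# the raw product is the beam score that ranks the designs, which biases
# toward short strings; an opt-in normalized ranking is provided.
# Equal scores are broken lexicographically by token-index sequence, which
# is deterministic across platforms.

.tok_key <- function(ids) paste(sprintf("%05d", ids), collapse = ",")

#' Beam-search decoding with intrinsic scoring
#'
#' Deterministic k-best decoding. At each step every live hypothesis is
#' expanded with every token of positive probability; hypotheses extended
#' with `END` move to a completed pool (they do not consume beam slots), and
#' the `width_k` highest-scoring incomplete hypotheses survive. Decoding
#' stops when no incomplete hypothesis remains or `max_length` emission
#' steps are reached; hypotheses still alive then are truncated and
#' excluded from the results unless `keep_truncated = TRUE`.
#'
#' @param model A `beamchem_clm` checkpoint or `beamchem_toy` model.
#' @param width_k Beam width (>= 1); `width_k = 1` is greedy decoding.
#' @param max_length Maximum emission steps (END included); defaults to the
#'   model's configured maximum (60 for toy models).
#' @param length_normalize Rank by log-score divided by emission length
#'   instead of the raw log-score (default `FALSE`: the raw product of
#'   token probabilities is the beam score).
#' @param keep_truncated Also return max-length hypotheses that never
#'   emitted `END`, flagged `completed = FALSE` (default `FALSE`).
#' @param verify Re-verify every returned score by a fresh stepwise
#'   evaluation of the model (default `TRUE`).
#' @return A data.frame with columns `rank`, `string`, `log_score`,
#'   `probability`, `n_tokens` (emission steps incl. END), `completed`,
#'   sorted by decreasing score. The token sequences are attached as the
#'   `tokens` attribute (list of character vectors).
#' @export
beam_search <- function(model, width_k, max_length = NULL,
                        length_normalize = FALSE, keep_truncated = FALSE,
                        verify = TRUE) {
  if (width_k < 1) stop("beam width must be >= 1")
  if (is.null(max_length))
    max_length <- if (!is.null(model$config$max_length))
      model$config$max_length else 60L
  vocab <- model$vocabulary
  V <- length(vocab$tokens)
  end_id <- 3L
  state <- .decoder_start(model, 1L)
  live_ids <- list(integer(0))   # emitted token ids per live hypothesis
  live_lp <- 0
  pool_ids <- list(); pool_lp <- numeric(0)
  trunc_ids <- list(); trunc_lp <- numeric(0)
  for (step in seq_len(max_length)) {
    P <- .decoder_probs(model, state)
    bad <- abs(rowSums(P) - 1) > 1e-4
    if (any(bad)) stop("model emitted a non-normalized distribution")
    nl <- length(live_lp)
    cand_lp <- as.vector(log(P)) + rep(live_lp, times = V)  # column-major: (hyp, token)
    pos <- which(P > 0)
    hyp_i <- ((pos - 1L) %% nl) + 1L
    tok_j <- ((pos - 1L) %/% nl) + 1L
    lp <- cand_lp[pos]
    is_end <- tok_j == end_id
    if (any(is_end)) {
      for (w in which(is_end)) {
        pool_ids[[length(pool_ids) + 1L]] <- c(live_ids[[hyp_i[w]]], end_id)
        pool_lp <- c(pool_lp, lp[w])
      }
    }
    keep <- which(!is_end)
    if (!length(keep) || step == max_length) {
      if (step == max_length && length(keep)) {
        # survivors would exceed max_length: truncated
        sel <- .rank_select(lp[keep], live_ids, hyp_i[keep], tok_j[keep], width_k)
        for (s in sel) {
          w <- keep[s]
          trunc_ids[[length(trunc_ids) + 1L]] <- c(live_ids[[hyp_i[w]]], tok_j[w])
          trunc_lp <- c(trunc_lp, lp[w])
        }
      }
      break
    }
    sel <- .rank_select(lp[keep], live_ids, hyp_i[keep], tok_j[keep], width_k)
    w <- keep[sel]
    new_ids <- lapply(w, function(x) c(live_ids[[hyp_i[x]]], tok_j[x]))
    state <- .decoder_select(model, state, hyp_i[w])
    state <- .decoder_advance(model, state, tok_j[w])
    live_ids <- new_ids
    live_lp <- lp[w]
  }
  res <- .assemble_results(model, pool_ids, pool_lp, trunc_ids, trunc_lp,
                           keep_truncated, length_normalize)
  if (verify && nrow(res)) {
    toks <- attr(res, "tokens")
    for (r in which(res$completed)) {
      chk <- beam_score(model, toks[[r]])
      if (!is.finite(chk) || abs(chk - res$log_score[r]) > 1e-9)
        stop("internal error: beam score failed stepwise re-verification")
    }
  }
  res
}

# order candidate expansions by descending score, ties lexicographic on the
# full token-id sequence, and return the indices of the best k
.rank_select <- function(lp, live_ids, hyp_i, tok_j, k) {
  keys <- vapply(seq_along(lp), function(x)
    .tok_key(c(live_ids[[hyp_i[x]]], tok_j[x])), character(1))
  ord <- order(-lp, keys, method = "radix")
  ord[seq_len(min(k, length(ord)))]
}

.assemble_results <- function(model, pool_ids, pool_lp, trunc_ids, trunc_lp,
                              keep_truncated, length_normalize) {
  vocab <- model$vocabulary
  ids <- pool_ids; lp <- pool_lp
  completed <- rep(TRUE, length(pool_lp))
  if (keep_truncated) {
    ids <- c(ids, trunc_ids); lp <- c(lp, trunc_lp)
    completed <- c(completed, rep(FALSE, length(trunc_lp)))
  }
  if (!length(ids)) {
    out <- data.frame(rank = integer(0), string = character(0),
                      log_score = numeric(0), probability = numeric(0),
                      n_tokens = integer(0), completed = logical(0))
    attr(out, "tokens") <- list()
    return(out)
  }
  keys <- vapply(ids, .tok_key, character(1))
  lens <- lengths(ids)
  score <- if (length_normalize) lp / lens else lp
  ord <- order(-completed, -score, keys, method = "radix")
  toks <- lapply(ids[ord], function(v)
    c(special_tokens$begin, vocab$tokens[v]))
  strings <- vapply(toks, function(tt) {
    if (tt[length(tt)] == special_tokens$end) detokenize(tt)
    else paste(tt[-1], collapse = "")
  }, character(1))
  out <- data.frame(rank = seq_along(ord), string = strings,
                    log_score = lp[ord], probability = exp(lp[ord]),
                    n_tokens = lens[ord], completed = completed[ord],
                    stringsAsFactors = FALSE)
  attr(out, "tokens") <- toks
  out
}

#' Beam score of a complete token sequence
#'
#' The log-probability of a complete sequence under the model: the sum over
#' steps of the log conditional probability of each emitted token
#' (log-domain product). `exp()` of the result is the sequence probability.
#'
#' @param model A `beamchem_clm` or `beamchem_toy` model.
#' @param tokens Character vector `BEGIN, ..., END` (e.g. from
#'   [tokenize()]).
#' @return The log-score (`-Inf` if any step has zero probability).
#' @export
beam_score <- function(model, tokens) {
  n <- length(tokens)
  if (n < 2 || tokens[1] != special_tokens$begin ||
      tokens[n] != special_tokens$end)
    stop("sequence must run BEGIN ... END")
  body <- tokens[-c(1, n)]
  if (any(body %in% unlist(special_tokens)))
    stop("special token inside the sequence body")
  ids <- encode_tokens(tokens, model$vocabulary)  # errors on unknown tokens
  st <- .decoder_start(model, 1L)
  lp <- 0
  for (t in 2:n) {
    p <- unname(.decoder_probs(model, st)[1, tokens[t]])
    if (!is.finite(p) || p <= 0) return(-Inf)
    lp <- lp + log(p)
    if (t < n) st <- .decoder_advance(model, st, ids[t])
  }
  lp
}

#' Temperature sampling from the model
#'
#' Stochastic baseline decoding: sequences are grown token by token, each
#' token drawn from the model distribution sharpened by `1/temperature`
#' (probabilities proportional to `p^(1/T)`). Low temperatures concentrate
#' on the most likely token (the `T -> 0` limit reproduces greedy
#' decoding); `T = 1` samples from the model distribution itself.
#'
#' @param model A `beamchem_clm` or `beamchem_toy` model.
#' @param num_samples Number of sequences to draw.
#' @param temperature Positive sampling temperature (default 1).
#' @param max_length Maximum emission steps; sequences reaching it without
#'   `END` are returned flagged `truncated = TRUE`.
#' @param seed Integer seed; a fixed seed reproduces the sample list.
#' @return A data.frame with columns `string`, `log_score`, `truncated`.
#' @export
temperature_sample <- function(model, num_samples, temperature = 1,
                               max_length = NULL, seed = 1) {
  stopifnot(num_samples >= 1, temperature > 0)
  if (is.null(max_length))
    max_length <- if (!is.null(model$config$max_length))
      model$config$max_length else 60L
  end_id <- 3L
  out_ids <- vector("list", num_samples)
  out_lp <- numeric(num_samples)
  out_trunc <- rep(TRUE, num_samples)
  .with_seed(seed, {
    state <- .decoder_start(model, num_samples)
    alive <- seq_len(num_samples)
    acc <- lapply(seq_len(num_samples), function(i) integer(0))
    lp <- numeric(num_samples)
    for (step in seq_len(max_length)) {
      P <- .decoder_probs(model, state)
      lw <- log(P) / temperature
      mx <- apply(lw, 1, max)
      W <- exp(lw - mx)
      W <- W / rowSums(W)
      u <- stats::runif(length(alive))
      cum <- t(apply(W, 1, cumsum))
      tok <- rowSums(cum < u) + 1L
      tok <- pmin(tok, ncol(P))
      for (r in seq_along(alive)) {
        i <- alive[r]
        acc[[i]] <- c(acc[[i]], tok[r])
        lp[i] <- lp[i] + log(P[r, tok[r]])
      }
      done <- tok == end_id
      if (any(done)) {
        for (i in alive[done]) {
          out_ids[[i]] <- acc[[i]]; out_lp[i] <- lp[i]; out_trunc[i] <- FALSE
        }
      }
      if (all(done)) { alive <- integer(0); break }
      keep <- which(!done)
      state <- .decoder_advance(model,
                                .decoder_select(model, state, keep),
                                tok[keep])
      alive <- alive[keep]
    }
    for (i in alive) { out_ids[[i]] <- acc[[i]]; out_lp[i] <- lp[i] }
  })
  vocab <- model$vocabulary
  strings <- vapply(seq_len(num_samples), function(i) {
    v <- vocab$tokens[out_ids[[i]]]
    if (!out_trunc[i]) v <- v[-length(v)]
    paste(v, collapse = "")
  }, character(1))
  data.frame(string = strings, log_score = out_lp, truncated = out_trunc,
             stringsAsFactors = FALSE)
}
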