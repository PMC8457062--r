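# Recurrent (LSTM) next-token language model over SMILES tokens.
#
# The model is implemented directly as vectorized matrix code: batched
# teacher-forcing forward pass, truncated-free full backpropagation through
# time, and Adam updates. Gates use the usual parameterization
#   z = [x, h] W + b,  z -> (i, f, g, o),  c' = f*c + i*g,  h' = o*tanh(c'),
# with a +1 forget-gate bias at initialization. The training objective is
# the mean per-token cross-entropy (nats) of the next-token prediction.
# Gradients are verified against finite differences in the test suite.

.sigm <- function(x) 1 / (1 + exp(-x))

#' Language-model configuration
#'
#' @param vocab_size Number of tokens in the vocabulary (incl. specials).
#' @param embedding_dim Token embedding width (default 64).
#' @param hidden_units LSTM hidden width per layer (default 256; tests and
#'   desk-scale runs typically use 64).
#' @param num_layers Number of stacked LSTM layers (default 2).
#' @param learning_rate Adam step size (default 0.005).
#' @param batch_size Sequences per update (default 32).
#' @param max_length Maximum emission steps per sequence; longer training
#'   sequences are skipped, and decoding stops here (default 140).
#' @param seed Integer seed fixing weight initialization and shuffling.
#' @return A list of class `beamchem_config`.
#' @export
clm_config <- function(vocab_size, embedding_dim = 64, hidden_units = 256,
                       num_layers = 2, learning_rate = 0.005,
                       batch_size = 32, max_length = 140, seed = 1) {
  stopifnot(vocab_size >= 4, embedding_dim >= 1, hidden_units >= 1,
            num_layers >= 1, learning_rate > 0, batch_size >= 1,
            max_length >= 2)
  structure(list(vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 hidden_units = as.integer(hidden_units),
                 num_layers = as.integer(num_layers),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_length = as.integer(max_length),
                 seed = as.integer(seed)),
            class = "beamchem_config")
}

#' Full-scale run parameters of the published design campaign
#'
#' Documentation constants for a full-scale campaign: pre-training on
#' 365,063 bioactive molecules for 10 epochs, a first fine-tuning stage of
#' 20 epochs on 255 target ligands, a second stage of 16 epochs on 4
#' natural-product modulators, with beam sampling over fine-tuning epochs
#' 5-16 and 1024-bit radius-2 Morgan fingerprints for evaluation. The
#' package's tests and examples run scaled-down analogues of this protocol
#' on synthetic corpora.
#'
#' @return A named list of the full-scale constants.
#' @export
full_scale_defaults <- function() {
  list(pretrain_molecules = 365063L, pretrain_epochs = 10L,
       stage1_molecules = 255L, stage1_epochs = 20L,
       stage2_molecules = 4L, stage2_epochs = 16L,
       sample_window = c(5L, 16L),
       fingerprint_bits = 1024L, fingerprint_radius = 2L)
}

# ---- parameter initialization ------------------------------------------

.init_params <- function(config) {
  V <- config$vocab_size; E <- config$embedding_dim
  H <- config$hidden_units; L <- config$num_layers
  runifm <- function(nr, nc, s = 0.08) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    din <- if (l == 1) E else H
    W[[l]] <- runifm(din + H, 4 * H)
    b[[l]] <- numeric(4 * H)
    b[[l]][(H + 1):(2 * H)] <- 1  # forget-gate bias
  }
  list(E = runifm(V, E), W = W, b = b, Wy = runifm(H, V), by = numeric(V))
}

# flatten/unflatten for the optimizer and finite-difference checks
.flatten <- function(p) {
  out <- list(E = p$E, Wy = p$Wy, by = p$by)
  for (l in seq_along(p$W)) {
    out[[paste0("W", l)]] <- p$W[[l]]
    out[[paste0("b", l)]] <- p$b[[l]]
  }
  out
}
.unflatten <- function(f, L) {
  p <- list(E = f$E, W = vector("list", L), b = vector("list", L),
            Wy = f$Wy, by = f$by)
  for (l in seq_len(L)) {
    p$W[[l]] <- f[[paste0("W", l)]]
    p$b[[l]] <- f[[paste0("b", l)]]
  }
  p
}

# ---- batched forward / backward ----------------------------------------

# inputs, targets: B x T integer matrices (PAD-padded); returns loss and,
# if grad=TRUE, gradients in the same shape as params.
.clm_batch <- function(params, config, inputs, targets, grad = TRUE) {
  B <- nrow(inputs); Tn <- ncol(inputs)
  H <- config$hidden_units; L <- config$num_layers
  V <- config$vocab_size
  pad <- 1L
  mask <- targets != pad
  ntok <- sum(mask)
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); oo <- (3 * H + 1):(4 * H)

  Hs <- vector("list", L); Cs <- vector("list", L)   # states per layer/time
  Gz <- vector("list", L)                            # post-activation gates
  Xin <- vector("list", L)                           # layer inputs per time
  for (l in seq_len(L)) {
    Hs[[l]] <- vector("list", Tn + 1L); Cs[[l]] <- vector("list", Tn + 1L)
    Hs[[l]][[1]] <- matrix(0, B, H); Cs[[l]][[1]] <- matrix(0, B, H)
    Gz[[l]] <- vector("list", Tn); Xin[[l]] <- vector("list", Tn)
  }
  loss <- 0
  dlogits_store <- if (grad) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    x <- params$E[inputs[, t], , drop = FALSE]
    for (l in seq_len(L)) {
      Xin[[l]][[t]] <- x
      z <- cbind(x, Hs[[l]][[t]]) %*% params$W[[l]]
      z <- sweep(z, 2, params$b[[l]], "+")
      gi <- .sigm(z[, ii, drop = FALSE]); gf <- .sigm(z[, ff, drop = FALSE])
      gg_ <- tanh(z[, gg, drop = FALSE]); go <- .sigm(z[, oo, drop = FALSE])
      cnew <- gf * Cs[[l]][[t]] + gi * gg_
      hnew <- go * tanh(cnew)
      Gz[[l]][[t]] <- list(i = gi, f = gf, g = gg_, o = go)
      Cs[[l]][[t + 1L]] <- cnew; Hs[[l]][[t + 1L]] <- hnew
      x <- hnew
    }
    logits <- sweep(x %*% params$Wy, 2, params$by, "+")
    logits <- logits - apply(logits, 1, max)
    P <- exp(logits); P <- P / rowSums(P)
    m <- mask[, t]
    if (any(m)) {
      idx <- cbind(which(m), targets[m, t])
      loss <- loss - sum(log(pmax(P[idx], 1e-300)))
    }
    if (grad) {
      Y <- matrix(0, B, V)
      if (any(m)) Y[cbind(which(m), targets[m, t])] <- 1
      dl <- (P - Y) * (m / ntok)
      dlogits_store[[t]] <- dl
    }
  }
  loss <- loss / ntok
  if (!grad) return(list(loss = loss))

  g <- list(E = matrix(0, V, config$embedding_dim),
            W = lapply(params$W, function(w) w * 0),
            b = lapply(params$b, function(bb) bb * 0),
            Wy = params$Wy * 0, by = params$by * 0)
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  for (t in rev(seq_len(Tn))) {
    dl <- dlogits_store[[t]]
    htop <- Hs[[L]][[t + 1L]]
    g$Wy <- g$Wy + t(htop) %*% dl
    g$by <- g$by + colSums(dl)
    dx_above <- dl %*% t(params$Wy)
    for (l in rev(seq_len(L))) {
      dh <- dh_next[[l]] + dx_above
      ga <- Gz[[l]][[t]]
      cnew <- Cs[[l]][[t + 1L]]; tc <- tanh(cnew)
      dc <- dc_next[[l]] + dh * ga$o * (1 - tc^2)
      dgo <- dh * tc
      dgi <- dc * ga$g
      dgg <- dc * ga$i
      dgf <- dc * Cs[[l]][[t]]
      dz <- cbind(dgi * ga$i * (1 - ga$i),
                  dgf * ga$f * (1 - ga$f),
                  dgg * (1 - ga$g^2),
                  dgo * ga$o * (1 - ga$o))
      xcat <- cbind(Xin[[l]][[t]], Hs[[l]][[t]])
      g$W[[l]] <- g$W[[l]] + t(xcat) %*% dz
      g$b[[l]] <- g$b[[l]] + colSums(dz)
      dxcat <- dz %*% t(params$W[[l]])
      din <- ncol(Xin[[l]][[t]])
      dx_above <- dxcat[, seq_len(din), drop = FALSE]
      dh_next[[l]] <- dxcat[, (din + 1):(din + H), drop = FALSE]
      dc_next[[l]] <- dc * ga$f
    }
    # dx_above now holds the embedding gradient for time t
    agg <- rowsum(dx_above, group = inputs[, t])
    rows <- as.integer(rownames(agg))
    g$E[rows, ] <- g$E[rows, , drop = FALSE] + agg
  }
  list(loss = loss, grad = g)
}

# ---- Adam ---------------------------------------------------------------

.adam_new <- function(params) {
  f <- .flatten(params)
  list(m = lapply(f, function(x) x * 0), v = lapply(f, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 5) {
  fp <- .flatten(params); fg <- .flatten(grads)
  gnorm <- sqrt(sum(vapply(fg, function(x) sum(x^2), numeric(1))))
  if (gnorm > clip) fg <- lapply(fg, function(x) x * (clip / gnorm))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(fp)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * fg[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * fg[[k]]^2
    fp[[k]] <- fp[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  L <- length(params$W)
  list(params = .unflatten(fp, L), state = state)
}

# ---- training -----------------------------------------------------------

.encode_corpus <- function(corpus, vocab, max_length) {
  seqs <- lapply(corpus, function(s) encode_tokens(tokenize(s), vocab))
  keep <- vapply(seqs, function(x) length(x) - 1L <= max_length, logical(1))
  list(seqs = seqs[keep], skipped = sum(!keep))
}

.make_batch <- function(seqs, idx) {
  lens <- vapply(seqs[idx], length, integer(1))
  Tn <- max(lens) - 1L
  B <- length(idx)
  inputs <- matrix(1L, B, Tn); targets <- matrix(1L, B, Tn)  # PAD = 1
  for (r in seq_along(idx)) {
    s <- seqs[[idx[r]]]; n <- length(s)
    inputs[r, seq_len(n - 1L)] <- s[-n]
    targets[r, seq_len(n - 1L)] <- s[-1L]
  }
  list(inputs = inputs, targets = targets)
}

# run body with a locally-seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Train or fine-tune the chemical language model
#'
#' Teacher-forced training of the LSTM next-token model. One epoch is one
#' full pass over the corpus. When `init` is given, training continues from
#' that checkpoint (transfer learning / fine-tuning); the vocabulary is
#' frozen to the initial checkpoint's, and a corpus containing tokens
#' outside it is an error (the vocabulary is never silently extended).
#'
#' @param corpus Character vector of SMILES strings.
#' @param epochs Number of passes over the corpus (>= 1).
#' @param config A [clm_config()]; ignored (taken from the checkpoint) when
#'   `init` is given.
#' @param init Optional `beamchem_clm` checkpoint to fine-tune from.
#' @param stage_label Label recorded in the returned checkpoints.
#' @param vocab Optional pre-built vocabulary for pre-training; by default
#'   it is built from `corpus`.
#' @param keep_epochs Integer vector of epochs whose checkpoints to retain
#'   (default all). The final epoch is always retained.
#' @param checkpoint_dir Optional directory; when given, every epoch's
#'   checkpoint is written there as `<stage_label>_epoch_NNN.rds` and a
#'   training log `<stage_label>_log.csv` is written alongside.
#' @param verbose Print per-epoch loss.
#' @return A list of class `beamchem_fit`: `checkpoints` (named list,
#'   `epoch_N`), `final` (last checkpoint), `log` (data.frame epoch/loss),
#'   `skipped` (sequences dropped for exceeding `max_length`).
#' @export
train_clm <- function(corpus, epochs, config = NULL, init = NULL,
                      stage_label = if (is.null(init)) "pretrain" else "finetune",
                      vocab = NULL, keep_epochs = NULL, checkpoint_dir = NULL,
                      verbose = FALSE) {
  stopifnot(length(corpus) >= 1, epochs >= 1)
  if (!is.null(init)) {
    stopifnot(inherits(init, "beamchem_clm"))
    config <- init$config
    vocab <- init$vocabulary
    novel <- setdiff(unique(unlist(lapply(corpus, tokenize))), vocab$tokens)
    if (length(novel))
      stop(sprintf("fine-tuning corpus contains tokens absent from the model vocabulary: %s",
                   paste(novel, collapse = ", ")))
    params <- init$params
  } else {
    if (is.null(vocab)) vocab <- build_vocabulary(corpus)
    if (is.null(config)) config <- clm_config(vocab_size = length(vocab$tokens))
    if (config$vocab_size != length(vocab$tokens))
      stop("config vocab_size does not match the vocabulary")
    params <- .with_seed(config$seed, .init_params(config))
  }
  enc <- .encode_corpus(corpus, vocab, config$max_length)
  if (!length(enc$seqs)) stop("no trainable sequences within max_length")
  n <- length(enc$seqs)
  opt <- .adam_new(params)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  checkpoints <- list()
  base_epoch <- if (is.null(init)) 0L else init$epoch
  for (ep in seq_len(epochs)) {
    ord <- .with_seed(config$seed + 7919L * ep, sample.int(n))
    tot_loss <- 0; tot_tok <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      bt <- .make_batch(enc$seqs, idx)
      res <- .clm_batch(params, config, bt$inputs, bt$targets, grad = TRUE)
      ntok <- sum(bt$targets != 1L)
      tot_loss <- tot_loss + res$loss * ntok; tot_tok <- tot_tok + ntok
      upd <- .adam_step(params, res$grad, opt, config$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    mean_loss <- tot_loss / tot_tok
    log <- rbind(log, data.frame(epoch = ep, loss = mean_loss))
    if (verbose) message(sprintf("[%s] epoch %d  loss %.4f", stage_label, ep, mean_loss))
    ckpt <- structure(list(config = config, params = params,
                           stage_label = stage_label, epoch = ep,
                           vocabulary = vocab, train_loss = mean_loss),
                      class = "beamchem_clm")
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(ckpt, file.path(checkpoint_dir,
                              sprintf("%s_epoch_%03d.rds", stage_label, ep)))
    }
    if (is.null(keep_epochs) || ep %in% keep_epochs || ep == epochs)
      checkpoints[[paste0("epoch_", ep)]] <- ckpt
  }
  if (!is.null(checkpoint_dir))
    utils::write.csv(log, file.path(checkpoint_dir,
                                    paste0(stage_label, "_log.csv")),
                     row.names = FALSE)
  structure(list(checkpoints = checkpoints,
                 final = checkpoints[[paste0("epoch_", epochs)]],
                 log = log, skipped = enc$skipped, base_epoch = base_epoch),
            class = "beamchem_fit")
}

#' @export
print.beamchem_clm <- function(x, ...) {
  cat(sprintf("CLM checkpoint: stage '%s', epoch %d, |V|=%d, %d x %d LSTM\n",
              x$stage_label, x$epoch, x$config$vocab_size,
              x$config$num_layers, x$config$hidden_units))
  invisible(x)
}

#' @export
print.beamchem_fit <- function(x, ...) {
  cat(sprintf("CLM fit: %d epochs, final loss %.4f (%d sequences skipped)\n",
              nrow(x$log), x$log$loss[nrow(x$log)], x$skipped))
  invisible(x)
}

#' Mean per-token log-likelihood of SMILES under a checkpoint
#'
#' Evaluates the model's teacher-forced log-likelihood on held-out strings,
#' the quantity transfer learning is expected to raise for molecules of the
#' fine-tuning family.
#'
#' @param model A `beamchem_clm` checkpoint.
#' @param smiles Character vector of SMILES strings.
#' @return Mean log-likelihood per token (nats; higher is better).
#' @export
corpus_log_likelihood <- function(model, smiles) {
  stopifnot(inherits(model, "beamchem_clm"))
  enc <- .encode_corpus(smiles, model$vocabulary, model$config$max_length)
  if (!length(enc$seqs)) stop("no sequences to evaluate")
  bt <- .make_batch(enc$seqs, seq_along(enc$seqs))
  -.clm_batch(model$params, model$config, bt$inputs, bt$targets, grad = FALSE)$loss
}

# ---- decoding interface -------------------------------------------------

# Stateful batched decoder: state carries per-layer (h, c) for n parallel
# sequences. .decoder_probs returns the next-token distribution(s) given
# everything consumed so far; PAD and BEGIN are masked to zero probability
# and the row renormalized.

.decoder_start <- function(model, n) UseMethod(".decoder_start")
.decoder_advance <- function(model, state, tok_ids) UseMethod(".decoder_advance")
.decoder_probs <- function(model, state) UseMethod(".decoder_probs")
.decoder_select <- function(model, state, idx) UseMethod(".decoder_select")

.decoder_start.beamchem_clm <- function(model, n) {
  H <- model$config$hidden_units; L <- model$config$num_layers
  st <- list(h = lapply(seq_len(L), function(l) matrix(0, n, H)),
             c = lapply(seq_len(L), function(l) matrix(0, n, H)))
  .decoder_advance(model, st, rep(2L, n))  # consume BEGIN (id 2)
}

.decoder_advance.beamchem_clm <- function(model, state, tok_ids) {
  p <- model$params; H <- model$config$hidden_units
  x <- p$E[tok_ids, , drop = FALSE]
  for (l in seq_along(p$W)) {
    z <- cbind(x, state$h[[l]]) %*% p$W[[l]]
    z <- sweep(z, 2, p$b[[l]], "+")
    gi <- .sigm(z[, 1:H, drop = FALSE])
    gf <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    go <- .sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cnew <- gf * state$c[[l]] + gi * gg
    state$c[[l]] <- cnew
    state$h[[l]] <- go * tanh(cnew)
    x <- state$h[[l]]
  }
  state
}

.decoder_probs.beamchem_clm <- function(model, state) {
  p <- model$params
  L <- length(p$W)
  logits <- sweep(state$h[[L]] %*% p$Wy, 2, p$by, "+")
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits); P <- P / rowSums(P)
  P[, c(1L, 2L)] <- 0              # PAD, BEGIN masked at decode time
  P <- P / rowSums(P)
  colnames(P) <- model$vocabulary$tokens
  P
}

.decoder_select.beamchem_clm <- function(model, state, idx) {
  list(h = lapply(state$h, function(m) m[idx, , drop = FALSE]),
       c = lapply(state$c, function(m) m[idx, , drop = FALSE]))
}

# toy models: state is the vector of current context symbols
.decoder_start.beamchem_toy <- function(model, n) rep("BEGIN", n)
.decoder_advance.beamchem_toy <- function(model, state, tok_ids) {
  model$vocabulary$tokens[tok_ids]
}
.decoder_probs.beamchem_toy <- function(model, state) {
  V <- model$vocabulary$tokens
  P <- matrix(0, length(state), length(V), dimnames = list(NULL, V))
  rows <- model$table[state, , drop = FALSE]
  P[, model$symbols] <- rows[, model$symbols, drop = FALSE]
  P[, special_tokens$end] <- rows[, "END"]
  P
}
.decoder_select.beamchem_toy <- function(model, state, idx) state[idx]

#' Next-token conditional distribution
#'
#' The probability of every vocabulary token given a prefix, under a trained
#' checkpoint or a toy model. `PAD` and `BEGIN` have probability zero at
#' decode time. Deterministic for a fixed model.
#'
#' @param model A `beamchem_clm` checkpoint or `beamchem_toy` model.
#' @param prefix Character vector of tokens starting with `BEGIN` and
#'   containing no `END`.
#' @param ... Unused.
#' @return Named numeric vector over the vocabulary, summing to 1.
#' @export
next_token_distribution <- function(model, prefix, ...) {
  UseMethod("next_token_distribution")
}

#' @export
next_token_distribution.beamchem_clm <- function(model, prefix, ...) {
  if (!length(prefix) || prefix[1] != special_tokens$begin)
    stop("prefix must start with BEGIN")
  if (any(prefix == special_tokens$end))
    stop("prefix must not contain END")
  if (length(prefix) > model$config$max_length + 1L)
    stop(sprintf("prefix exceeds the model's maximum length (%d)",
                 model$config$max_length))
  st <- .decoder_start(model, 1L)
  body <- prefix[-1]
  if (length(body))
    for (tok in body)
      st <- .decoder_advance(model, st, encode_tokens(tok, model$vocabulary))
  p <- .decoder_probs(model, st)[1, ]
  p
}
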