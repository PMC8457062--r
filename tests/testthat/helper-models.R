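# Shared fixtures: toy models and small trained checkpoints, built once per
# test run.

iid_toy <- function() make_toy_model(c("a", "b"), c(a = 0.5, b = 0.3, END = 0.2))

# seeded random iid/markov toy models over small alphabets
random_toy <- function(seed, n_symbols = 3, order = "iid", min_end = 0.1) {
  set.seed(seed)
  syms <- letters[seq_len(n_symbols)]
  draw_row <- function() {
    p <- stats::runif(n_symbols + 1) + 0.05
    p <- p / sum(p)
    # guarantee a decent END mass so enumeration converges quickly
    p[n_symbols + 1] <- max(p[n_symbols + 1], min_end)
    p / sum(p)
  }
  if (order == "iid") {
    probs <- stats::setNames(draw_row(), c(syms, "END"))
    make_toy_model(syms, probs)
  } else {
    tab <- t(vapply(seq_len(n_symbols + 1), function(i) draw_row(),
                    numeric(n_symbols + 1)))
    dimnames(tab) <- list(c("BEGIN", syms), c(syms, "END"))
    make_toy_model(syms, tab, order = "markov")
  }
}

# stepwise argmax walk (END included), the reference for greedy decoding
greedy_walk <- function(model, max_length) {
  prefix <- special_tokens$begin
  for (step in seq_len(max_length)) {
    p <- next_token_distribution(model, prefix)
    nxt <- names(p)[which.max(p)]
    prefix <- c(prefix, nxt)
    if (nxt == special_tokens$end)
      return(list(string = detokenize(prefix), tokens = prefix,
                  truncated = FALSE))
  }
  list(string = paste(prefix[-1], collapse = ""), tokens = prefix,
       truncated = TRUE)
}

# small overfit checkpoint on 5 distinct SMILES, cached for the session
memorization_strings <- c("CCO", "CCC", "COC", "OCCO", "CCCCC")

overfit_checkpoint <- local({
  ckpt <- NULL
  function() {
    if (is.null(ckpt)) {
      vocab <- build_vocabulary(memorization_strings)
      cfg <- clm_config(vocab_size = length(vocab$tokens),
                        embedding_dim = 16, hidden_units = 64,
                        num_layers = 2, batch_size = 5,
                        learning_rate = 0.01, max_length = 30, seed = 1)
      fit <- train_clm(memorization_strings, epochs = 400, config = cfg,
                       keep_epochs = 400)
      ckpt <<- fit$final
    }
    ckpt
  }
})
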