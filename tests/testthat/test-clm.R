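# The LSTM is authored in-package, so its backward pass is verified against
# a finite-difference oracle before any behavioural test relies on it.

test_that("analytic gradients match finite differences", {
  corpus <- c("CCO", "CCC", "COC")
  vocab <- build_vocabulary(corpus)
  cfg <- clm_config(length(vocab$tokens), embedding_dim = 5, hidden_units = 7,
                    num_layers = 2, batch_size = 3, max_length = 20, seed = 3)
  params <- beamchem:::.with_seed(3, beamchem:::.init_params(cfg))
  enc <- beamchem:::.encode_corpus(corpus, vocab, 20)
  bt <- beamchem:::.make_batch(enc$seqs, 1:3)
  res <- beamchem:::.clm_batch(params, cfg, bt$inputs, bt$targets, grad = TRUE)
  fp <- beamchem:::.flatten(params)
  fg <- beamchem:::.flatten(res$grad)
  eps <- 1e-6
  set.seed(99)
  for (k in names(fp)) {
    for (j in sample(length(fp[[k]]), min(6, length(fp[[k]])))) {
      p2 <- fp
      p2[[k]][j] <- p2[[k]][j] + eps
      lp <- beamchem:::.clm_batch(beamchem:::.unflatten(p2, 2), cfg,
                                  bt$inputs, bt$targets, grad = FALSE)$loss
      p2[[k]][j] <- p2[[k]][j] - 2 * eps
      lm <- beamchem:::.clm_batch(beamchem:::.unflatten(p2, 2), cfg,
                                  bt$inputs, bt$targets, grad = FALSE)$loss
      expect_equal(fg[[k]][j], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  corpus <- make_corpus("ethers", 10)
  vocab <- build_vocabulary(corpus)
  cfg <- clm_config(length(vocab$tokens), embedding_dim = 8, hidden_units = 16,
                    num_layers = 1, batch_size = 4, max_length = 20, seed = 42)
  f1 <- train_clm(corpus, epochs = 2, config = cfg)
  f2 <- train_clm(corpus, epochs = 2, config = cfg)
  expect_identical(f1$log$loss, f2$log$loss)
  prefix <- tokenize("CCOC")[1:4]
  expect_identical(next_token_distribution(f1$final, prefix),
                   next_token_distribution(f2$final, prefix))
})

test_that("training loss decreases over epochs on a fixture corpus", {
  corpus <- make_corpus("mixed", 60, seed = 11)
  vocab <- build_vocabulary(corpus)
  cfg <- clm_config(length(vocab$tokens), embedding_dim = 16, hidden_units = 32,
                    num_layers = 2, batch_size = 16, learning_rate = 0.01,
                    max_length = 40, seed = 5)
  fit <- train_clm(corpus, epochs = 10, config = cfg, keep_epochs = c(1, 10))
  expect_lt(fit$log$loss[10], fit$log$loss[1])
})

test_that("an overfit model approaches the memorization loss bound and recalls its corpus", {
  ckpt <- overfit_checkpoint()
  # a model that memorizes n equiprobable strings cannot do better than
  # -log(1/n) per sequence, spread over the total target tokens
  n <- length(memorization_strings)
  total_tokens <- sum(vapply(memorization_strings,
                             function(s) length(tokenize(s)) - 1L, integer(1)))
  bound <- n * log(n) / total_tokens
  expect_lt(ckpt$train_loss, bound + 0.05)
  expect_gt(ckpt$train_loss, bound - 1e-3)

  # a prefix unique to one training string forces that string's next token
  prefix <- tokenize("OCCO")[1:3]  # "OC" is unique to OCCO
  p <- next_token_distribution(ckpt, prefix)
  expect_identical(names(which.max(p)), "C")
})

test_that("next-token distributions are normalized and mask specials", {
  ckpt <- overfit_checkpoint()
  set.seed(7)
  for (i in 1:20) {
    s <- memorization_strings[sample(5, 1)]
    toks <- tokenize(s)
    cut <- sample(length(toks) - 1L, 1)
    p <- next_token_distribution(ckpt, toks[seq_len(cut)])
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_identical(unname(p[special_tokens$pad]), 0)
    expect_identical(unname(p[special_tokens$begin]), 0)
    expect_true(all(p >= 0))
  }
  expect_error(next_token_distribution(ckpt, c("C", "C")), "BEGIN")
  expect_error(next_token_distribution(ckpt, tokenize("CCO")), "END")
})

test_that("fine-tuning refuses corpora with novel tokens", {
  ckpt <- overfit_checkpoint()
  expect_error(train_clm(c("CCS"), epochs = 1, init = ckpt), "S")
  expect_error(train_clm(c("c1ccccc1"), epochs = 1, init = ckpt),
               "absent from the model vocabulary")
})

test_that("fine-tuning raises the likelihood of the fine-tuning family", {
  pre <- make_corpus("mixed", 120, seed = 21)
  vocab <- build_vocabulary(pre)
  cfg <- clm_config(length(vocab$tokens), embedding_dim = 16, hidden_units = 32,
                    num_layers = 2, batch_size = 16, learning_rate = 0.01,
                    max_length = 40, seed = 2)
  base <- train_clm(pre, epochs = 6, config = cfg, keep_epochs = 6)$final
  fam <- make_corpus("aromatics", 16, max_heavy_atoms = 14)
  ft <- train_clm(fam[1:8], epochs = 8, init = base, keep_epochs = 8)$final
  held_out <- fam[9:16]
  expect_gt(corpus_log_likelihood(ft, held_out),
            corpus_log_likelihood(base, held_out))
})

test_that("checkpoints written to disk restore identical distributions", {
  ckpt <- overfit_checkpoint()
  dir <- withr::local_tempdir()
  fit <- train_clm(memorization_strings, epochs = 2, init = ckpt,
                   stage_label = "resume", checkpoint_dir = dir)
  path <- file.path(dir, "resume_epoch_002.rds")
  expect_true(file.exists(path))
  restored <- readRDS(path)
  prefix <- tokenize("CCO")[1:3]
  expect_identical(next_token_distribution(restored, prefix),
                   next_token_distribution(fit$final, prefix))
  log <- utils::read.csv(file.path(dir, "resume_log.csv"))
  expect_identical(log$epoch, 1:2)
})
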