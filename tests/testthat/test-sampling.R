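# Beam search is checked against exhaustive enumeration: on toy models small
# enough to enumerate, a wide-enough beam must reproduce the true k-best
# ranking exactly, and narrower beams must return order-consistent subsets.

test_that("the worked two-symbol example ranks as the closed-form products", {
  toy <- iid_toy()
  bs <- beam_search(toy, width_k = 2, max_length = 3)
  expect_identical(bs$string[1:3], c("", "a", "b"))
  expect_equal(bs$probability[1:3], c(0.2, 0.10, 0.06))
  expect_equal(bs$log_score, sort(bs$log_score, decreasing = TRUE))
  en <- enumerate_completions(toy, 3)
  m <- match(bs$string, en$string)
  expect_false(anyNA(m))
  expect_equal(bs$log_score, en$log_score[m], tolerance = 1e-12)
})

test_that("a wide beam reproduces the exhaustive enumeration ranking", {
  for (seed in 1:8) {
    toy <- random_toy(seed, n_symbols = 2 + seed %% 2,
                      order = if (seed %% 2) "iid" else "markov")
    depth <- 4 + seed %% 3
    en <- enumerate_completions(toy, depth)
    bs <- beam_search(toy, width_k = nrow(en), max_length = depth)
    expect_identical(bs$string, en$string)
    expect_equal(bs$log_score, en$log_score, tolerance = 1e-9)
  }
})

test_that("narrow beams return order-consistent, identically-scored subsets", {
  for (seed in c(2, 9)) {
    toy <- random_toy(seed, n_symbols = 3,
                      order = if (seed %% 2) "iid" else "markov")
    en <- enumerate_completions(toy, 5)
    for (k in c(1, 2, 4)) {
      bs <- beam_search(toy, width_k = k, max_length = 5)
      m <- match(bs$string, en$string)
      expect_false(anyNA(m))
      expect_identical(m, sort(m))   # pruning removes, never reorders
      expect_equal(bs$log_score, en$log_score[m], tolerance = 1e-9)
    }
  }
})

test_that("width-1 beam follows the greedy argmax trajectory", {
  # completed hypotheses are archived rather than competing for beam slots,
  # so the k=1 beam's live path is the argmax over continuation tokens and
  # the greedy string (when it terminates) is always in the returned pool
  # with its exact stepwise score
  for (seed in c(4, 6)) {
    toy <- random_toy(seed, n_symbols = 3, order = "markov")
    g <- greedy_walk(toy, 8)
    bs <- beam_search(toy, width_k = 1, max_length = 8)
    if (!g$truncated) {
      m <- match(g$string, bs$string)
      expect_false(anyNA(m))
      expect_equal(bs$log_score[m], beam_score(toy, g$tokens),
                   tolerance = 1e-12)
    }
    # every pooled completion is a prefix (plus END) of the argmax-over-
    # continuations trajectory
    prefix <- special_tokens$begin
    for (step in seq_len(8)) {
      p <- next_token_distribution(toy, prefix)
      p[special_tokens$end] <- 0
      prefix <- c(prefix, names(p)[which.max(p)])
    }
    live_path <- paste(prefix[-1], collapse = "")
    expect_true(all(vapply(bs$string, function(s)
      startsWith(live_path, s), logical(1))))
  }
})

test_that("beam scores re-verify against beam_score and closed forms", {
  toy <- iid_toy()
  expect_equal(beam_score(toy, c(special_tokens$begin, "a", special_tokens$end)),
               log(0.5) + log(0.2))
  expect_equal(beam_score(toy, c(special_tokens$begin, special_tokens$end)),
               log(0.2))
  expect_error(beam_score(toy, c(special_tokens$begin, "z", special_tokens$end)),
               "not in vocabulary")
  bs <- beam_search(toy, width_k = 3, max_length = 4)
  toks <- attr(bs, "tokens")
  for (i in seq_len(nrow(bs)))
    expect_equal(beam_score(toy, toks[[i]]), bs$log_score[i], tolerance = 1e-9)
})

test_that("beam width and invalid distributions are rejected", {
  toy <- iid_toy()
  expect_error(beam_search(toy, width_k = 0), ">= 1")
  broken <- toy
  broken$table["BEGIN", ] <- broken$table["BEGIN", ] * 0.9
  expect_error(beam_search(broken, width_k = 2, max_length = 3),
               "non-normalized")
})

test_that("equal scores break lexicographically by token index", {
  # p(a) == p(b): "ab" and "ba" tie; "a..." sequences must come first
  toy <- make_toy_model(c("a", "b"), c(a = 0.4, b = 0.4, END = 0.2))
  bs <- beam_search(toy, width_k = 8, max_length = 3)
  tie <- bs[abs(bs$log_score - (2 * log(0.4) + log(0.2))) < 1e-12, ]
  expect_identical(tie$string, c("aa", "ab", "ba", "bb"))
})

test_that("length normalization and truncation handling are opt-in", {
  toy <- iid_toy()
  bs <- beam_search(toy, width_k = 2, max_length = 3, keep_truncated = TRUE)
  expect_true(any(!bs$completed))
  expect_true(all(bs$completed[1:3]))
  trunc <- bs[!bs$completed, ]
  expect_true(all(nchar(trunc$string) == 3))

  bn <- beam_search(toy, width_k = 2, max_length = 3, length_normalize = TRUE)
  # per-token scores: "aa" (log(.25*.2)/3) beats "a" beats END-only (log .2)
  expect_identical(bn$string[1:3], c("aa", "a", "ab"))
  expect_identical(bn$string[5], "")
})

test_that("memorization recovery: a 5-string overfit model is recovered at k=5", {
  ckpt <- overfit_checkpoint()
  bs <- beam_search(ckpt, width_k = 5, max_length = 30)
  expect_true(all(memorization_strings %in% bs$string[1:8]))
})

test_that("temperature sampling is seeded, reproducible and limits to greedy", {
  toy <- iid_toy()
  s1 <- temperature_sample(toy, 50, temperature = 1, max_length = 20, seed = 11)
  s2 <- temperature_sample(toy, 50, temperature = 1, max_length = 20, seed = 11)
  expect_identical(s1, s2)
  s3 <- temperature_sample(toy, 50, temperature = 1, max_length = 20, seed = 12)
  expect_false(identical(s1, s3))

  greedy <- greedy_walk(toy, 20)
  cold <- temperature_sample(toy, 20, temperature = 1e-6, max_length = 20,
                             seed = 1)
  expect_true(all(cold$string == greedy$string))
  expect_true(all(cold$truncated == greedy$truncated))

  ckpt <- overfit_checkpoint()
  greedy_clm <- greedy_walk(ckpt, 30)
  cold_clm <- temperature_sample(ckpt, 5, temperature = 1e-6, max_length = 30,
                                 seed = 1)
  expect_true(all(cold_clm$string == greedy_clm$string))
})

test_that("unit-temperature first-token frequencies match the model", {
  toy <- iid_toy()
  n <- 10000
  s <- temperature_sample(toy, n, temperature = 1, max_length = 25, seed = 17)
  first <- substr(s$string, 1, 1)
  first[s$string == "" & !s$truncated] <- "<END>"
  p_a <- 0.5
  se <- sqrt(p_a * (1 - p_a) / n)
  expect_lt(abs(mean(first == "a") - p_a), 3 * se)
})

test_that("truncated samples are flagged", {
  never_end <- make_toy_model(c("a"), c(a = 0.999, END = 0.001))
  s <- temperature_sample(never_end, 30, temperature = 1, max_length = 5,
                          seed = 2)
  expect_true(any(s$truncated))
  expect_true(all(nchar(s$string[s$truncated]) == 5))
})
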