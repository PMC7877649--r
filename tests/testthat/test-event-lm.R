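test_that("MLE bigram probabilities are hand-count ratios", {
  m <- toy_model()
  expect_equal(transition_prob(m, "a", "b"), 1)
  expect_equal(transition_prob(m, "b", "c"), 2 / 3)
  expect_equal(transition_prob(m, "b", "d"), 1 / 3)
  expect_equal(transition_prob(m, "b", "a"), 0)  # seen context, unseen target
  expect_error(transition_prob(m, "zz", "a"), "unknown context")
  # single deterministic successor
  m2 <- fit_ngram(list(c("x", "y")))
  expect_equal(transition_prob(m2, "x", "y"), 1)
})

test_that("MLE equals an independent brute-force oracle on random corpora", {
  set.seed(101)
  bos <- reserved_tokens()[["bos"]]
  for (rep in 1:30) {
    seqs <- random_sequences(sample(3:10, 1), sample(3:8, 1))
    m <- fit_ngram(seqs)
    ctxs <- c(bos, m$vocabulary)
    for (ctx in ctxs) {
      oracle_any <- FALSE
      for (tgt in c(m$vocabulary, reserved_tokens()[["eos"]])) {
        oracle <- brute_bigram_prob(seqs, ctx, tgt)
        if (is.na(oracle)) next
        oracle_any <- TRUE
        expect_equal(transition_prob(m, ctx, tgt), oracle,
                     tolerance = 1e-12)
      }
      if (oracle_any) {
        expect_equal(sum(successor_distribution(m, ctx)), 1,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("conditional distributions normalize under both smoothing modes", {
  set.seed(11)
  seqs <- random_sequences(10, 5)
  for (m in list(fit_ngram(seqs), fit_ngram(seqs, smoothing = "add_k",
                                            k = 0.5))) {
    for (ctx in c(reserved_tokens()[["bos"]], m$vocabulary)) {
      if (!ctx %in% names(m$context_totals)) next
      expect_equal(sum(successor_distribution(m, ctx)), 1,
                   tolerance = 1e-9)
    }
  }
  # add_k removes zeros
  ms <- fit_ngram(list(c("a", "b"), c("a", "c")), smoothing = "add_k", k = 1)
  expect_gt(transition_prob(ms, "b", "a"), 0)
})

test_that("surprisal follows -log2 p with an infinite sentinel at p = 0", {
  m <- toy_model()
  expect_equal(surprisal(m, "a", "b")$bits, 0)
  expect_equal(surprisal(m, "b", "c")$bits, -log2(2 / 3))
  expect_equal(round(surprisal(m, "b", "c")$bits, 3), 0.585)
  s0 <- surprisal(m, "b", "a")
  expect_identical(s0$bits, Inf)
  expect_identical(s0$probability, 0)
})

test_that("bits/percent conversions reproduce the printed equivalences", {
  expect_equal(bits_to_percent(2.13), 22.8)
  expect_equal(bits_to_percent(2.18), 22.1)
  expect_equal(bits_to_percent(0), 100)
  expect_equal(bits_to_percent(Inf), 0)
  expect_error(bits_to_percent(-1), "non-negative")
  # round trip for reference probabilities
  for (p in c(1, 1 / 2, 1 / 3, 2 / 3, 0.228)) {
    expect_equal(bits_to_percent(-log2(p), digits = 6), round(100 * p, 6))
  }
})

test_that("vocabulary statistics follow the documented counting convention", {
  m <- toy_model()
  st <- vocab_stats(m)
  expect_equal(st$vocabulary_size, 4L)         # a, b, c, d
  expect_equal(st$ngram_count, 3L)             # a.b, b.c, b.d
  expect_equal(vocab_stats(m, include_boundaries = TRUE)$ngram_count, 6L)
  # one sequence of k distinct labels
  m2 <- fit_ngram(list(letters[1:5]))
  expect_equal(vocab_stats(m2)$vocabulary_size, 5L)
})

test_that("mean surprisal averages per-transition bits and flags Inf", {
  m <- toy_model()
  ms <- mean_surprisal(m, c("a", "b", "c"))
  expect_equal(ms$bits, mean(c(0, -log2(2 / 3))))
  expect_equal(ms$per_transition, c(0, -log2(2 / 3)))
  expect_equal(mean_surprisal(m, c("a", "b"))$bits, 0)
  inf <- mean_surprisal(m, c("a", "b", "a"))
  expect_identical(inf$bits, Inf)
  expect_equal(inf$n_infinite, 1L)
})

test_that("monotonicity: adding a bigram occurrence never lowers its probability", {
  set.seed(21)
  for (rep in 1:10) {
    seqs <- random_sequences(8, 4)
    m1 <- fit_ngram(seqs)
    pair <- m1$ngram_counts[!grepl("<", m1$ngram_counts$context, fixed = TRUE) &
                              !grepl("<", m1$ngram_counts$target), ]
    if (nrow(pair) == 0L) next
    ctx <- pair$context[1L]; tgt <- pair$target[1L]
    m2 <- fit_ngram(c(seqs, list(c(ctx, tgt))))
    expect_gte(transition_prob(m2, ctx, tgt), transition_prob(m1, ctx, tgt))
  }
})

test_that("model fitting rejects placeholders and empty input", {
  expect_error(fit_ngram(list()), "no sequences")
  expect_error(fit_ngram(list(c("a b", paste("boil",
    reserved_tokens()[["placeholder"]])))), "placeholder")
})

test_that("plain-text serialization and ARPA export round trip", {
  m <- toy_model()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, tf)
  back <- read_model(tf)
  expect_equal(back$unigram_counts, m$unigram_counts)
  expect_equal(back$ngram_counts, m$ngram_counts)
  expect_equal(transition_prob(back, "b", "c"), 2 / 3)

  af <- withr::local_tempfile(fileext = ".arpa")
  write_arpa(m, af)
  lines <- readLines(af)
  expect_true("\\data\\" %in% lines)
  expect_true("\\1-grams:" %in% lines)
  expect_true(any(grepl("^\\\\2-grams:", lines)))
  # the b -> c bigram carries log10(2/3)
  bc <- grep("\tb c$", lines, value = TRUE)
  expect_equal(as.numeric(strsplit(bc, "\t")[[1L]][1L]), log10(2 / 3),
               tolerance = 1e-5)
})
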