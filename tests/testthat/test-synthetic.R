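test_that("script graphs validate stochasticity and reachability", {
  expect_s3_class(three_state_graph(), "script_graph")
  expect_error(script_graph(c("a b", "c d"),
                            rbind(c(0, 0.5, 0.4), c(0, 0, 1))),
               "sum to 1")
  expect_error(script_graph(c("a b", "c d"),
                            rbind(c(0, 1, 0), c(1, 0, 0))),
               "terminal")
  expect_error(script_graph(c("a b", "a b"),
                            rbind(c(0, 0.5, 0.5), c(0, 0, 1))),
               "duplicate")
})

test_that("corpus sampling is seed-deterministic and returns aligned truth", {
  g <- pasta_graph()
  s1 <- sample_esd_corpus(g, 20, pasta_noise(), seed = 9)
  s2 <- sample_esd_corpus(g, 20, pasta_noise(), seed = 9)
  expect_identical(s1$corpus$events, s2$corpus$events)
  expect_identical(s1$truth, s2$truth)
  s3 <- sample_esd_corpus(g, 20, pasta_noise(), seed = 10)
  expect_false(identical(s1$corpus$events$text, s3$corpus$events$text))
  expect_identical(lengths(s1$truth),
                   lengths(corpus_sequences(s1$corpus)))
  expect_error(sample_esd_corpus(g, 0), ">= 1")
})

test_that("noise-free corpora label back to ground truth exactly", {
  g <- pasta_graph()
  sim <- sample_esd_corpus(g, 50, noise_spec(), seed = 3)
  lab <- label_corpus(sim$corpus, graph_lexicon(g))
  expect_identical(unname(unlist(lab$sequences)),
                   unname(unlist(sim$truth)))
  # deterministic 2-state chain: all ESDs identical
  g2 <- script_graph(c("put water", "boil water"),
                     rbind(c(0, 1, 0), c(0, 0, 1)))
  sim2 <- sample_esd_corpus(g2, 50, seed = 1)
  expect_true(all(vapply(sim2$truth, identical, logical(1),
                         c("put water", "boil water"))))
})

test_that("full pronoun noise is restored by the companion lexicon", {
  g <- three_state_graph()
  noise <- noise_spec(pronoun_rate = 1, plural_nouns = character(0))
  sim <- sample_esd_corpus(g, 40, noise, seed = 13)
  lab <- label_corpus(sim$corpus, graph_lexicon(g, noise))
  expect_identical(unname(unlist(lab$sequences)),
                   unname(unlist(sim$truth)))
  # direct pronoun-map route on a shared-noun graph
  lex <- normalization_lexicon(
    pronouns = data.frame(scenario = "synthetic", pronoun = "it",
                          noun = "water"))
  g3 <- script_graph(c("put water", "boil water"),
                     rbind(c(0, 1, 0), c(0, 0, 1)))
  sim3 <- sample_esd_corpus(g3, 20, noise, seed = 14)
  lab3 <- label_corpus(sim3$corpus, lex)
  expect_identical(unname(unlist(lab3$sequences)),
                   unname(unlist(sim3$truth)))
})

test_that("synonym and ellipsis noise are inverted by the companion lexicon", {
  g <- pasta_graph()
  noise <- pasta_noise()
  sim <- sample_esd_corpus(g, 60, noise, seed = 21)
  lab <- label_corpus(sim$corpus, graph_lexicon(g, noise))
  expect_identical(unname(unlist(lab$sequences)),
                   unname(unlist(sim$truth)))
})

test_that("transition recovery: deterministic graphs recover exactly", {
  g <- script_graph(c("put water", "boil water", "pour pasta"),
                    rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)))
  rec <- recover_transitions(g, 30, seed = 2)
  expect_equal(rec$max_error, 0)
})

test_that("transition recovery error shrinks with corpus size", {
  g <- three_state_graph()
  set.seed(88)
  errs_small <- vapply(1:10, function(s)
    recover_transitions(g, 20, seed = 100 + s)$mean_error, numeric(1))
  errs_large <- vapply(1:10, function(s)
    recover_transitions(g, 2000, seed = 200 + s)$mean_error, numeric(1))
  expect_lt(mean(errs_large), mean(errs_small))
})

test_that("rating simulation respects the Latin square and the seed", {
  des <- latin_square_design(8, 8)
  expect_true(all(table(des$subject, des$item) == 1))
  # each subject: n_items/4 trials per condition
  per <- table(des$subject, des$sententiality, des$predictability)
  expect_true(all(per == 2))

  spec <- rating_sim_spec(n_subjects = 8, n_items = 8)
  t1 <- sample_ratings(spec, seed = 4)
  t2 <- sample_ratings(spec, seed = 4)
  expect_identical(t1$rating, t2$rating)
  expect_true(all(t1$rating %in% 1:7))
  expect_equal(sum(t1$is_control), 8 * spec$n_controls)
  expect_error(sample_ratings(spec,
    design = data.frame(subject = c(1, 1), item = c(1, 1))),
    "exactly once")
})

test_that("null generator gives symmetric ratings; effects point the coded way", {
  spec0 <- rating_sim_spec(n_subjects = 40, n_items = 16,
                           fixed_effects = c(sententiality = 0),
                           random_sds = c(subject_intercept = 0),
                           n_controls = 0)
  tab0 <- sample_ratings(spec0, seed = 6)
  # symmetric thresholds, zero effects: mean rating near the scale center
  expect_lt(abs(mean(tab0$rating) - 4), 0.15)

  specS <- rating_sim_spec(n_subjects = 40, n_items = 16,
                           fixed_effects = c(sententiality = -1.5),
                           random_sds = c(subject_intercept = 0),
                           n_controls = 0)
  tabS <- sample_ratings(specS, seed = 6)
  frag <- mean(tabS$rating[tabS$sententiality == "fragment"])
  sent <- mean(tabS$rating[tabS$sententiality == "sentence"])
  expect_lt(frag, sent)  # fragments (+1) rated lower under a negative effect
})
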