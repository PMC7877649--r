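# Fixtures built in code: tiny corpora, graphs and random-model helpers.

pasta_events <- function() {
  data.frame(
    esd_id = rep(c("esd4", "esd5"), c(5L, 6L)),
    position = c(1:5, 1:6),
    text = c("Look up a pasta recipe", "Get all the sauce ingredients",
             "Boil the noodles until well done", "Cook the sauce",
             "Combine the sauce and the pasta",
             "Put water in a pot", "Turn the stove on",
             "Put the pot on the stove", "Boil water",
             "Put pasta in the water", "Wait for pasta to cook"),
    stringsAsFactors = FALSE)
}

pasta_corpus <- function() {
  script_corpus("cooking pasta", pasta_events(), script_type = "adapted")
}

toy_model <- function() {
  fit_ngram(list(c("a", "b", "c"), c("a", "b", "d"), c("a", "b", "c")))
}

# Random label sequences over a small alphabet, for oracle checks.
random_sequences <- function(n_esds, n_labels, max_len = 6L) {
  labels <- letters[seq_len(n_labels)]
  lapply(seq_len(n_esds), function(i) {
    sample(labels, sample(2:max_len, 1L), replace = TRUE)
  })
}

# Independent brute-force bigram probability: count ratios straight from
# the raw sequences, no model code involved.
brute_bigram_prob <- function(sequences, context, target) {
  bos <- reserved_tokens()[["bos"]]; eos <- reserved_tokens()[["eos"]]
  num <- 0L; den <- 0L
  for (s in sequences) {
    w <- c(bos, s, eos)
    for (i in seq_len(length(w) - 1L)) {
      if (w[i] == context) {
        den <- den + 1L
        if (w[i + 1L] == target) num <- num + 1L
      }
    }
  }
  if (den == 0L) return(NA_real_)
  num / den
}

# Random row-stochastic transition structure as a fitted-model stand-in:
# builds sequences whose empirical argmax structure is then checked.
random_transition_model <- function(n_states, n_esds = 40L) {
  labels <- paste0("ev", seq_len(n_states))
  seqs <- lapply(seq_len(n_esds), function(i) {
    sample(labels, sample(2:min(n_states, 5L), 1L), replace = FALSE)
  })
  fit_ngram(seqs)
}

three_state_graph <- function() {
  script_graph(
    c("put water", "boil water", "pour pasta"),
    rbind(c(0, 0.7, 0.3, 0),
          c(0, 0, 0.8, 0.2),
          c(0, 0, 0, 1)),
    start_distribution = c(1, 0, 0))
}
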