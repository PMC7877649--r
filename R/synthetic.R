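#' Probabilistic script graph
#'
#' Ground-truth generator for ESD corpora: each state is a canonical
#' verb-noun event, transitions form a row-stochastic matrix over the
#' states plus an explicit terminal column (so generated sequence lengths
#' vary realistically), and a start distribution selects the first event.
#'
#' @param states character vector of event labels (`"verb noun"`).
#' @param transition_matrix numeric matrix, `length(states)` rows and
#'   `length(states) + 1` columns (the last column is the terminal state);
#'   rows sum to 1.
#' @param start_distribution probability vector over states; defaults to
#'   all mass on the first state.
#' @return A `script_graph`.
#' @export
#' @examples
#' g <- script_graph(c("put water", "boil water", "pour pasta"),
#'   rbind(c(0, 1, 0, 0), c(0, 0, 0.7, 0.3), c(0, 0, 0, 1)))
script_graph <- function(states, transition_matrix,
                         start_distribution = NULL) {
  states <- as.character(states)
  n <- length(states)
  if (anyDuplicated(states)) stop("duplicate state labels", call. = FALSE)
  transition_matrix <- as.matrix(transition_matrix)
  if (nrow(transition_matrix) != n || ncol(transition_matrix) != n + 1L) {
    stop("transition matrix must be ", n, " x ", n + 1L,
         " (last column = terminal)", call. = FALSE)
  }
  if (any(transition_matrix < 0)) {
    stop("negative transition probability", call. = FALSE)
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  if (is.null(start_distribution)) {
    start_distribution <- c(1, rep(0, n - 1L))
  }
  if (length(start_distribution) != n ||
      abs(sum(start_distribution) - 1) > 1e-9 ||
      any(start_distribution < 0)) {
    stop("invalid start distribution", call. = FALSE)
  }
  # every state must be able to reach the terminal column
  reach <- transition_matrix[, n + 1L] > 0
  repeat {
    new <- reach | (transition_matrix[, seq_len(n), drop = FALSE] %*%
                      reach > 0)
    if (all(new == reach)) break
    reach <- as.vector(new)
  }
  if (!all(reach)) {
    stop("state(s) with no path to the terminal: ",
         paste(states[!reach], collapse = ", "), call. = FALSE)
  }
  dimnames(transition_matrix) <- list(states, c(states, "<end>"))
  structure(list(states = states, transition_matrix = transition_matrix,
                 start_distribution = setNames(start_distribution, states)),
            class = "script_graph")
}

#' @export
print.script_graph <- function(x, ...) {
  cat("<script_graph>", length(x$states), "states:",
      paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

graph_verbs <- function(graph) {
  vapply(strsplit(graph$states, " ", fixed = TRUE), `[[`, character(1), 1L)
}

graph_nouns <- function(graph) {
  vapply(strsplit(graph$states, " ", fixed = TRUE),
         function(p) paste(p[-1L], collapse = " "), character(1))
}

#' Lexical noise specification for corpus generation
#'
#' Controls how canonical events are rendered as raw text: with
#' probability `synonym_rate` the noun is replaced by a synonym drawn
#' from its `synonym_sets` entry; with `pronoun_rate` it is replaced by a
#' pronoun (`it`, or `them` for nouns listed in `plural_nouns`); with
#' `ellipsis_rate` the object is omitted entirely; each event is dropped
#' from the ESD with `skip_rate` (at least one event is always kept).
#' Probabilities are applied in that order, at most one lexical
#' replacement per event.
#'
#' @param synonym_sets named list: canonical noun -> list with `alts`
#'   (character) and `probs` (selection probabilities summing to 1).
#' @param synonym_rate,pronoun_rate,ellipsis_rate,skip_rate rates in
#'   `[0, 1]`.
#' @param plural_nouns canonical nouns rendered with plural agreement
#'   (pronoun `them`, no determiner inflection).
#' @return A `noise_spec`.
#' @export
noise_spec <- function(synonym_sets = list(), synonym_rate = 0,
                       pronoun_rate = 0, ellipsis_rate = 0, skip_rate = 0,
                       plural_nouns = character(0)) {
  rates <- c(synonym_rate, pronoun_rate, ellipsis_rate, skip_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("noise rates must be in [0, 1]", call. = FALSE)
  }
  if (synonym_rate + pronoun_rate + ellipsis_rate > 1) {
    stop("synonym_rate + pronoun_rate + ellipsis_rate must be <= 1",
         call. = FALSE)
  }
  for (nm in names(synonym_sets)) {
    s <- synonym_sets[[nm]]
    if (abs(sum(s$probs) - 1) > 1e-9 ||
        length(s$probs) != length(s$alts)) {
      stop("synonym set for '", nm, "' is malformed", call. = FALSE)
    }
  }
  structure(list(synonym_sets = synonym_sets, synonym_rate = synonym_rate,
                 pronoun_rate = pronoun_rate, ellipsis_rate = ellipsis_rate,
                 skip_rate = skip_rate, plural_nouns = plural_nouns),
            class = "noise_spec")
}

render_event <- function(verb, noun, mode, plural) {
  cap <- function(w) paste0(toupper(substring(w, 1, 1)), substring(w, 2))
  switch(mode,
    canonical = paste(cap(verb), "the", noun),
    synonym = paste(cap(verb), "the", noun),  # noun already replaced
    pronoun = paste(cap(verb), if (plural) "them" else "it"),
    ellipsis = cap(verb)
  )
}

#' Sample an ESD corpus from a script graph
#'
#' Each ESD is a path sampled from the graph (start distribution, then
#' row-wise transitions until the terminal state); each retained event is
#' rendered as text through the lexical noise channel. The ground-truth
#' canonical label sequences (after skipping) are returned alongside, so
#' every downstream stage can be checked against truth.
#'
#' @param graph a [script_graph()].
#' @param n_esds number of ESDs (>= 1).
#' @param noise a [noise_spec()]; default noise-free.
#' @param scenario scenario name for the corpus.
#' @param seed integer seed; sampling is reproducible given the seed.
#' @param max_events hard cap on path length (guards improbable loops).
#' @return List with `corpus` (a `script_corpus`) and `truth` (named list
#'   of canonical label sequences, aligned with the corpus ESDs).
#' @export
#' @examples
#' g <- script_graph(c("put water", "boil water"),
#'   rbind(c(0, 1, 0), c(0, 0, 1)))
#' sample_esd_corpus(g, 3, seed = 1)$truth
sample_esd_corpus <- function(graph, n_esds, noise = noise_spec(),
                              scenario = "synthetic", seed = 1L,
                              max_events = 50L) {
  stopifnot(inherits(graph, "script_graph"), inherits(noise, "noise_spec"))
  if (n_esds < 1L) stop("n_esds must be >= 1", call. = FALSE)
  set.seed(seed)
  verbs <- graph_verbs(graph)
  nouns <- graph_nouns(graph)
  n <- length(graph$states)
  rows <- vector("list", n_esds)
  truth <- vector("list", n_esds)
  for (e in seq_len(n_esds)) {
    # path through the graph
    path <- integer(0)
    s <- sample.int(n, 1L, prob = graph$start_distribution)
    for (step in seq_len(max_events)) {
      path <- c(path, s)
      nxt <- sample.int(n + 1L, 1L, prob = graph$transition_matrix[s, ])
      if (nxt == n + 1L) break
      s <- nxt
    }
    # event skipping, keeping at least one event
    keep <- runif(length(path)) >= noise$skip_rate
    if (!any(keep)) keep[sample.int(length(path), 1L)] <- TRUE
    path <- path[keep]
    # lexical rendering
    texts <- vapply(path, function(st) {
      u <- runif(1)
      noun <- nouns[st]
      if (u < noise$synonym_rate && noun %in% names(noise$synonym_sets)) {
        ss <- noise$synonym_sets[[noun]]
        alt <- ss$alts[sample.int(length(ss$alts), 1L, prob = ss$probs)]
        render_event(verbs[st], alt, "synonym", FALSE)
      } else if (u < noise$synonym_rate + noise$pronoun_rate) {
        render_event(verbs[st], noun, "pronoun",
                     noun %in% noise$plural_nouns)
      } else if (u < noise$synonym_rate + noise$pronoun_rate +
                 noise$ellipsis_rate) {
        render_event(verbs[st], noun, "ellipsis", FALSE)
      } else {
        render_event(verbs[st], noun, "canonical", FALSE)
      }
    }, character(1))
    id <- sprintf("esd%03d", e)
    rows[[e]] <- data.frame(esd_id = id, position = seq_along(path),
                            text = texts, stringsAsFactors = FALSE)
    truth[[e]] <- graph$states[path]
    names(truth)[e] <- id
  }
  corpus <- script_corpus(scenario, do.call(rbind, rows))
  list(corpus = corpus, truth = truth)
}

#' Companion lexicon for a noisy synthetic corpus
#'
#' Builds the normalization lexicon that exactly inverts the noise
#' channel of [sample_esd_corpus()]: synonym surface forms map back to
#' the canonical noun; pronoun renderings resolve through event mappings
#' (`"verb it"` / `"verb them"` -> canonical label, which requires verbs
#' to be unique per state, as they are in the bundled example graphs);
#' elided objects resolve through the default-object map keyed by verb.
#'
#' @param graph a [script_graph()].
#' @param noise the [noise_spec()] used for generation.
#' @param scenario scenario name the lexicon is scoped to.
#' @return A [normalization_lexicon()].
#' @export
graph_lexicon <- function(graph, noise = noise_spec(),
                          scenario = "synthetic") {
  verbs <- graph_verbs(graph)
  nouns <- graph_nouns(graph)
  if ((noise$pronoun_rate > 0 || noise$ellipsis_rate > 0) &&
      anyDuplicated(verbs)) {
    stop("pronoun/ellipsis noise needs verbs unique per state for exact ",
         "inversion", call. = FALSE)
  }
  syn <- do.call(rbind, lapply(names(noise$synonym_sets), function(nn) {
    data.frame(scenario = scenario,
               from = lemmatize(noise$synonym_sets[[nn]]$alts), to = nn,
               stringsAsFactors = FALSE)
  }))
  pron <- vapply(nouns, function(nn) {
    if (nn %in% noise$plural_nouns) "them" else "it"
  }, character(1))
  events <- data.frame(
    scenario = scenario,
    from = paste(verbs, pron),
    to = graph$states, stringsAsFactors = FALSE)
  defaults <- data.frame(scenario = scenario, verb = verbs, noun = nouns,
                         stringsAsFactors = FALSE)
  normalization_lexicon(synonyms = syn, events = events,
                        default_objects = defaults)
}

#' Transition-probability recovery check
#'
#' Validation harness for the estimation pipeline: samples a noise-free
#' corpus from the graph, labels it with the rule-based parser, fits an
#' MLE bigram model, and reports the absolute error between every fitted
#' conditional probability and the generator's transition matrix
#' (terminal transitions compared against the end marker).
#'
#' @param graph a [script_graph()].
#' @param n_esds corpus size.
#' @param seed integer seed.
#' @return List with `max_error`, `mean_error`, `n_cells` (compared
#'   cells), `model` and `fitted` (fitted probability matrix, states x
#'   states+end).
#' @export
recover_transitions <- function(graph, n_esds, seed = 1L) {
  stopifnot(inherits(graph, "script_graph"))
  sim <- sample_esd_corpus(graph, n_esds, noise_spec(), seed = seed)
  labeled <- label_corpus(sim$corpus, graph_lexicon(graph))
  model <- fit_ngram(labeled, order = 2L)
  n <- length(graph$states)
  fitted <- matrix(NA_real_, n, n + 1L,
                   dimnames = dimnames(graph$transition_matrix))
  errs <- c()
  for (i in seq_len(n)) {
    st <- graph$states[i]
    if (!st %in% names(model$context_totals)) next  # state never sampled
    dist <- successor_distribution(model, st)
    for (j in seq_len(n + 1L)) {
      target <- if (j <= n) graph$states[j] else EOS
      p_hat <- if (target %in% names(dist)) unname(dist[target]) else 0
      fitted[i, j] <- p_hat
      errs <- c(errs, abs(p_hat - graph$transition_matrix[i, j]))
    }
  }
  list(max_error = max(errs), mean_error = mean(errs),
       n_cells = length(errs), model = model, fitted = fitted)
}

#' Example script graph: cooking pasta
#'
#' A small kitchen-script graph emulating the structure of crowd-sourced
#' pasta-scenario ESDs: a mostly linear backbone (put water, turn stove,
#' boil water, pour pasta, drain pasta, serve pasta) with branching and
#' optional events so sampled ESD lengths vary around 5-6 events.
#'
#' @return A [script_graph()].
#' @export
pasta_graph <- function() {
  st <- c("put water", "turn stove", "boil water", "pour pasta",
          "stir pasta", "drain pasta", "serve pasta", "set table")
  P <- matrix(0, 8, 9, dimnames = list(st, c(st, "<end>")))
  P["put water", "turn stove"] <- 0.8
  P["put water", "boil water"] <- 0.2
  P["turn stove", "boil water"] <- 1
  P["boil water", "pour pasta"] <- 0.85
  P["boil water", "set table"] <- 0.15
  P["set table", "pour pasta"] <- 1
  P["pour pasta", "stir pasta"] <- 0.4
  P["pour pasta", "drain pasta"] <- 0.6
  P["stir pasta", "drain pasta"] <- 1
  P["drain pasta", "serve pasta"] <- 0.9
  P["drain pasta", "<end>"] <- 0.1
  P["serve pasta", "<end>"] <- 1
  script_graph(st, P)
}

#' Default lexical noise for the pasta graph
#'
#' Synonym sets (pot/saucepan for water's vessel stand-in is omitted;
#' noodle/spaghetti for pasta), moderate pronoun/ellipsis/skip rates -
#' the kind of granularity and explicitness variation real ESDs show.
#'
#' @return A [noise_spec()].
#' @export
pasta_noise <- function() {
  noise_spec(
    synonym_sets = list(
      pasta = list(alts = c("noodles", "spaghetti"), probs = c(0.6, 0.4)),
      stove = list(alts = c("burner", "hob"), probs = c(0.7, 0.3))
    ),
    synonym_rate = 0.3, pronoun_rate = 0.1, ellipsis_rate = 0.1,
    skip_rate = 0.1,
    plural_nouns = "pasta"
  )
}
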