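#' Fit an event-level n-gram model
#'
#' Counts n-grams over label sequences wrapped in begin/end boundary
#' markers and exposes conditional probabilities p(e_j | context).
#' The default is a bigram model: with roughly a hundred sequences per
#' scenario, higher orders are not reasonably estimable, and the bigram
#' transition probability p(e_j | e_i) is exactly the likelihood of event
#' e_j to follow e_i. Probabilities are maximum likelihood (count ratios)
#' by default; add-k smoothing spreads `k` pseudo-counts over the
#' successor vocabulary. Zero probabilities only exist unsmoothed, which
#' the stimulus-construction step relies on.
#'
#' @param sequences list of character vectors of event labels (e.g.
#'   `labeled_corpus$sequences`), or a `labeled_corpus`.
#' @param order n-gram order, >= 1; default 2 (bigram).
#' @param smoothing `"mle"` (default) or `"add_k"`.
#' @param k pseudo-count for `"add_k"`; default 1.
#' @param scenario scenario name recorded on the model.
#' @return A `transition_model`: list with `scenario`, `order`, `smoothing`,
#'   `k`, `vocabulary` (event labels, boundaries excluded),
#'   `unigram_counts` (named, boundaries included), `ngram_counts` (data
#'   frame `context`, `target`, `count`) and `context_totals`.
#' @export
#' @examples
#' m <- fit_ngram(list(c("a", "b", "c"), c("a", "b", "d"), c("a", "b", "c")))
#' transition_prob(m, "b", "c")  # 2/3
fit_ngram <- function(sequences, order = 2L, smoothing = c("mle", "add_k"),
                      k = 1, scenario = NA_character_) {
  if (inherits(sequences, "labeled_corpus")) {
    if (is.na(scenario)) scenario <- sequences$scenario
    sequences <- sequences$sequences
  }
  smoothing <- match.arg(smoothing)
  order <- as.integer(order)
  if (order < 1L) stop("n-gram order must be >= 1", call. = FALSE)
  if (length(sequences) == 0L) stop("no sequences to fit", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  for (i in seq_along(sequences)) {
    if (PLACEHOLDER %in% strsplit(paste(sequences[[i]], collapse = " "),
                                  " ", fixed = TRUE)[[1L]]) {
      stop("placeholder label in ESD '", ids[i],
           "'; resolve or exclude it before fitting", call. = FALSE)
    }
    if (length(sequences[[i]]) == 0L) {
      stop("ESD '", ids[i], "' is empty", call. = FALSE)
    }
  }

  wrapped <- lapply(sequences, function(s) c(BOS, s, EOS))
  tokens <- unlist(wrapped, use.names = FALSE)
  unigram_counts <- table(tokens)
  unigram_counts <- setNames(as.integer(unigram_counts),
                             names(unigram_counts))

  ctx_n <- order - 1L
  grams <- do.call(rbind, lapply(wrapped, function(s) {
    L <- length(s)
    if (L < order) return(NULL)
    idx <- seq_len(L - ctx_n)
    ctx <- if (ctx_n == 0L) rep("", length(idx)) else
      vapply(idx, function(i) paste(s[i:(i + ctx_n - 1L)], collapse = " ␟ "),
             character(1))
    data.frame(context = ctx, target = s[idx + ctx_n],
               stringsAsFactors = FALSE)
  }))
  if (is.null(grams) || nrow(grams) == 0L) {
    stop("no ", order, "-grams observed; sequences too short for this order",
         call. = FALSE)
  }
  agg <- aggregate(list(count = rep(1L, nrow(grams))),
                   grams[, c("context", "target")], sum)
  agg <- agg[base::order(agg$context, agg$target), ]
  rownames(agg) <- NULL
  totals <- tapply(agg$count, agg$context, sum)

  vocab <- sort(setdiff(unique(tokens), c(BOS, EOS)))
  structure(list(
    scenario = scenario, order = order, smoothing = smoothing,
    k = if (smoothing == "add_k") k else NA_real_,
    vocabulary = vocab,
    unigram_counts = unigram_counts,
    ngram_counts = agg,
    context_totals = setNames(as.integer(totals), names(totals)),
    n_sequences = length(sequences)
  ), class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  st <- vocab_stats(x)
  cat("<transition_model> scenario:", x$scenario, "\n")
  cat(sprintf("  order %d, smoothing %s, %d sequences\n", x$order,
              x$smoothing, x$n_sequences))
  cat(sprintf("  vocabulary %d event labels, %d distinct observed %d-grams\n",
              st$vocabulary_size, st$ngram_count, x$order))
  invisible(x)
}

model_context_key <- function(model, context) {
  if (model$order == 1L) return("")
  if (length(context) != model$order - 1L) {
    stop("context must have ", model$order - 1L, " label(s)", call. = FALSE)
  }
  paste(context, collapse = " ␟ ")
}

# Successor support for smoothing: every event label plus the end marker.
successor_vocab <- function(model) c(model$vocabulary, EOS)

#' Conditional transition probability
#'
#' @param model a `transition_model`.
#' @param context conditioning label(s); `order - 1` of them. The begin
#'   marker (see [reserved_tokens()]) is a legal context.
#' @param target target event label (the end marker is a legal target).
#' @return Probability p(target | context) in `[0, 1]`. Unknown contexts
#'   error (distinct from a seen context with an unseen target, which has
#'   probability 0 under MLE).
#' @export
transition_prob <- function(model, context, target) {
  stopifnot(inherits(model, "transition_model"))
  key <- model_context_key(model, context)
  tot <- model$context_totals[key]
  if (is.na(tot)) {
    stop("unknown context: '", paste(context, collapse = " "), "'",
         call. = FALSE)
  }
  cnt <- model$ngram_counts$count[model$ngram_counts$context == key &
                                    model$ngram_counts$target == target]
  cnt <- if (length(cnt)) cnt else 0L
  if (model$smoothing == "add_k") {
    V <- length(successor_vocab(model))
    unname((cnt + model$k) / (tot + model$k * V))
  } else {
    unname(cnt / tot)
  }
}

#' Full conditional distribution over successors
#'
#' @inheritParams transition_prob
#' @return Named numeric vector of p(. | context) over the successor
#'   vocabulary (event labels plus the end marker); sums to 1.
#' @export
successor_distribution <- function(model, context) {
  stopifnot(inherits(model, "transition_model"))
  key <- model_context_key(model, context)
  tot <- model$context_totals[key]
  if (is.na(tot)) {
    stop("unknown context: '", paste(context, collapse = " "), "'",
         call. = FALSE)
  }
  succ <- successor_vocab(model)
  cnt <- setNames(numeric(length(succ)), succ)
  sub <- model$ngram_counts[model$ngram_counts$context == key, ]
  cnt[sub$target] <- sub$count
  if (model$smoothing == "add_k") {
    (cnt + model$k) / (tot + model$k * length(succ))
  } else {
    cnt / tot
  }
}

#' Event surprisal in bits
#'
#' Surprisal is the negative base-2 logarithm of a conditional
#' probability: an event certain to follow carries 0 bits; an event with
#' probability 0 carries infinite surprisal, represented by the `Inf`
#' sentinel (never an error), so chains and reports can carry it.
#'
#' @inheritParams transition_prob
#' @return A `surprisal_value`: list with `bits` (>= 0, possibly `Inf`)
#'   and `probability`.
#' @export
#' @examples
#' m <- fit_ngram(list(c("a", "b", "c"), c("a", "b", "d"), c("a", "b", "c")))
#' surprisal(m, "b", "c")  # -log2(2/3) = 0.585 bits
surprisal <- function(model, context, target) {
  p <- transition_prob(model, context, target)
  bits <- if (p > 0) -log2(p) + 0 else Inf  # + 0 avoids negative zero
  structure(list(bits = bits, probability = p), class = "surprisal_value")
}

#' @export
print.surprisal_value <- function(x, ...) {
  cat(sprintf("<surprisal> %.4g bits (p = %.4g)\n", x$bits, x$probability))
  invisible(x)
}

#' Convert surprisal in bits to a probability percentage
#'
#' `100 * 2^(-bits)`, rounded to `digits` decimals: 2.13 bits correspond
#' to a likelihood of 22.8%, 2.18 bits to 22.1%.
#'
#' @param bits non-negative surprisal in bits (may be `Inf`).
#' @param digits decimals in the returned percentage; default 1.
#' @return Probability as a percentage.
#' @export
#' @examples
#' bits_to_percent(2.13)  # 22.8
bits_to_percent <- function(bits, digits = 1) {
  if (any(is.na(bits)) || any(bits < 0)) {
    stop("surprisal must be non-negative", call. = FALSE)
  }
  round(100 * 2^(-bits), digits)
}

#' Vocabulary statistics of a fitted model
#'
#' @param model a `transition_model`.
#' @param include_boundaries count n-grams involving the boundary markers?
#'   Default `FALSE`: the vocabulary size is the number of distinct
#'   primitive events, and the n-gram count covers event-to-event
#'   transitions only.
#' @return List with `vocabulary_size` and `ngram_count` (distinct
#'   observed n-grams).
#' @export
vocab_stats <- function(model, include_boundaries = FALSE) {
  stopifnot(inherits(model, "transition_model"))
  ng <- model$ngram_counts
  if (!include_boundaries) {
    boundary <- function(x) grepl(BOS, x, fixed = TRUE) |
      grepl(EOS, x, fixed = TRUE)
    ng <- ng[!boundary(ng$context) & !boundary(ng$target), , drop = FALSE]
  }
  list(vocabulary_size = length(model$vocabulary),
       ngram_count = nrow(ng))
}

#' Mean surprisal of a chain
#'
#' Arithmetic mean of the per-transition surprisal (bits) over a label
#' sequence's adjacent pairs. Any zero-probability transition makes the
#' mean infinite; the result flags how many transitions were infinite.
#'
#' @param model a `transition_model` (order 2).
#' @param chain character vector of >= 2 event labels.
#' @return List with `bits` (mean), `per_transition` (numeric vector),
#'   and `n_infinite`.
#' @export
mean_surprisal <- function(model, chain) {
  stopifnot(inherits(model, "transition_model"))
  if (model$order != 2L) {
    stop("mean_surprisal is defined for bigram models", call. = FALSE)
  }
  if (length(chain) < 2L) stop("chain needs >= 2 events", call. = FALSE)
  per <- vapply(seq_len(length(chain) - 1L), function(i) {
    surprisal(model, chain[i], chain[i + 1L])$bits
  }, numeric(1))
  list(bits = mean(per), per_transition = per,
       n_infinite = sum(is.infinite(per)))
}

#' Serialize / read a transition model as plain text
#'
#' Format: a header line `scenario<TAB>order<TAB>smoothing<TAB>k`, then
#' `unigram<TAB>label<TAB>count` lines, then
#' `ngram<TAB>context<TAB>target<TAB>count` lines (context labels joined
#' by `" | "`).
#'
#' @param model a `transition_model`.
#' @param path output path.
#' @return `write_model`: `path` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("header", model$scenario, model$order, model$smoothing,
                   model$k, model$n_sequences, sep = "\t"), con)
  writeLines(paste("unigram", names(model$unigram_counts),
                   model$unigram_counts, sep = "\t"), con)
  ctx <- gsub(" ␟ ", " | ", model$ngram_counts$context, fixed = TRUE)
  writeLines(paste("ngram", ctx, model$ngram_counts$target,
                   model$ngram_counts$count, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1L)
  hd <- parts[[which(kind == "header")[1L]]]
  uni <- parts[kind == "unigram"]
  ngr <- parts[kind == "ngram"]
  unigram_counts <- setNames(as.integer(vapply(uni, `[[`, character(1), 3L)),
                             vapply(uni, `[[`, character(1), 2L))
  ng <- data.frame(
    context = gsub(" | ", " ␟ ",
                   vapply(ngr, `[[`, character(1), 2L), fixed = TRUE),
    target = vapply(ngr, `[[`, character(1), 3L),
    count = as.integer(vapply(ngr, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  totals <- tapply(ng$count, ng$context, sum)
  structure(list(
    scenario = hd[2L], order = as.integer(hd[3L]), smoothing = hd[4L],
    k = if (hd[5L] %in% c("NA", "")) NA_real_ else as.numeric(hd[5L]),
    vocabulary = sort(setdiff(names(unigram_counts), c(BOS, EOS))),
    unigram_counts = unigram_counts, ngram_counts = ng,
    context_totals = setNames(as.integer(totals), names(totals)),
    n_sequences = as.integer(hd[6L])
  ), class = "transition_model")
}

#' Export a bigram model in ARPA format
#'
#' Standard n-gram interchange format (log10 probabilities, `\\data\\`
#' header, per-order sections). MLE models write `-99` for the log
#' probability of zero-probability unigrams, following common practice.
#'
#' @param model a `transition_model` of order 2.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arpa <- function(model, path) {
  stopifnot(inherits(model, "transition_model"), model$order == 2L)
  uni <- model$unigram_counts
  toks <- names(uni)
  total <- sum(uni[!toks %in% BOS])
  lp1 <- vapply(toks, function(t) {
    if (t == BOS) return(-99)
    log10(uni[[t]] / total)
  }, numeric(1))
  ng <- model$ngram_counts
  lp2 <- log10(ng$count / model$context_totals[ng$context])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("\\data\\",
               paste0("ngram 1=", length(toks)),
               paste0("ngram 2=", nrow(ng)), "",
               "\\1-grams:"), con)
  writeLines(sprintf("%.6f\t%s", lp1, toks), con)
  writeLines(c("", "\\2-grams:"), con)
  writeLines(sprintf("%.6f\t%s %s", lp2, ng$context, ng$target), con)
  writeLines(c("", "\\end\\"), con)
  invisible(path)
}
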