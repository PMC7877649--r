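#' Events frequent enough for stimulus construction
#'
#' Overall rare events (fewer than `min_count` occurrences in the script
#' data) are not considered when building chains and stimuli: an event
#' mentioned by a single contributor should not be taken to represent the
#' script knowledge of the whole population. The threshold applies to
#' chain/stimulus selection, never to model fitting.
#'
#' @param model a `transition_model`.
#' @param min_count minimum unigram count; default 8.
#' @return Character vector of eligible event labels (boundaries excluded).
#' @export
eligible_events <- function(model, min_count = 8L) {
  stopifnot(inherits(model, "transition_model"))
  if (min_count < 1L) stop("min_count must be >= 1", call. = FALSE)
  cnt <- model$unigram_counts[model$vocabulary]
  out <- names(cnt)[cnt >= min_count]
  if (length(out) == 0L) {
    warning("no event reaches min_count = ", min_count, call. = FALSE)
  }
  out
}

#' Extract a maximum-likelihood event chain
#'
#' Greedy walk over the transition model: starting from `start`, each
#' step appends the eligible, not-yet-visited successor with the maximal
#' conditional probability (ties broken lexicographically on the label).
#' The walk stops early, with a flag, when no eligible unvisited successor
#' has positive probability. Events never repeat within a chain, so the
#' walk always terminates.
#'
#' @param model a bigram `transition_model`.
#' @param start starting event label, or `"auto"` (default) to start at
#'   the eligible event most likely to open a sequence (the argmax
#'   successor of the begin marker).
#' @param length target chain length (>= 2).
#' @param min_count eligibility threshold, as in [eligible_events()].
#' @return An `event_chain`: list with `scenario`, `events`,
#'   `transition_probs`, `transition_bits`, `complete` (reached target
#'   length) and `stopped_early`.
#' @export
#' @examples
#' m <- fit_ngram(list(c("a", "b", "c"), c("a", "b", "d"), c("a", "b", "c")))
#' extract_chain(m, start = "a", length = 3, min_count = 1)
extract_chain <- function(model, start = "auto", length = 4L,
                          min_count = 8L) {
  stopifnot(inherits(model, "transition_model"))
  if (model$order != 2L) {
    stop("chain extraction is defined for bigram models", call. = FALSE)
  }
  if (length < 2L) stop("chain length must be >= 2", call. = FALSE)
  elig <- eligible_events(model, min_count)

  pick_best <- function(context, visited) {
    dist <- successor_distribution(model, context)
    cand <- setdiff(intersect(names(dist)[dist > 0], elig), visited)
    if (!base::length(cand)) return(NULL)
    p <- dist[cand]
    best <- sort(cand[p == max(p)])[1L]  # lexicographic tie-break
    list(label = best, prob = unname(dist[best]))
  }

  if (identical(start, "auto")) {
    first <- pick_best(BOS, character(0))
    if (is.null(first)) {
      stop("no eligible event follows the begin marker", call. = FALSE)
    }
    start <- first$label
  } else if (!start %in% elig) {
    stop("start event '", start, "' is not eligible (count < ", min_count,
         " or unknown)", call. = FALSE)
  }

  events <- start
  probs <- numeric(0)
  stopped_early <- FALSE
  while (base::length(events) < length) {
    nxt <- pick_best(events[base::length(events)], events)
    if (is.null(nxt)) { stopped_early <- TRUE; break }
    events <- c(events, nxt$label)
    probs <- c(probs, nxt$prob)
  }
  structure(list(scenario = model$scenario, events = events,
                 transition_probs = probs,
                 transition_bits = -log2(probs) + 0,
                 complete = base::length(events) == length,
                 stopped_early = stopped_early),
            class = "event_chain")
}

#' @export
print.event_chain <- function(x, ...) {
  cat("<event_chain> scenario:", x$scenario, "\n ",
      paste(x$events, collapse = " -> "), "\n")
  if (length(x$transition_probs)) {
    cat("  p:", paste(sprintf("%.3f", x$transition_probs), collapse = ", "),
        "\n")
  }
  if (x$stopped_early) cat("  (stopped early: no eligible successor)\n")
  invisible(x)
}

#' Build a stimulus specification from an event chain
#'
#' The first three chain events become the context story's events; the
#' fourth is the predictable target (by construction, each context event's
#' successor is its most likely eligible successor). `target_bits` is the
#' surprisal of the target given the last context event;
#' `mean_context_bits` is the mean surprisal over all chain transitions.
#' The unpredictable slot is filled later from human-proposed candidates
#' via [propose_unpredictable()].
#'
#' @param model the bigram `transition_model` the chain came from.
#' @param chain an `event_chain` with >= 4 events.
#' @param script_type scenario's script type, carried onto the spec.
#' @return A `stimulus_spec`: list with `scenario`, `context_events` (3),
#'   `target_predictable`, `target_unpredictable` (`NA` until chosen),
#'   `target_bits`, `target_percent`, `mean_context_bits`, `script_type`.
#' @export
build_stimulus <- function(model, chain, script_type = NA_character_) {
  stopifnot(inherits(model, "transition_model"),
            inherits(chain, "event_chain"))
  if (length(chain$events) < 4L) {
    stop("stimulus construction needs a chain of >= 4 events ",
         "(3 context + target)", call. = FALSE)
  }
  ctx <- chain$events[1:3]
  target <- chain$events[4L]
  tb <- surprisal(model, ctx[3L], target)$bits
  mcb <- mean_surprisal(model, chain$events[1:4])$bits
  structure(list(scenario = chain$scenario,
                 context_events = ctx,
                 target_predictable = target,
                 target_unpredictable = NA_character_,
                 target_bits = tb,
                 target_percent = bits_to_percent(tb),
                 mean_context_bits = mcb,
                 script_type = script_type),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec> scenario:", x$scenario, "\n")
  cat("  context:", paste(x$context_events, collapse = " -> "), "\n")
  cat(sprintf("  predictable target: %s (%.3g bits, %.1f%%)\n",
              x$target_predictable, x$target_bits, x$target_percent))
  cat("  unpredictable target:",
      if (is.na(x$target_unpredictable)) "(unset)" else
        x$target_unpredictable, "\n")
  invisible(x)
}

#' Screen candidate unpredictable targets
#'
#' Keeps the candidates that either never occur in the script data or
#' have probability 0 after the given context under the (unsmoothed)
#' model. Plausibility of the survivors is a human judgment and is out of
#' scope; input order is preserved.
#'
#' @param model a bigram `transition_model` (MLE; smoothing would leave
#'   nothing with probability 0).
#' @param context the last context event label.
#' @param candidates non-empty character vector of candidate labels.
#' @return Character vector, the zero-probability subset of `candidates`.
#' @export
propose_unpredictable <- function(model, context, candidates) {
  stopifnot(inherits(model, "transition_model"))
  if (length(candidates) == 0L) {
    stop("no candidate unpredictable events supplied", call. = FALSE)
  }
  if (model$smoothing != "mle") {
    warning("smoothed model: no candidate has exact probability 0",
            call. = FALSE)
  }
  keep <- vapply(candidates, function(cand) {
    if (!cand %in% model$vocabulary) return(TRUE)   # absent from scenario
    transition_prob(model, context, cand) == 0
  }, logical(1))
  candidates[keep]
}

#' Summarize a set of stimulus specifications
#'
#' Bookkeeping over items: mean target surprisal and mean of the chains'
#' mean surprisal, in bits and as probability percentages. Infinite
#' values are excluded from the means and counted.
#'
#' @param specs list of `stimulus_spec` objects (>= 1).
#' @return List with `n`, `mean_target_bits`, `mean_target_percent`,
#'   `mean_context_bits`, `mean_context_percent`, `n_infinite_target`,
#'   `n_infinite_context`.
#' @export
stimulus_report <- function(specs) {
  if (inherits(specs, "stimulus_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("no stimulus specs", call. = FALSE)
  tb <- vapply(specs, function(s) s$target_bits, numeric(1))
  cb <- vapply(specs, function(s) s$mean_context_bits, numeric(1))
  fin_t <- tb[is.finite(tb)]
  fin_c <- cb[is.finite(cb)]
  list(
    n = length(specs),
    mean_target_bits = mean(fin_t),
    mean_target_percent = bits_to_percent(mean(fin_t)),
    mean_context_bits = mean(fin_c),
    mean_context_percent = bits_to_percent(mean(fin_c)),
    n_infinite_target = sum(is.infinite(tb)),
    n_infinite_context = sum(is.infinite(cb))
  )
}

#' Write chains / stimulus specs as delimited text and JSON
#'
#' @param x an `event_chain`, `stimulus_spec`, or list of either.
#' @param path output path; `.json` extension selects JSON, anything
#'   else TSV.
#' @return `path`, invisibly.
#' @export
write_chain <- function(x, path) {
  if (inherits(x, "event_chain") || inherits(x, "stimulus_spec")) x <- list(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lapply(x, unclass), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(seq_along(x), function(i) {
    el <- x[[i]]
    if (inherits(el, "event_chain")) {
      data.frame(id = i, kind = "chain", scenario = el$scenario,
                 events = paste(el$events, collapse = " -> "),
                 probs = paste(sprintf("%.6g", el$transition_probs),
                               collapse = ","),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = i, kind = "stimulus", scenario = el$scenario,
                 events = paste(c(el$context_events, el$target_predictable),
                                collapse = " -> "),
                 probs = sprintf("%.6g", el$target_bits),
                 stringsAsFactors = FALSE)
    }
  }))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
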