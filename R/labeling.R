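#' Parse result for one event description
#'
#' @param tokens ordered word tokens.
#' @param pos_tags one tag per token (coarse Penn-style: `VB`, `NN`, `DT`,
#'   `IN`, `CC`, `PRP`, `JJ`, `RB`).
#' @param head_verb_index index of the main verb, or `NA` if none found.
#' @param object_noun_index index of its post-verbal object noun (or
#'   pronoun), or `NA`.
#' @return A `parse_result` object.
#' @export
parse_result <- function(tokens, pos_tags, head_verb_index = NA_integer_,
                         object_noun_index = NA_integer_) {
  stopifnot(length(tokens) == length(pos_tags))
  chk <- function(i) {
    if (!is.na(i) && (i < 1L || i > length(tokens))) {
      stop("parse index out of range", call. = FALSE)
    }
    as.integer(i)
  }
  structure(list(tokens = as.character(tokens),
                 pos_tags = as.character(pos_tags),
                 head_verb_index = chk(head_verb_index),
                 object_noun_index = chk(object_noun_index)),
            class = "parse_result")
}

#' @export
print.parse_result <- function(x, ...) {
  cat("<parse_result>", paste(x$tokens, x$pos_tags, sep = "/",
                              collapse = " "), "\n")
  v <- x$head_verb_index
  o <- x$object_noun_index
  cat("  verb:", if (is.na(v)) "-" else x$tokens[v],
      " object:", if (is.na(o)) "-" else x$tokens[o], "\n")
  invisible(x)
}

tokenize_description <- function(text) {
  text <- squeeze_ws(text)
  toks <- strsplit(text, " ", fixed = TRUE)[[1L]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

tag_token <- function(tok) {
  w <- tolower(tok)
  lemma <- lemmatize(w)
  if (w %in% DETERMINERS) return("DT")
  if (w %in% PREPOSITIONS) return("IN")
  if (w %in% CONJUNCTIONS) return("CC")
  if (w %in% PRONOUNS) return("PRP")
  if (w %in% ADVERBS) return("RB")
  if (w %in% ADJECTIVES) return("JJ")
  if (lemma %in% SCRIPT_VERBS) return("VB")
  "NN"
}

#' Rule-based parse of an event description
#'
#' Deterministic heuristic parser for short, mostly imperative
#' event descriptions ("put water in a pot", "turn the stove on"). The
#' main verb is the first token whose lemma is in the built-in verb list;
#' failing that, a sentence-initial token that is not a determiner,
#' pronoun or preposition is taken as an imperative verb. The object is
#' the first noun or pronoun after the verb, skipping determiners,
#' adjectives and adverbs; a preposition or conjunction encountered first
#' means the direct object was elided and the object is absent. Never
#' fails on non-empty input.
#'
#' @param text raw event description (non-empty).
#' @return A [parse_result()].
#' @export
#' @examples
#' fallback_parse("put water in a pot")
#' fallback_parse("Pour in pan")   # object elided
fallback_parse <- function(text) {
  if (!nzchar(squeeze_ws(text))) {
    stop("cannot parse an empty description", call. = FALSE)
  }
  toks <- tokenize_description(text)
  tags <- vapply(toks, tag_token, character(1), USE.NAMES = FALSE)

  verb_i <- which(tags == "VB")[1L]
  if (is.na(verb_i) && length(toks) >= 1L &&
      !tags[1L] %in% c("DT", "PRP", "IN", "CC")) {
    # verb-first imperative with an out-of-lexicon verb
    verb_i <- 1L
    tags[1L] <- "VB"
  }

  obj_i <- NA_integer_
  if (!is.na(verb_i)) {
    j <- verb_i + 1L
    while (j <= length(toks)) {
      tg <- tags[j]
      if (tg %in% c("DT", "JJ", "RB")) { j <- j + 1L; next }
      if (tg %in% c("IN", "CC")) break   # elided object, PP follows
      if (tg %in% c("NN", "PRP")) { obj_i <- j }
      break
    }
  }
  parse_result(toks, tags, verb_i, obj_i)
}

#' Parse an event description through a pluggable provider
#'
#' Parsing is a provider contract, not a bundled statistical model: any
#' function taking the raw text and returning a [parse_result()] (tokens,
#' tags, head verb index, object noun index) can stand behind it.
#' [fallback_parse()] is the deterministic default.
#'
#' @param text raw event description (non-empty).
#' @param parser a function `(text) -> parse_result`.
#' @return A [parse_result()].
#' @export
parse_description <- function(text, parser = fallback_parse) {
  if (!nzchar(squeeze_ws(text))) {
    stop("cannot parse an empty description", call. = FALSE)
  }
  res <- tryCatch(parser(text), error = function(e) {
    stop("parse unavailable for description: \"", text, "\" (",
         conditionMessage(e), ")", call. = FALSE)
  })
  if (!inherits(res, "parse_result")) {
    stop("parser provider must return a parse_result", call. = FALSE)
  }
  res
}

#' Canonical event label
#'
#' An event label is the main verb of the description plus its post-verbal
#' noun, lowercase lemmas, rendered as `"verb noun"`. A missing object is
#' the `PLACEHOLDER` sentinel until resolved by normalization.
#'
#' @param verb verb lemma (non-empty).
#' @param noun noun lemma, or the placeholder sentinel.
#' @param source_text originating raw description, kept for audit.
#' @return An `event_label` object with fields `verb`, `noun`,
#'   `source_text` and `label` (the rendered string).
#' @export
#' @examples
#' event_label("pour", "egg")
event_label <- function(verb, noun = PLACEHOLDER, source_text = NA_character_) {
  verb <- tolower(trimws(verb))
  if (!nzchar(verb)) stop("event label needs a non-empty verb", call. = FALSE)
  if (noun != PLACEHOLDER) noun <- tolower(trimws(noun))
  structure(list(verb = verb, noun = noun, source_text = source_text,
                 label = paste(verb, noun)),
            class = "event_label")
}

#' @export
print.event_label <- function(x, ...) {
  cat("<event_label>", x$label, "\n")
  invisible(x)
}

#' @export
format.event_label <- function(x, ...) x$label

#' Extract a verb-noun label from a parse
#'
#' @param parse a [parse_result()].
#' @return An [event_label()] with lemmatized, lowercased verb and noun;
#'   the noun is the placeholder sentinel when no object was found.
#'   Errors (for the manual queue) when the parse has no head verb.
#' @export
#' @examples
#' extract_label(fallback_parse("Pour eggs into the pan"))
extract_label <- function(parse) {
  stopifnot(inherits(parse, "parse_result"))
  if (is.na(parse$head_verb_index)) {
    stop("no head verb found in: \"", paste(parse$tokens, collapse = " "),
         "\" (routed to manual queue)", call. = FALSE)
  }
  verb <- lemmatize(parse$tokens[parse$head_verb_index])
  noun <- if (is.na(parse$object_noun_index)) PLACEHOLDER else
    lemmatize(parse$tokens[parse$object_noun_index])
  event_label(verb, noun,
              source_text = paste(parse$tokens, collapse = " "))
}

#' Normalize an event label against a lexicon
#'
#' Application order: pronoun resolution (pronoun map), placeholder
#' resolution (default-object map, keyed by verb), synonym pooling on verb
#' and noun, then whole-label event mapping. The result is a fixed point:
#' normalizing twice equals normalizing once. A placeholder noun with no
#' default-object entry passes through unchanged (callers record it as
#' unresolved).
#'
#' @param label an [event_label()].
#' @param lexicon a [normalization_lexicon()].
#' @param scenario scenario name used to scope lexicon lookups.
#' @return A normalized [event_label()].
#' @export
normalize_label <- function(label, lexicon, scenario) {
  stopifnot(inherits(label, "event_label"),
            inherits(lexicon, "normalization_lexicon"))
  verb <- label$verb
  noun <- label$noun

  if (noun %in% PRONOUNS) {
    hit <- lexicon_lookup(lexicon$pronouns, "pronoun", "noun", scenario, noun)
    if (!is.na(hit)) noun <- hit
  }
  if (noun == PLACEHOLDER) {
    hit <- lexicon_lookup(lexicon$default_objects, "verb", "noun",
                          scenario, verb)
    if (!is.na(hit)) noun <- hit
  }
  syn <- function(w) {
    hit <- lexicon_lookup(lexicon$synonyms, "from", "to", scenario, w)
    if (is.na(hit)) w else hit
  }
  verb <- syn(verb)
  if (noun != PLACEHOLDER) noun <- syn(noun)

  lab <- paste(verb, noun)
  hit <- lexicon_lookup(lexicon$events, "from", "to", scenario, lab)
  if (!is.na(hit)) {
    parts <- strsplit(hit, " ", fixed = TRUE)[[1L]]
    verb <- parts[1L]
    noun <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else
      PLACEHOLDER
  }
  event_label(verb, noun, source_text = label$source_text)
}

#' Label a whole corpus
#'
#' Runs parse -> extract -> normalize over every event description,
#' preserving ESD order and length (no silent drops: descriptions that
#' fail parsing or keep a placeholder are carried through and collected in
#' the uniqueness report). Deterministic for a fixed parser.
#'
#' @param corpus a `script_corpus`.
#' @param lexicon a [normalization_lexicon()].
#' @param parser parsing provider, [fallback_parse()] by default.
#' @return A `labeled_corpus`: list with
#'   \describe{
#'     \item{scenario}{scenario name.}
#'     \item{labels}{data frame `esd_id`, `position`, `label`, `verb`,
#'       `noun`, `text`.}
#'     \item{sequences}{named list of label-string vectors, one per ESD.}
#'     \item{report}{a `uniqueness_report` (see Details).}
#'   }
#'
#' @details The uniqueness report mirrors the manual screening step:
#'   `unresolved_placeholders` (labels whose object never resolved),
#'   `manual_queue` (descriptions with no identifiable verb),
#'   `merge_candidates` (disjoint groups of distinct labels sharing a verb
#'   with nouns within edit distance 2, or sharing a noun with verbs within
#'   edit distance 2 - a cheap high-recall screen), and the participant
#'   (noun) and action (verb) inventories.
#' @export
label_corpus <- function(corpus, lexicon = normalization_lexicon(),
                         parser = fallback_parse) {
  stopifnot(inherits(corpus, "script_corpus"))
  ev <- corpus$events
  n <- nrow(ev)
  verbs <- character(n); nouns <- character(n); labs <- character(n)
  queue <- character(0)
  for (i in seq_len(n)) {
    lab <- tryCatch(
      normalize_label(extract_label(parse_description(ev$text[i], parser)),
                      lexicon, corpus$scenario),
      error = function(e) NULL)
    if (is.null(lab)) {
      queue <- c(queue, ev$text[i])
      # carried through under the sentinel so sequence lengths are stable
      lab <- event_label("UNPARSED", PLACEHOLDER, source_text = ev$text[i])
    }
    verbs[i] <- lab$verb; nouns[i] <- lab$noun; labs[i] <- lab$label
  }
  labels <- data.frame(esd_id = ev$esd_id, position = ev$position,
                       label = labs, verb = verbs, noun = nouns,
                       text = ev$text, stringsAsFactors = FALSE)
  sequences <- split(labels$label,
                     factor(labels$esd_id, levels = unique(labels$esd_id)))
  report <- uniqueness_report(labels, manual_queue = queue)
  structure(list(scenario = corpus$scenario, labels = labels,
                 sequences = sequences, report = report),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat("<labeled_corpus> scenario:", x$scenario, "-",
      length(x$sequences), "ESDs,",
      length(unique(x$labels$label)), "distinct labels\n")
  if (length(x$report$unresolved_placeholders)) {
    cat("  unresolved placeholders:",
        length(x$report$unresolved_placeholders), "\n")
  }
  if (nrow(x$report$merge_candidates)) {
    cat("  merge candidate groups:",
        length(unique(x$report$merge_candidates$group)), "\n")
  }
  invisible(x)
}

uniqueness_report <- function(labels, manual_queue = character(0)) {
  distinct <- unique(labels[, c("label", "verb", "noun")])
  unresolved <- unique(labels$label[labels$noun == PLACEHOLDER])
  groups <- find_merge_candidates(distinct)
  structure(list(
    merge_candidates = groups,
    unresolved_placeholders = unresolved,
    manual_queue = manual_queue,
    participant_inventory = sort(unique(distinct$noun[
      distinct$noun != PLACEHOLDER])),
    action_inventory = sort(unique(distinct$verb))
  ), class = "uniqueness_report")
}

# Disjoint groups of distinct labels likely describing one event:
# same verb + nouns within edit distance 2, or same noun + verbs within
# edit distance 2. Grouping is by connected components via union-find.
find_merge_candidates <- function(distinct) {
  m <- nrow(distinct)
  out <- data.frame(group = integer(0), label = character(0))
  if (m < 2L) return(out)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  close_pair <- function(i, j) {
    (distinct$verb[i] == distinct$verb[j] &&
       distinct$noun[i] != PLACEHOLDER && distinct$noun[j] != PLACEHOLDER &&
       adist(distinct$noun[i], distinct$noun[j]) <= 2) ||
      (distinct$noun[i] == distinct$noun[j] &&
         distinct$noun[i] != PLACEHOLDER &&
         adist(distinct$verb[i], distinct$verb[j]) <= 2)
  }
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (close_pair(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  keep <- roots %in% roots[duplicated(roots)]
  if (!any(keep)) return(out)
  grp <- as.integer(factor(roots[keep]))
  data.frame(group = grp, label = distinct$label[keep],
             stringsAsFactors = FALSE)[order(grp), ]
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat("<uniqueness_report>\n")
  cat("  actions:", length(x$action_inventory),
      " participants:", length(x$participant_inventory), "\n")
  cat("  unresolved placeholders:", length(x$unresolved_placeholders),
      " manual queue:", length(x$manual_queue), "\n")
  cat("  merge candidate groups:",
      if (nrow(x$merge_candidates)) length(unique(x$merge_candidates$group))
      else 0L, "\n")
  invisible(x)
}
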