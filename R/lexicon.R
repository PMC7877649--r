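# Closed-class word lists for the rule-based parser and the lemmatizer.
# These are deliberately small: the parser only needs to find an imperative
# main verb and its bare direct object in short crowd-sourced descriptions.

DETERMINERS <- c("the", "a", "an", "some", "any", "all", "each", "every",
                 "this", "that", "these", "those", "my", "your", "his",
                 "her", "its", "our", "their", "no", "another", "both",
                 "few", "several", "many", "much", "more", "most", "enough")

PREPOSITIONS <- c("in", "into", "on", "onto", "at", "to", "from", "with",
                  "without", "for", "of", "over", "under", "off", "by",
                  "about", "through", "until", "till", "before", "after",
                  "during", "near", "behind", "up", "down", "out", "inside",
                  "outside", "around", "between", "onto", "upon")

CONJUNCTIONS <- c("and", "or", "but", "so", "then", "when", "while", "if",
                  "because", "as", "that")

PRONOUNS <- c("it", "them", "him", "her", "me", "us", "you", "they", "he",
              "she", "we", "i", "everything", "something", "anything",
              "itself", "themselves", "yourself")

ADVERBS <- c("well", "slowly", "quickly", "carefully", "gently", "again",
             "now", "first", "next", "finally", "together", "thoroughly",
             "completely", "done", "once", "twice", "there", "here",
             "away", "back", "not")

ADJECTIVES <- c("hot", "cold", "warm", "boiling", "large", "small", "big",
                "little", "clean", "dirty", "fresh", "dry", "wet", "new",
                "old", "empty", "full", "right", "whole", "correct",
                "desired", "necessary", "appropriate", "remaining")

# Verbs common in everyday-activity scripts (imperative base forms).
SCRIPT_VERBS <- c("put", "turn", "boil", "pour", "wait", "look", "get",
                  "cook", "combine", "set", "take", "fill", "add", "heat",
                  "stir", "drain", "serve", "wash", "dry", "crack", "beat",
                  "whisk", "mix", "place", "remove", "open", "close", "buy",
                  "pay", "go", "enter", "leave", "choose", "read", "check",
                  "bring", "drive", "order", "call", "eat", "drink",
                  "prepare", "cut", "chop", "peel", "grab", "gather",
                  "select", "pick", "find", "clean", "rinse", "season",
                  "taste", "cover", "uncover", "strain", "melt", "fry",
                  "bake", "measure", "weigh", "unpack", "pack", "store",
                  "throw", "toss", "sprinkle", "spread", "flip", "lower",
                  "raise", "reduce", "simmer", "let", "allow", "make",
                  "start", "stop", "finish", "use", "ask", "tell", "give",
                  "return", "sit", "stand", "walk", "ride", "board",
                  "exit", "push", "pull", "press", "switch", "plug",
                  "light", "dump", "empty", "scramble", "grate", "slice",
                  "stack", "load", "unload", "carry", "move", "adjust")

# Irregular lemmas the suffix rules would get wrong.
LEMMA_EXCEPTIONS <- c(
  children = "child", dishes = "dish", knives = "knife", leaves = "leaf",
  loaves = "loaf", shelves = "shelf", men = "man", women = "woman",
  feet = "foot", teeth = "tooth", mice = "mouse", geese = "goose",
  potatoes = "potato", tomatoes = "tomato", glasses = "glass",
  boxes = "box", matches = "match", sauces = "sauce", recipes = "recipe",
  noodles = "noodle", groceries = "grocery", clothes = "clothes",
  scissors = "scissors", pasta = "pasta", water = "water", gets = "get",
  puts = "put", goes = "go", does = "do", has = "have", is = "be",
  was = "be", are = "be", made = "make", took = "take", got = "get",
  went = "go", left = "leave", cutting = "cut", putting = "put",
  getting = "get", stirring = "stir", chopping = "chop", sitting = "sit",
  stopped = "stop", dropped = "drop"
)

#' Lemmatize tokens
#'
#' Deterministic dictionary-plus-rules lemmatizer: lowercases, applies a
#' small irregular-form dictionary, then strips plural/3sg `-s` and common
#' verbal suffixes (`-ies` to `y`, `-es` after sibilants, `-ing`/`-ed` with
#' a vowel check). Intended for the short, mostly imperative event
#' descriptions of script corpora, not for general text.
#'
#' @param tokens character vector of word tokens.
#' @return Character vector of lowercase lemmas, same length.
#' @export
#' @examples
#' lemmatize(c("Noodles", "dishes", "eggs", "boils", "contents"))
lemmatize <- function(tokens) {
  x <- tolower(tokens)
  vapply(x, function(w) {
    if (w %in% names(LEMMA_EXCEPTIONS)) return(unname(LEMMA_EXCEPTIONS[w]))
    if (nchar(w) <= 3L) return(w)
    if (grepl("ies$", w)) return(sub("ies$", "y", w))
    if (grepl("(ss|us|is)$", w)) return(w)
    if (grepl("(ches|shes|xes|zes|ses)$", w)) return(sub("es$", "", w))
    if (grepl("ing$", w) && nchar(w) > 5L &&
        grepl("[aeiou]", sub("ing$", "", w))) {
      stem <- sub("ing$", "", w)
      # "boiling" -> "boil"; restore final e for "-Cing" stems like "serving"
      if (stem %in% SCRIPT_VERBS) return(stem)
      if (paste0(stem, "e") %in% SCRIPT_VERBS) return(paste0(stem, "e"))
      return(w)
    }
    if (grepl("s$", w)) return(sub("s$", "", w))
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Normalization lexicon
#'
#' Machine-readable replacement for the manual curation step that turns raw
#' verb-noun pairs into unique canonical event labels. Four scenario-scoped
#' maps (scenario `"*"` applies everywhere):
#' \describe{
#'   \item{synonyms}{surface lemma -> canonical participant lemma
#'     (e.g. skillet -> pan), applied to verbs and nouns.}
#'   \item{events}{raw label string -> canonical label string, applied last
#'     (pools syntactically differing descriptions of one event).}
#'   \item{pronouns}{pronoun -> canonical noun for that scenario.}
#'   \item{default_objects}{verb -> canonical noun used when the object was
#'     elided (placeholder resolution).}
#' }
#' Canonical values must be fixed points: applying a map twice equals
#' applying it once, and no canonical event label maps onward.
#'
#' @param synonyms data frame with columns `scenario`, `from`, `to`.
#' @param events data frame with columns `scenario`, `from`, `to` (label
#'   strings, `"verb noun"`).
#' @param pronouns data frame with columns `scenario`, `pronoun`, `noun`.
#' @param default_objects data frame with columns `scenario`, `verb`, `noun`.
#' @return A `normalization_lexicon` object.
#' @export
#' @examples
#' lex <- normalization_lexicon(
#'   synonyms = data.frame(scenario = "*", from = "skillet", to = "pan"))
#' normalize_label(event_label("pour", "skillet"), lex, "eggs")
normalization_lexicon <- function(synonyms = NULL, events = NULL,
                                  pronouns = NULL, default_objects = NULL) {
  empty <- function(cols) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  fix <- function(tab, cols) {
    if (is.null(tab) || nrow(as.data.frame(tab)) == 0L) return(empty(cols))
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    missing_cols <- setdiff(cols, names(tab))
    if (length(missing_cols)) {
      stop("lexicon table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    tab[cols] <- lapply(tab[cols], function(x) trimws(as.character(x)))
    tab[, cols]
  }
  obj <- structure(list(
    synonyms = fix(synonyms, c("scenario", "from", "to")),
    events = fix(events, c("scenario", "from", "to")),
    pronouns = fix(pronouns, c("scenario", "pronoun", "noun")),
    default_objects = fix(default_objects, c("scenario", "verb", "noun"))
  ), class = "normalization_lexicon")
  validate_lexicon(obj)
  obj
}

validate_lexicon <- function(lex) {
  # fixed-point invariant: no map output is another entry's input
  chain <- function(tab, from, to, what) {
    bad <- tab[[to]] %in% tab[[from]][tab[[from]] != tab[[to]]]
    onward <- tab[[to]][bad]
    onward <- onward[vapply(onward, function(v) {
      tab[[to]][match(v, tab[[from]])] != v
    }, logical(1))]
    if (length(onward)) {
      stop("lexicon ", what, " map is not a fixed point: '", onward[1L],
           "' maps onward", call. = FALSE)
    }
  }
  chain(lex$synonyms, "from", "to", "synonym")
  chain(lex$events, "from", "to", "event")
  invisible(lex)
}

#' @export
print.normalization_lexicon <- function(x, ...) {
  cat("<normalization_lexicon>",
      nrow(x$synonyms), "synonyms,",
      nrow(x$events), "event mappings,",
      nrow(x$pronouns), "pronouns,",
      nrow(x$default_objects), "default objects\n")
  invisible(x)
}

lexicon_lookup <- function(tab, key_col, val_col, scenario, key) {
  hit <- tab[[key_col]] == key &
    (tab$scenario == scenario | tab$scenario == "*")
  if (!any(hit)) return(NA_character_)
  # scenario-specific entries shadow wildcard entries
  sub <- tab[hit, , drop = FALSE]
  specific <- sub$scenario == scenario
  if (any(specific)) sub[[val_col]][specific][1L] else sub[[val_col]][1L]
}

#' Read / write a normalization lexicon directory
#'
#' A lexicon directory holds up to four TSV files: `synonyms.tsv`
#' (`scenario`, `from`, `to`), `events.tsv` (`scenario`, `from`, `to`),
#' `pronouns.tsv` (`scenario`, `pronoun`, `noun`) and
#' `default_objects.tsv` (`scenario`, `verb`, `noun`). Missing files yield
#' empty maps.
#'
#' @param dir directory path.
#' @return `read_lexicon`: a `normalization_lexicon`. `write_lexicon`:
#'   `dir`, invisibly.
#' @export
read_lexicon <- function(dir) {
  if (!dir.exists(dir)) stop("lexicon directory not found: ", dir,
                             call. = FALSE)
  rd <- function(file) {
    p <- file.path(dir, file)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  normalization_lexicon(
    synonyms = rd("synonyms.tsv"), events = rd("events.tsv"),
    pronouns = rd("pronouns.tsv"), default_objects = rd("default_objects.tsv")
  )
}

#' @rdname read_lexicon
#' @param lexicon a `normalization_lexicon`.
#' @export
write_lexicon <- function(lexicon, dir) {
  stopifnot(inherits(lexicon, "normalization_lexicon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, file) {
    write.table(tab, file.path(dir, file), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  wr(lexicon$synonyms, "synonyms.tsv")
  wr(lexicon$events, "events.tsv")
  wr(lexicon$pronouns, "pronouns.tsv")
  wr(lexicon$default_objects, "default_objects.tsv")
  invisible(dir)
}
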