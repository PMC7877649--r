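#' Event-sequence description corpora
#'
#' A `script_corpus` holds one scenario's crowd-sourced event-sequence
#' descriptions (ESDs): each ESD is one contributor's ordered list of short
#' textual event descriptions. The object is a list with fields
#' `scenario` (name string), `title` (human-readable script title),
#' `script_type` (`"two_participant"`, `"adapted"`, or `NA`), and `events`,
#' a data frame with columns `esd_id`, `position` (1-based, consecutive
#' within an ESD), `text`, and `contributor`.
#'
#' @param scenario scenario name, e.g. `"cooking pasta"`.
#' @param events data frame with columns `esd_id`, `position`, `text` and
#'   optionally `contributor`.
#' @param script_type `"two_participant"` (the scenario natively involves two
#'   interlocutors), `"adapted"` (a second participant was introduced), or
#'   `NA` when unknown.
#' @param title human-readable title; defaults to the scenario name.
#' @return A `script_corpus` object.
#' @seealso [read_corpus_xml()], [read_corpus_table()], [corpus_summary()]
#' @export
#' @examples
#' ev <- data.frame(esd_id = "e1", position = 1:2,
#'                  text = c("put water in a pot", "turn the stove on"))
#' script_corpus("cooking pasta", ev)
script_corpus <- function(scenario, events, script_type = NA_character_,
                          title = scenario) {
  stopifnot(is.character(scenario), length(scenario) == 1L)
  if (!nzchar(trimws(scenario))) {
    stop("scenario name must be non-empty", call. = FALSE)
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("esd_id", "position", "text")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(events$contributor)) events$contributor <- NA_character_
  events$contributor <- as.character(events$contributor)
  events$esd_id <- as.character(events$esd_id)
  events$position <- as.integer(events$position)
  events$text <- squeeze_ws(events$text)
  events <- events[order(match(events$esd_id, unique(events$esd_id)),
                         events$position),
                   c("esd_id", "position", "text", "contributor")]
  rownames(events) <- NULL
  obj <- structure(
    list(scenario = scenario, title = title,
         script_type = script_type, events = events),
    class = "script_corpus"
  )
  validate_corpus(obj)
  obj
}

# Trim surrounding whitespace and collapse internal runs to a single space.
# Case is preserved at this layer; folding happens during labeling.
squeeze_ws <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

validate_corpus <- function(corpus) {
  ev <- corpus$events
  if (nrow(ev) == 0L) {
    stop("corpus '", corpus$scenario, "' contains no events", call. = FALSE)
  }
  if (any(!nzchar(ev$text))) {
    bad <- ev$esd_id[!nzchar(ev$text)][1L]
    stop("empty event description in ESD '", bad, "'", call. = FALSE)
  }
  st <- corpus$script_type
  if (!is.na(st) && !st %in% c("two_participant", "adapted")) {
    stop("script_type must be 'two_participant', 'adapted' or NA",
         call. = FALSE)
  }
  for (id in unique(ev$esd_id)) {
    pos <- ev$position[ev$esd_id == id]
    if (!identical(as.integer(pos), seq_along(pos))) {
      stop("positions in ESD '", id, "' are not consecutive from 1: ",
           paste(pos, collapse = ","), call. = FALSE)
    }
  }
  invisible(corpus)
}

#' @export
print.script_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat("<script_corpus> scenario:", x$scenario, "\n")
  cat("  script_type:", x$script_type, " title:", x$title, "\n")
  cat(sprintf("  %d ESDs, %d event descriptions (lengths %d-%d, mean %.1f)\n",
              s$esd_count, s$event_count, s$min_length, s$max_length,
              s$mean_length))
  invisible(x)
}

#' Split a corpus into per-ESD description vectors
#'
#' @param corpus a `script_corpus`.
#' @return Named list of character vectors, one per ESD, in corpus order.
#' @export
corpus_sequences <- function(corpus) {
  stopifnot(inherits(corpus, "script_corpus"))
  ev <- corpus$events
  split(ev$text, factor(ev$esd_id, levels = unique(ev$esd_id)))
}

#' Read an ESD corpus from XML
#'
#' The dialect: a root `<scripts>` element (or a bare `<script>`) containing
#' `<script scenario="..." type="..." title="...">` elements, each holding
#' `<esd id="..." contributor="...">` elements whose ordered `<event>`
#' children carry the raw descriptions (an optional `position` attribute is
#' checked against document order).
#'
#' @param path path to an XML file.
#' @return A `script_corpus`, or a named list of them when the file holds
#'   several scenarios.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".xml")
#' writeLines(c('<scripts><script scenario="demo"><esd id="a">',
#'              '<event>put water in a pot</event>',
#'              '<event>boil the water</event></esd></script></scripts>'), tf)
#' read_corpus_xml(tf)
read_corpus_xml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)  # malformed XML: xml2 error names the line
  root <- xml2::xml_name(doc)
  nodes <- if (root == "script") list(doc) else xml2::xml_find_all(doc, ".//script")
  if (length(nodes) == 0L) stop("no <script> elements in ", path, call. = FALSE)
  corpora <- lapply(nodes, xml_to_corpus)
  names(corpora) <- vapply(corpora, function(cp) cp$scenario, character(1))
  if (length(corpora) == 1L) corpora[[1L]] else corpora
}

xml_to_corpus <- function(node) {
  scenario <- xml2::xml_attr(node, "scenario")
  if (is.na(scenario) || !nzchar(trimws(scenario))) {
    stop("<script> element without a scenario attribute", call. = FALSE)
  }
  type <- xml2::xml_attr(node, "type")
  title <- xml2::xml_attr(node, "title")
  esds <- xml2::xml_find_all(node, "./esd")
  if (length(esds) == 0L) stop("scenario '", scenario, "' has no ESDs",
                               call. = FALSE)
  ids <- xml2::xml_attr(esds, "id")
  ids[is.na(ids)] <- paste0("esd", seq_along(esds))[is.na(ids)]
  if (anyDuplicated(ids)) {
    stop("duplicate esd_id in scenario '", scenario, "': ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  rows <- lapply(seq_along(esds), function(i) {
    evs <- xml2::xml_find_all(esds[[i]], "./event")
    if (length(evs) == 0L) stop("ESD '", ids[i], "' has no events",
                                call. = FALSE)
    pos_attr <- xml2::xml_attr(evs, "position")
    if (!all(is.na(pos_attr)) &&
        !identical(as.integer(pos_attr), seq_along(evs))) {
      stop("position attributes in ESD '", ids[i],
           "' disagree with document order", call. = FALSE)
    }
    data.frame(esd_id = ids[i], position = seq_along(evs),
               text = xml2::xml_text(evs),
               contributor = xml2::xml_attr(esds[[i]], "contributor"),
               stringsAsFactors = FALSE)
  })
  script_corpus(scenario, do.call(rbind, rows),
                script_type = if (is.na(type)) NA_character_ else type,
                title = if (is.na(title)) scenario else title)
}

#' Write an ESD corpus to XML
#'
#' @param corpus a `script_corpus` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_xml <- function(corpus, path) {
  corpora <- if (inherits(corpus, "script_corpus")) list(corpus) else corpus
  doc <- xml2::xml_new_root("scripts")
  for (cp in corpora) {
    stopifnot(inherits(cp, "script_corpus"))
    sc <- xml2::xml_add_child(doc, "script", scenario = cp$scenario,
                              title = cp$title)
    if (!is.na(cp$script_type)) xml2::xml_set_attr(sc, "type", cp$script_type)
    for (id in unique(cp$events$esd_id)) {
      sub <- cp$events[cp$events$esd_id == id, ]
      esd <- xml2::xml_add_child(sc, "esd", id = id)
      if (!is.na(sub$contributor[1L])) {
        xml2::xml_set_attr(esd, "contributor", sub$contributor[1L])
      }
      for (j in seq_len(nrow(sub))) {
        xml2::xml_add_child(esd, "event", sub$text[j],
                            position = as.character(sub$position[j]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an ESD corpus from delimited text
#'
#' The tabular dialect is the canonical fixture format: a TSV/CSV with
#' header columns `scenario`, `esd_id`, `position`, `text` (and optional
#' `contributor`, `script_type`, `title`). Round-trips with
#' [write_corpus_table()].
#'
#' @param path path to a delimited file.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return A `script_corpus`, or a named list of them for multi-scenario
#'   tables.
#' @export
read_corpus_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", encoding = "UTF-8")
  req <- c("scenario", "esd_id", "position", "text")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("corpus table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  corpora <- lapply(split(tab, tab$scenario), function(sub) {
    script_corpus(
      scenario = sub$scenario[1L],
      events = sub[, intersect(c("esd_id", "position", "text", "contributor"),
                               names(sub))],
      script_type = if ("script_type" %in% names(sub) &&
                        !is.na(sub$script_type[1L]) && nzchar(sub$script_type[1L]))
        sub$script_type[1L] else NA_character_,
      title = if ("title" %in% names(sub) && nzchar(sub$title[1L]))
        sub$title[1L] else sub$scenario[1L]
    )
  })
  if (length(corpora) == 1L) corpora[[1L]] else corpora
}

#' Write an ESD corpus as delimited text
#'
#' @inheritParams write_corpus_xml
#' @param sep field separator, `"\t"` by default.
#' @return `path`, invisibly.
#' @export
write_corpus_table <- function(corpus, path, sep = "\t") {
  corpora <- if (inherits(corpus, "script_corpus")) list(corpus) else corpus
  rows <- do.call(rbind, lapply(corpora, function(cp) {
    cbind(scenario = cp$scenario, cp$events,
          script_type = cp$script_type, title = cp$title)
  }))
  write.table(rows, path, sep = sep, row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize an ESD corpus
#'
#' @param corpus a `script_corpus`.
#' @return A list with `scenario`, `esd_count`, `event_count`, `mean_length`,
#'   `min_length`, `max_length` and `distinct_descriptions` (distinct raw
#'   description strings).
#' @export
#' @examples
#' ev <- data.frame(esd_id = rep(c("a", "b"), c(2, 3)),
#'                  position = c(1:2, 1:3),
#'                  text = c("x", "y", "x", "y", "z"))
#' corpus_summary(script_corpus("demo", ev))
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "script_corpus"))
  lens <- lengths(corpus_sequences(corpus))
  list(
    scenario = corpus$scenario,
    esd_count = length(lens),
    event_count = nrow(corpus$events),
    mean_length = mean(lens),
    min_length = min(lens),
    max_length = max(lens),
    distinct_descriptions = length(unique(corpus$events$text))
  )
}
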