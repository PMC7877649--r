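#' Latin-square assignment for a 2 x 2 rating experiment
#'
#' Assigns every subject every item in exactly one of the four
#' Sententiality x Predictability conditions, rotating conditions across
#' four lists so each subject sees `n_items / 4` items per condition.
#'
#' @param n_subjects number of subjects (multiple of 4 recommended).
#' @param n_items number of items (multiple of 4 required).
#' @return Data frame with `subject`, `item`, `list`, `sententiality`
#'   (`"sentence"`/`"fragment"`), `predictability`
#'   (`"predictable"`/`"unpredictable"`).
#' @export
latin_square_design <- function(n_subjects = 48L, n_items = 24L) {
  if (n_items %% 4L != 0L) {
    stop("n_items must be a multiple of 4 for the 2 x 2 Latin square",
         call. = FALSE)
  }
  conds <- expand.grid(
    sententiality = c("sentence", "fragment"),
    predictability = c("predictable", "unpredictable"),
    stringsAsFactors = FALSE)
  grid <- expand.grid(subject = seq_len(n_subjects), item = seq_len(n_items))
  grid$list <- (grid$subject - 1L) %% 4L + 1L
  ci <- (grid$item - 1L + grid$list - 1L) %% 4L + 1L
  grid$sententiality <- conds$sententiality[ci]
  grid$predictability <- conds$predictability[ci]
  grid[base::order(grid$subject, grid$item), ]
}

#' Simulation specification for Likert rating tables
#'
#' Defines the generating ordinal mixed model: sum-coded (-1, +1) fixed
#' effects on a latent logistic scale, independent normal random
#' intercepts/slopes by subject and by item, and ordered thresholds
#' cutting the latent value into the 7 response categories.
#'
#' Default fixed effects are the effect sizes of the accompanying
#' acceptability case study (fragments and unpredictable targets lower
#' ratings; their interaction softens the sentence preference for
#' predictable events; familiarity amplifies the predictability
#' contrast); terms not listed default to zero.
#'
#' @param n_subjects,n_items design size; defaults 48 and 24.
#' @param fixed_effects named numeric vector over the term vocabulary
#'   `sententiality`, `predictability`, `script_type`, `position`,
#'   `familiarity` and `:`-interactions thereof.
#' @param random_sds named numeric vector; names are
#'   `<group>_<term>` with group `subject` or `item` and term
#'   `intercept` or a fixed-term name.
#' @param thresholds strictly increasing cutpoints; 6 of them for the
#'   7-point scale.
#' @param n_controls ungrammatical control trials per subject (rated via
#'   a strongly negative latent shift), for the exclusion-rule pipeline.
#' @param control_shift latent shift of control trials.
#' @param n_missing_familiarity number of scenarios whose familiarity
#'   score is withheld (emulating questionnaire loss); default 0.
#' @return A `rating_sim_spec`.
#' @export
rating_sim_spec <- function(n_subjects = 48L, n_items = 24L,
                            fixed_effects = default_rating_effects(),
                            random_sds = c(subject_intercept = 1,
                                           subject_sententiality = 0.5,
                                           item_intercept = 0.5,
                                           item_sententiality = 0.25),
                            thresholds = seq(-2.5, 2.5, by = 1),
                            n_controls = 5L, control_shift = -4,
                            n_missing_familiarity = 0L) {
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (length(thresholds) != 6L) {
    stop("a 7-point scale needs 6 thresholds", call. = FALSE)
  }
  if (any(random_sds < 0)) stop("random-effect SDs must be >= 0",
                                call. = FALSE)
  known <- c("sententiality", "predictability", "script_type", "position",
             "familiarity")
  for (nm in names(fixed_effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (!all(parts %in% known)) {
      stop("unknown fixed-effect term: ", nm, call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_items = as.integer(n_items),
                 fixed_effects = fixed_effects, random_sds = random_sds,
                 thresholds = thresholds, n_controls = as.integer(n_controls),
                 control_shift = control_shift,
                 n_missing_familiarity = as.integer(n_missing_familiarity)),
            class = "rating_sim_spec")
}

#' Default generator effect sizes
#'
#' The latent-scale coefficients used by [rating_sim_spec()] unless
#' overridden: the case study's reported fixed effects, with unreported
#' terms at zero.
#'
#' @return Named numeric vector.
#' @export
default_rating_effects <- function() {
  c(sententiality = -0.958, predictability = -0.554,
    familiarity = -0.012, position = -0.021,
    "sententiality:predictability" = -0.22,
    "predictability:familiarity" = -0.206)
}

# Sum coding: the marked level carries +1.
code_sent <- function(x) ifelse(x == "fragment", 1, -1)
code_pred <- function(x) ifelse(x == "unpredictable", 1, -1)
code_stype <- function(x) ifelse(x == "adapted", 1, -1)

term_value <- function(term, cols) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  Reduce(`*`, lapply(parts, function(p) cols[[p]]))
}

#' Sample a Likert rating table from a known ordinal mixed model
#'
#' Generates trial-level 7-point ratings under the model of
#' [rating_sim_spec()]: latent value = sum-coded fixed effects + normal
#' random effects + standard logistic noise; the rating is the category
#' the thresholds assign. Items 1..n/2 are "two_participant" scenarios,
#' the rest "adapted". Presentation position is a per-subject random
#' permutation; familiarity is a per-subject-per-scenario 1-5 score whose
#' pooled z-transform enters the latent value. Ungrammatical control
#' trials (shifted far down the latent scale) are appended per subject.
#' Fully reproducible under `seed`.
#'
#' @param spec a [rating_sim_spec()].
#' @param design optional design data frame as from
#'   [latin_square_design()]; generated from the spec sizes by default.
#' @param seed integer seed.
#' @return A data frame (`rating_table` schema): `subject`, `item`,
#'   `scenario`, `rating`, `sententiality`, `predictability`,
#'   `script_type`, `position`, `familiarity_raw`, `is_control`,
#'   `control_kind`, plus attribute `truth` (the generating parameters
#'   and sampled random effects).
#' @export
#' @examples
#' head(sample_ratings(rating_sim_spec(n_subjects = 8, n_items = 8), seed = 1))
sample_ratings <- function(spec, design = NULL, seed = 1L) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  set.seed(seed)
  if (is.null(design)) {
    design <- latin_square_design(spec$n_subjects, spec$n_items)
  } else {
    tab <- table(design$subject, design$item)
    if (any(tab != 1L)) {
      stop("design must assign each subject each item exactly once",
           call. = FALSE)
    }
  }
  ns <- max(design$subject); ni <- max(design$item)

  d <- design
  d$scenario <- sprintf("scenario%02d", d$item)
  d$script_type <- ifelse(d$item <= ni / 2, "two_participant", "adapted")
  # presentation order: per-subject permutation
  d$position <- NA_integer_
  for (s in seq_len(ns)) {
    idx <- which(d$subject == s)
    d$position[idx] <- sample.int(length(idx))
  }
  # familiarity: subject-specific 1-5 score per scenario around a
  # scenario-level mean
  scen_mean <- rnorm(ni, mean = 4, sd = 0.6)
  fam <- matrix(pmin(5, pmax(1, round(rnorm(ns * ni, mean = rep(scen_mean,
                each = ns), sd = 0.8)))), nrow = ns)
  d$familiarity_raw <- fam[cbind(d$subject, d$item)]
  if (spec$n_missing_familiarity > 0L) {
    drop_items <- seq_len(spec$n_missing_familiarity)
    d$familiarity_raw[d$item %in% drop_items] <- NA_integer_
  }
  fam_z <- (d$familiarity_raw - mean(d$familiarity_raw, na.rm = TRUE)) /
    sd(d$familiarity_raw, na.rm = TRUE)
  fam_z[is.na(fam_z)] <- 0

  cols <- list(sententiality = code_sent(d$sententiality),
               predictability = code_pred(d$predictability),
               script_type = code_stype(d$script_type),
               position = d$position,
               familiarity = fam_z)
  eta <- rep(0, nrow(d))
  for (term in names(spec$fixed_effects)) {
    eta <- eta + spec$fixed_effects[[term]] * term_value(term, cols)
  }
  # random effects: independent, one SD per (group, term)
  ranef <- list()
  for (nm in names(spec$random_sds)) {
    sdv <- spec$random_sds[[nm]]
    grp <- sub("_.*$", "", nm)
    term <- sub("^[^_]+_", "", nm)
    nlev <- if (grp == "subject") ns else ni
    b <- rnorm(nlev, 0, sdv)
    ranef[[nm]] <- b
    lev <- if (grp == "subject") d$subject else d$item
    x <- if (term == "intercept") 1 else term_value(term, cols)
    eta <- eta + b[lev] * x
  }
  latent <- eta + rlogis(nrow(d))
  d$rating <- as.integer(1L + rowSums(outer(latent, spec$thresholds, `>`)))
  d$is_control <- FALSE
  d$control_kind <- NA_character_

  # ungrammatical controls
  if (spec$n_controls > 0L) {
    ctrl <- data.frame(
      subject = rep(seq_len(ns), each = spec$n_controls),
      item = NA_integer_, scenario = NA_character_,
      list = NA_integer_,
      sententiality = NA_character_, predictability = NA_character_,
      script_type = NA_character_, position = NA_integer_,
      familiarity_raw = NA_integer_, stringsAsFactors = FALSE)
    b_subj <- if ("subject_intercept" %in% names(ranef))
      ranef$subject_intercept[ctrl$subject] else 0
    lat_c <- spec$control_shift + b_subj + rlogis(nrow(ctrl))
    ctrl$rating <- as.integer(1L + rowSums(outer(lat_c, spec$thresholds,
                                                 `>`)))
    ctrl$is_control <- TRUE
    ctrl$control_kind <- "ungrammatical"
    d <- rbind(d[, names(ctrl)], ctrl)
  }
  rownames(d) <- NULL
  attr(d, "truth") <- list(fixed_effects = spec$fixed_effects,
                           random_sds = spec$random_sds,
                           thresholds = spec$thresholds, ranef = ranef)
  d
}

#' Read a rating table from CSV
#'
#' Loads trial-level Likert data. `mapping` renames source columns to the
#' package schema (`schema_name = "source_name"`), since deposited rating
#' files rarely share one header convention. The loader degrades
#' gracefully: missing optional columns are reported via the
#' `missing_columns` attribute and [feasible_checks()] says which
#' analyses the table supports.
#'
#' @param path CSV path.
#' @param mapping named character vector, e.g.
#'   `c(subject = "VP", rating = "antwort")`.
#' @param sep field separator.
#' @return Data frame in the rating-table schema (available columns only).
#' @export
read_ratings <- function(path, mapping = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (nm in names(mapping)) {
      src <- mapping[[nm]]
      if (src %in% names(tab)) names(tab)[names(tab) == src] <- nm
    }
  }
  schema <- c("subject", "item", "scenario", "rating", "sententiality",
              "predictability", "script_type", "position",
              "familiarity_raw", "is_control", "control_kind")
  missing_cols <- setdiff(schema, names(tab))
  if ("rating" %in% missing_cols) {
    stop("rating table has no 'rating' column (after mapping)",
         call. = FALSE)
  }
  if (!all(tab$rating %in% 1:7)) {
    stop("ratings must be integers 1..7", call. = FALSE)
  }
  if (!"is_control" %in% names(tab)) tab$is_control <- FALSE
  if (!"control_kind" %in% names(tab)) tab$control_kind <- NA_character_
  out <- tab[, intersect(c(schema, setdiff(names(tab), schema)), names(tab))]
  attr(out, "missing_columns") <- setdiff(missing_cols,
                                          c("is_control", "control_kind"))
  out
}

#' Which analyses does a rating table support?
#'
#' @param table a rating table.
#' @return Named logical vector: `exclusion_rule` (needs ungrammatical
#'   controls), `familiarity_terms` (needs familiarity scores),
#'   `script_type_term`, `position_term`, `core_model` (needs the two
#'   manipulated factors).
#' @export
feasible_checks <- function(table) {
  has <- function(col) col %in% names(table) && !all(is.na(table[[col]]))
  c(exclusion_rule = has("control_kind") &&
      any(table$control_kind %in% "ungrammatical"),
    familiarity_terms = has("familiarity_raw"),
    script_type_term = has("script_type"),
    position_term = has("position"),
    core_model = has("sententiality") && has("predictability") &&
      has("rating"))
}

#' Apply the control-based subject exclusion rule
#'
#' Subjects who rated more than `min_flagged` of their ungrammatical
#' control trials as natural (rating at or above `natural_cutoff`) are
#' removed entirely.
#'
#' @param table a rating table containing ungrammatical control rows.
#' @param min_flagged exclusion if the count is strictly greater; default 2.
#' @param natural_cutoff rating counted as "natural"; default 6.
#' @return List with `table` (all rows of retained subjects) and
#'   `excluded` (subject ids removed).
#' @export
#' @examples
#' tab <- sample_ratings(rating_sim_spec(n_subjects = 8, n_items = 8),
#'                       seed = 1)
#' exclude_subjects(tab)$excluded
exclude_subjects <- function(table, min_flagged = 2L, natural_cutoff = 6L) {
  ctrl <- table[table$is_control %in% TRUE &
                  table$control_kind %in% "ungrammatical", ]
  if (nrow(ctrl) == 0L) {
    stop("no ungrammatical control rows: cannot apply the exclusion rule",
         call. = FALSE)
  }
  flagged <- tapply(ctrl$rating >= natural_cutoff, ctrl$subject, sum)
  excluded <- names(flagged)[flagged > min_flagged]
  keep <- !(as.character(table$subject) %in% excluded)
  list(table = table[keep, , drop = FALSE],
       excluded = type.convert(excluded, as.is = TRUE))
}
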