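# Coded verb-token tables: the ingestion boundary of the pipeline.
# One row per verb token (or pre-aggregated count): dyad, session, child age,
# speaker stratum (CS/CDS), root, binyan, temporal category, agreement.

.token_columns <- c("dyad_id", "session_index", "age_days", "speaker",
                    "root", "binyan", "temporal", "person", "number",
                    "gender", "count")

#' Validate a coded verb-token table
#'
#' Checks the tabular schema the whole pipeline consumes: one row per verb
#' token (or per pre-aggregated `count`), with the agreement fields forming
#' one of the 25 inflectional categories valid for the row's temporal
#' category, the binyan-temporal cell defined in the paradigm table, roots
#' in canonical romanization, and session indices consistently ordered by
#' child age within each dyad.
#'
#' @param tokens A data frame with columns `dyad_id`, `session_index`,
#'   `age_days`, `speaker` (`"CS"`/`"CDS"`), `root`, `binyan`, `temporal`,
#'   `person`, `number`, `gender` and optionally `count` (default 1).
#' @param lenient If `TRUE`, invalid rows are dropped with a warning naming
#'   them; if `FALSE` (default) any invalid row is an error.
#' @return The validated table as a tibble with all schema columns,
#'   invisibly classed `verb_tokens`.
#' @export
validate_verb_tokens <- function(tokens, lenient = FALSE) {
  if (inherits(tokens, "verb_tokens")) return(tokens) # already validated
  tokens <- tibble::as_tibble(tokens)
  if (!"count" %in% names(tokens)) tokens$count <- 1L
  missing_cols <- setdiff(.token_columns, names(tokens))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tokens <- dplyr::select(tokens, dplyr::all_of(.token_columns))
  for (col in c("person", "number", "gender")) {
    v <- as.character(tokens[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    tokens[[col]] <- v
  }

  problems <- character(0)
  flag <- function(bad, rule) {
    if (any(bad)) {
      problems <<- c(problems, sprintf("row %d: %s", which(bad), rule))
    }
    bad
  }
  bad <- flag(!tokens$speaker %in% c("CS", "CDS"), "speaker must be CS or CDS")
  bad <- bad | flag(!tokens$binyan %in% binyanim(), "unknown binyan")
  bad <- bad | flag(!tokens$temporal %in% temporal_categories(),
                    "unknown temporal category")
  bad <- bad | flag(is.na(tokens$session_index) | tokens$session_index < 1 |
                      tokens$session_index != round(tokens$session_index),
                    "session_index must be a positive integer")
  bad <- bad | flag(is.na(tokens$age_days) | tokens$age_days < 1,
                    "age_days must be positive")
  bad <- bad | flag(is.na(tokens$count) | tokens$count < 1 |
                      tokens$count != round(tokens$count),
                    "count must be a positive integer")
  bad <- bad | flag(!grepl("^[a-zA-Z?](-[a-zA-Z?]){1,3}$", tokens$root),
                    "root not in canonical romanized form")

  # agreement bundle must be one of the 25 categories, and the
  # binyan-temporal cell must exist (Hufal/Pual lack imperative/infinitive)
  valid_cells <- pattern_inventory()
  valid_infl <- .inflection_table()
  key <- function(t, p, n, g) paste(t, p, n, g, sep = "\r")
  ok_infl <- key(tokens$temporal, tokens$person, tokens$number,
                 tokens$gender) %in%
    key(valid_infl$temporal, valid_infl$person, valid_infl$number,
        valid_infl$gender)
  bad <- bad | flag(!ok_infl & !is.na(tokens$temporal) &
                      tokens$temporal %in% temporal_categories(),
                    "agreement features invalid for temporal category")
  ok_cell <- paste(tokens$binyan, tokens$temporal) %in%
    paste(valid_cells$binyan, valid_cells$temporal)
  bad <- bad | flag(!ok_cell & tokens$binyan %in% binyanim() &
                      tokens$temporal %in% temporal_categories(),
                    "binyan-temporal cell undefined in paradigm")

  if (any(bad)) {
    msg <- paste(utils::head(problems, 20), collapse = "\n  ")
    if (lenient) {
      warning(sum(bad), " invalid row(s) dropped:\n  ", msg)
      tokens <- tokens[!bad, ]
    } else {
      stop(sum(bad), " invalid row(s):\n  ", msg)
    }
  }
  if (nrow(tokens) == 0) stop("no valid verb-token rows")

  # session_index must be strictly ordered by age within dyad
  ord <- tokens |>
    dplyr::distinct(.data$dyad_id, .data$session_index, .data$age_days) |>
    dplyr::arrange(.data$dyad_id, .data$session_index)
  dup <- ord |>
    dplyr::count(.data$dyad_id, .data$session_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("session_index maps to multiple ages in dyad(s): ",
         paste(unique(dup$dyad_id), collapse = ", "))
  }
  mono <- ord |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::summarise(ok = all(diff(.data$age_days) > 0) || dplyr::n() == 1)
  if (!all(mono$ok)) {
    stop("age_days must strictly increase with session_index in dyad(s): ",
         paste(mono$dyad_id[!mono$ok], collapse = ", "))
  }
  class(tokens) <- c("verb_tokens", class(tokens))
  tokens
}

#' Read a coded verb-token table from CSV/TSV
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.tsv`/`.tab` for tab, anything else comma) unless `delim` is given.
#' @param delim Optional explicit field delimiter.
#' @param lenient Passed to [validate_verb_tokens()].
#' @return A validated `verb_tokens` tibble.
#' @export
read_verb_tokens <- function(path, delim = NULL, lenient = FALSE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      dyad_id = readr::col_character(), session_index = readr::col_integer(),
      age_days = readr::col_integer(), speaker = readr::col_character(),
      root = readr::col_character(), binyan = readr::col_character(),
      temporal = readr::col_character(), person = readr::col_character(),
      number = readr::col_character(), gender = readr::col_character(),
      .default = readr::col_guess()))
  validate_verb_tokens(raw, lenient = lenient)
}

#' Write a verb-token table to CSV/TSV
#'
#' Round-trips through [read_verb_tokens()] on the canonical dialect.
#'
#' @param tokens A validated verb-token table.
#' @param path Output path; extension chooses the delimiter as in
#'   [read_verb_tokens()].
#' @return The path, invisibly.
#' @export
write_verb_tokens <- function(tokens, path) {
  tokens <- validate_verb_tokens(tokens)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(as.data.frame(tokens), path, delim = delim, na = "")
  invisible(path)
}

#' Summarize a corpus per dyad and speaker
#'
#' Reports, for each dyad x speaker stratum: number of recording sessions,
#' child age range, verb tokens (sum of `count`), and verb types counted as
#' lemmas — distinct root x binyan pairs, so the same root in two binyanim
#' counts as two lemmas.
#'
#' @param tokens A verb-token table.
#' @return A tibble with one row per (dyad_id, speaker).
#' @export
summarize_corpus <- function(tokens) {
  tokens <- validate_verb_tokens(tokens)
  strata <- tidyr::expand_grid(
    dyad_id = unique(tokens$dyad_id), speaker = c("CS", "CDS"))
  tokens |>
    dplyr::group_by(.data$dyad_id, .data$speaker) |>
    dplyr::summarise(
      n_sessions = dplyr::n_distinct(.data$session_index),
      age_min = min(.data$age_days), age_max = max(.data$age_days),
      verb_tokens = sum(.data$count),
      verb_types = dplyr::n_distinct(paste(.data$root, .data$binyan)),
      n_roots = dplyr::n_distinct(.data$root),
      n_patterns = dplyr::n_distinct(pattern_label(
        .data$binyan, .data$temporal, .data$person, .data$number,
        .data$gender)),
      .groups = "drop") |>
    dplyr::right_join(strata, by = c("dyad_id", "speaker")) |>
    dplyr::mutate(dplyr::across(
      c("n_sessions", "verb_tokens", "verb_types", "n_roots", "n_patterns"),
      ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::arrange(.data$dyad_id, dplyr::desc(.data$speaker))
}
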