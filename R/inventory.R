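# Closed morphological inventories: the seven binyan conjugations, their
# temporal-pattern templates, and the 25 agreement-inflection categories.

#' The seven binyan conjugation names
#'
#' @return Character vector of the seven binyanim in canonical order.
#' @export
binyanim <- function() {
  c("Qal", "Nifal", "Hifil", "Hufal", "Piel", "Pual", "Hitpael")
}

#' The five temporal categories
#'
#' @return Character vector: Past, Present, Future, Imperative, Infinitive.
#' @export
temporal_categories <- function() {
  c("Past", "Present", "Future", "Imperative", "Infinitive")
}

# binyan x temporal template table; NA = cell undefined in the paradigm.
# Hufal and Pual lack imperative and infinitive forms, leaving 31 defined
# binyan-specific temporal patterns.
.template_table <- function() {
  tibble::tribble(
    ~binyan,   ~Past,       ~Present,    ~Future,     ~Imperative, ~Infinitive,
    "Qal",     "CaCaC",     "CoCeC",     "yiCCoC",    "CCoC",      "liCCoC",
    "Nifal",   "niCCaC",    "niCCaC",    "yiCaCeC",   "hiCaCeC",   "lehiCaCeC",
    "Hifil",   "hiCCiC",    "maCCiC",    "yaCCiC",    "haCCeC",    "lehaCCiC",
    "Hufal",   "huCCaC",    "muCCaC",    "yuCCaC",    NA,          NA,
    "Piel",    "CiCeC",     "meCaCeC",   "yeCaCeC",   "CaCeC",     "leCaCeC",
    "Pual",    "CuCaC",     "meCuCaC",   "yeCuCaC",   NA,          NA,
    "Hitpael", "hitCaCeC",  "mitCaCeC",  "yitCaCeC",  "hitCaCeC",  "lehitCaCeC"
  )
}

#' Enumerate the binyan-specific temporal patterns
#'
#' Crossing the seven binyanim with the five temporal categories gives 35
#' cells, of which four (Hufal/Pual imperative and infinitive) are undefined,
#' leaving the 31 binyan-specific temporal patterns a Hebrew-acquiring child
#' must learn. Ordering is binyan-major, temporal-minor and deterministic.
#'
#' @return A tibble with columns `binyan`, `temporal`, `template`, one row
#'   per defined pattern (31 rows).
#' @export
#' @examples
#' nrow(pattern_inventory()) # 31
pattern_inventory <- function() {
  .template_table() |>
    tidyr::pivot_longer(-"binyan", names_to = "temporal", values_to = "template") |>
    dplyr::filter(!is.na(.data$template)) |>
    dplyr::mutate(
      binyan = factor(.data$binyan, levels = binyanim()),
      temporal = factor(.data$temporal, levels = temporal_categories())
    ) |>
    dplyr::arrange(.data$binyan, .data$temporal) |>
    dplyr::mutate(binyan = as.character(.data$binyan),
                  temporal = as.character(.data$temporal))
}

#' Agreement-feature applicability per temporal category
#'
#' Infinitives carry no agreement; present-tense verbs agree in number and
#' gender but not person; past, future and imperative verbs are marked for
#' all three (imperative person being implicitly 2nd and carried as `NA` in
#' category labels).
#'
#' @param temporal Optional temporal category name; if omitted the full
#'   five-row table is returned.
#' @return A tibble with columns `temporal`, `person`, `number`, `gender`
#'   (logical: is the feature marked).
#' @export
agreement_applicability <- function(temporal = NULL) {
  tab <- tibble::tribble(
    ~temporal,    ~person, ~number, ~gender,
    "Past",       TRUE,    TRUE,    TRUE,
    "Present",    FALSE,   TRUE,    TRUE,
    "Future",     TRUE,    TRUE,    TRUE,
    "Imperative", TRUE,    TRUE,    TRUE,
    "Infinitive", FALSE,   FALSE,   FALSE
  )
  if (is.null(temporal)) return(tab)
  stopifnot(temporal %in% tab$temporal)
  dplyr::filter(tab, .data$temporal == !!temporal)
}

# The 25 temporal-category x agreement inflectional categories, encoded
# literally (syncretisms included: no gender for 1st person, plural
# imperative, future plural non-1st, or past 3rd plural; past 2nd plural IS
# gender-marked). Imperative person is implicit-2nd, stored as NA.
.inflection_table <- function() {
  tibble::tribble(
    ~temporal,    ~person, ~number, ~gender,
    "Infinitive", NA,      NA,      NA,
    "Imperative", NA,      "Sg",    "Masc",
    "Imperative", NA,      "Sg",    "Fm",
    "Imperative", NA,      "Pl",    NA,
    "Future",     "1",     "Sg",    NA,
    "Future",     "2",     "Sg",    "Masc",
    "Future",     "2",     "Sg",    "Fm",
    "Future",     "3",     "Sg",    "Masc",
    "Future",     "3",     "Sg",    "Fm",
    "Future",     "1",     "Pl",    NA,
    "Future",     "2",     "Pl",    NA,
    "Future",     "3",     "Pl",    NA,
    "Present",    NA,      "Sg",    "Masc",
    "Present",    NA,      "Sg",    "Fm",
    "Present",    NA,      "Pl",    "Masc",
    "Present",    NA,      "Pl",    "Fm",
    "Past",       "1",     "Sg",    NA,
    "Past",       "2",     "Sg",    "Masc",
    "Past",       "2",     "Sg",    "Fm",
    "Past",       "3",     "Sg",    "Masc",
    "Past",       "3",     "Sg",    "Fm",
    "Past",       "1",     "Pl",    NA,
    "Past",       "2",     "Pl",    "Masc",
    "Past",       "2",     "Pl",    "Fm",
    "Past",       "3",     "Pl",    NA
  )
}

#' Enumerate the inflected-pattern categories of a binyan
#'
#' For a binyan with a full paradigm (Qal, Nifal, Hifil, Piel, Hitpael)
#' this yields the 25 temporal-category-by-agreement inflectional
#' categories; Hufal and Pual lack imperative (3 categories) and infinitive
#' (1 category) and yield 21.
#'
#' @param binyan One of the seven binyan names.
#' @return A tibble with columns `binyan`, `temporal`, `person`, `number`,
#'   `gender`, `template`, `label` (the canonical inflected-pattern label,
#'   e.g. `"Qal.Present.Fm.Sg"`).
#' @export
#' @examples
#' nrow(inflection_inventory("Qal"))   # 25
#' nrow(inflection_inventory("Hufal")) # 21
inflection_inventory <- function(binyan) {
  stopifnot(length(binyan) == 1, binyan %in% binyanim())
  pats <- dplyr::filter(pattern_inventory(), .data$binyan == !!binyan)
  .inflection_table() |>
    dplyr::inner_join(pats, by = "temporal") |>
    dplyr::mutate(label = pattern_label(.data$binyan, .data$temporal,
                                        .data$person, .data$number,
                                        .data$gender)) |>
    dplyr::select("binyan", "temporal", "person", "number", "gender",
                  "template", "label")
}

#' Canonical inflected-pattern label
#'
#' Components are dot-joined in the order binyan, temporal, person, gender,
#' number, omitting unmarked features, e.g. `"Qal.Present.Fm.Sg"`,
#' `"Piel.Past.3.Masc.Sg"`, `"Qal.Infinitive"`.
#'
#' @param binyan,temporal,person,number,gender Vectorized category fields;
#'   unmarked features are `NA`.
#' @return Character vector of labels.
#' @export
pattern_label <- function(binyan, temporal, person = NA, number = NA,
                          gender = NA) {
  parts <- cbind(binyan, temporal, person, gender, number)
  apply(parts, 1L, function(p) paste(p[!is.na(p)], collapse = "."))
}

#' Parse an inflected-pattern label back to its fields
#'
#' Inverse of [pattern_label()]; round-trips every label in
#' [inflection_inventory()].
#'
#' @param label Character vector of canonical labels.
#' @return A tibble with columns `binyan`, `temporal`, `person`, `number`,
#'   `gender`.
#' @export
parse_pattern_label <- function(label) {
  purrr::map_dfr(strsplit(label, ".", fixed = TRUE), function(tok) {
    if (length(tok) < 2 || !tok[1] %in% binyanim() ||
        !tok[2] %in% temporal_categories()) {
      stop("not a valid inflected-pattern label: ", paste(tok, collapse = "."))
    }
    rest <- tok[-(1:2)]
    tibble::tibble(
      binyan = tok[1], temporal = tok[2],
      person = if (any(rest %in% c("1", "2", "3")))
        rest[rest %in% c("1", "2", "3")][1] else NA_character_,
      number = if (any(rest %in% c("Sg", "Pl")))
        rest[rest %in% c("Sg", "Pl")][1] else NA_character_,
      gender = if (any(rest %in% c("Masc", "Fm")))
        rest[rest %in% c("Masc", "Fm")][1] else NA_character_
    )
  })
}

#' Format a root from its radicals
#'
#' Roots are 2-4 consonant radicals, romanized ASCII-safe: the glottal stop
#' is written `"?"` and the pharyngeal fricative `"H"`, so labels survive
#' CSV round-trips. The canonical label hyphen-joins the radicals,
#' e.g. `"l-m-d"`, `"l-q-H"`, `"r-?-y"`.
#'
#' @param radicals Character vector of radicals (one string per radical).
#' @return The canonical hyphen-joined root label.
#' @export
root_label <- function(radicals) {
  stopifnot(is.character(radicals), length(radicals) >= 2,
            length(radicals) <= 4, all(nchar(radicals) == 1),
            all(grepl("^[a-zA-Z?]$", radicals)))
  paste(radicals, collapse = "-")
}

#' Parse a root label into its radicals
#'
#' @param label Canonical hyphen-joined root label.
#' @return Character vector of radicals.
#' @export
parse_root <- function(label) {
  stopifnot(length(label) == 1, is.character(label))
  radicals <- strsplit(label, "-", fixed = TRUE)[[1]]
  root_label(radicals) # validates
  radicals
}

#' Expand the full inflectional paradigm of a root in one binyan
#'
#' Crosses a root with every inflected-pattern category of the binyan: 25
#' wordform links for a full-paradigm binyan, 21 for Hufal/Pual. Each row is
#' one potential edge of a bipartite verb network.
#'
#' @param root Canonical root label (e.g. `"l-q-H"`).
#' @param binyan One of the seven binyan names.
#' @return A tibble with columns `root`, `pattern` (inflected-pattern
#'   label) plus the category fields.
#' @export
#' @examples
#' nrow(expand_paradigm("l-q-H", "Qal")) # 25
expand_paradigm <- function(root, binyan) {
  parse_root(root) # validate
  inflection_inventory(binyan) |>
    dplyr::mutate(root = root, pattern = .data$label, .before = 1) |>
    dplyr::select("root", "pattern", "binyan", "temporal", "person",
                  "number", "gender")
}

#' Naive symbolic interpolation of a root into a C-slot template
#'
#' Replaces the template's C slots left-to-right with the root radicals.
#' This is a NAIVE symbolic rendering: the real surface forms undergo
#' morpho-phonological stem changes (spirantization, vowel alternation)
#' that are out of scope here, so e.g. `"CaCaC"` + `k-t-b` yields the
#' symbolic `"katab"`, not the true surface *katav*. Node identity in the
#' networks never uses this rendering.
#'
#' @param template C-slot template string, e.g. `"maCCiC"`.
#' @param root Canonical root label.
#' @return The interpolated symbolic string.
#' @export
#' @examples
#' interpolate_template("maCCiC", "k-t-b") # "maktib"
interpolate_template <- function(template, root) {
  radicals <- parse_root(root)
  slots <- gregexpr("C", template, fixed = TRUE)[[1]]
  n_slots <- if (identical(c(slots), -1L)) 0L else length(slots)
  if (n_slots != length(radicals)) {
    stop(sprintf(
      "template '%s' has %d C slots but root '%s' has %d radicals",
      template, n_slots, root, length(radicals)))
  }
  out <- strsplit(template, "")[[1]]
  out[slots] <- radicals
  paste(out, collapse = "")
}

#' Export the morphological inventories as JSON
#'
#' Writes the pattern inventory, the full inflected-pattern inventory over
#' all seven binyanim, and the agreement-applicability table to a single
#' JSON file for documentation and cross-language checks.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_inventory_json <- function(path) {
  jsonlite::write_json(
    list(
      patterns = pattern_inventory(),
      inflected_patterns = purrr::map_dfr(binyanim(), inflection_inventory),
      agreement_applicability = agreement_applicability()
    ),
    path, na = "null", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
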