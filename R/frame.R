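# Lagged CS/CDS model frames: the long tables feeding the adaptation models.
# Node-level frames carry one row per (session, node) for nodes active in
# BOTH speakers' networks that session; network-level frames carry one row
# per session. Every measure column gets a current and a prior (recording
# N-1) version, then is centered and scaled.

.measure_cols <- function(level) {
  base <- if (level == "node") {
    c("degree.cs", "degree.cds", "centrality.cs", "centrality.cds",
      "density.cs", "density.cds")
  } else {
    c("density.cs", "density.cds")
  }
  c(rbind(base, paste0("prior.", base)))
}

#' Assemble a lagged CS/CDS model frame from a measure table
#'
#' Takes the long measure table of one dyad and builds the wide lagged frame
#' the adaptation models are fitted on. Node-level frames keep only nodes
#' that appear in both the child's and the parent's network at that session;
#' each measure gets a `prior.*` twin holding its value at recording N-1
#' (zero-imputed before scaling when the node was inactive then — an
#' inactive node has no links, hence zero degree and centrality — or
#' row-dropped under `impute_prior = "drop"`). Rows for the first session
#' are dropped (no prior exists). All measure columns are then z-scored;
#' the per-column means and sds are stored in the `"scaling"` attribute.
#'
#' @param measures A measure table from [measure_table()] for a single dyad.
#' @param level `"node"` (degree/centrality/density columns) or `"network"`
#'   (density columns only, one row per session).
#' @param impute_prior `"zero"` (default) or `"drop"`.
#' @return A `model_frame` tibble. Node level: columns `name`, `class`,
#'   `session_index`, `age`, and the 12 scaled measure columns. Network
#'   level: `session_index`, `age`, and the 4 scaled density columns.
#' @export
assemble_model_frame <- function(measures, level = c("node", "network"),
                                 impute_prior = c("zero", "drop")) {
  level <- match.arg(level)
  impute_prior <- match.arg(impute_prior)
  measures <- tibble::as_tibble(measures)
  dyads <- unique(measures$dyad_id)
  if (length(dyads) != 1) {
    stop("measure table must cover exactly one dyad, found: ",
         paste(dyads, collapse = ", "))
  }
  sessions <- measures |>
    dplyr::distinct(.data$session_index, .data$age_days) |>
    dplyr::arrange(.data$session_index)
  if (nrow(sessions) < 2) stop("need at least 2 sessions to build a lagged frame")
  sessions$prior_session <- dplyr::lag(sessions$session_index)

  dens <- measures |>
    dplyr::filter(.data$level == "network") |>
    dplyr::select("session_index", "speaker", "density") |>
    tidyr::pivot_wider(names_from = "speaker", values_from = "density") |>
    dplyr::rename(density.cs = "CS", density.cds = "CDS")
  dens_prior <- dens |>
    dplyr::rename(prior_session = "session_index",
                  prior.density.cs = "density.cs",
                  prior.density.cds = "density.cds")

  if (level == "network") {
    frame <- sessions |>
      dplyr::inner_join(dens, by = "session_index") |>
      dplyr::left_join(dens_prior, by = "prior_session") |>
      dplyr::filter(!is.na(.data$prior_session)) |>
      dplyr::transmute(.data$session_index, age = .data$age_days,
                       .data$density.cs, .data$density.cds,
                       .data$prior.density.cs, .data$prior.density.cds)
  } else {
    node_meas <- measures |>
      dplyr::filter(.data$level == "node") |>
      dplyr::select("session_index", "speaker", "node", "class",
                    "degree", "centrality")
    wide <- node_meas |>
      tidyr::pivot_wider(
        names_from = "speaker", values_from = c("degree", "centrality"),
        names_glue = "{.value}.{tolower(speaker)}")
    for (col in c("degree.cs", "degree.cds", "centrality.cs",
                  "centrality.cds")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
    shared <- dplyr::filter(wide, !is.na(.data$degree.cs),
                            !is.na(.data$degree.cds))
    prior <- wide |>
      dplyr::rename(prior_session = "session_index") |>
      dplyr::rename_with(~ paste0("prior.", .x),
                         dplyr::matches("^(degree|centrality)\\."))
    frame <- shared |>
      dplyr::inner_join(sessions, by = "session_index") |>
      dplyr::filter(!is.na(.data$prior_session)) |>
      dplyr::left_join(prior, by = c("node", "class", "prior_session")) |>
      dplyr::inner_join(dens, by = "session_index") |>
      dplyr::left_join(dens_prior, by = "prior_session")
    prior_cols <- paste0("prior.", c("degree.cs", "degree.cds",
                                     "centrality.cs", "centrality.cds"))
    if (impute_prior == "zero") {
      # inactive at N-1 => no links => zero degree and centrality
      frame <- dplyr::mutate(frame, dplyr::across(
        dplyr::all_of(prior_cols), ~ dplyr::coalesce(.x, 0)))
    } else {
      frame <- dplyr::filter(frame, dplyr::if_all(
        dplyr::all_of(prior_cols), ~ !is.na(.x)))
    }
    frame <- frame |>
      dplyr::transmute(
        name = .data$node, .data$class, .data$session_index,
        age = .data$age_days,
        .data$degree.cs, .data$prior.degree.cs,
        .data$degree.cds, .data$prior.degree.cds,
        .data$centrality.cs, .data$prior.centrality.cs,
        .data$centrality.cds, .data$prior.centrality.cds,
        .data$density.cs, .data$prior.density.cs,
        .data$density.cds, .data$prior.density.cds)
  }
  frame <- dplyr::filter(frame, dplyr::if_all(
    dplyr::all_of(.measure_cols(level)), ~ !is.na(.x)))
  if (nrow(frame) < 2) stop("fewer than 2 usable rows after lagging/filtering")

  scaling <- purrr::map_dfr(.measure_cols(level), function(col) {
    m <- mean(frame[[col]])
    s <- stats::sd(frame[[col]])
    if (!is.finite(s) || s == 0) {
      stop("cannot scale constant column '", col, "'")
    }
    tibble::tibble(column = col, mean = m, sd = s)
  })
  for (i in seq_len(nrow(scaling))) {
    col <- scaling$column[i]
    frame[[col]] <- (frame[[col]] - scaling$mean[i]) / scaling$sd[i]
  }
  structure(frame, level = level, dyad_id = dyads, scaling = scaling,
            impute_prior = impute_prior,
            class = c("model_frame", class(frame)))
}

#' Back-transform scaled model-frame columns to their original units
#'
#' @param frame A `model_frame`.
#' @return The frame with measure columns on their original scale.
#' @export
unscale_model_frame <- function(frame) {
  scaling <- attr(frame, "scaling")
  stopifnot(!is.null(scaling))
  for (i in seq_len(nrow(scaling))) {
    col <- scaling$column[i]
    frame[[col]] <- frame[[col]] * scaling$sd[i] + scaling$mean[i]
  }
  frame
}
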