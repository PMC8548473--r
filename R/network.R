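# Per-session bipartite verb networks: roots and inflected patterns are the
# two node classes, verb wordforms (root x inflected pattern) are the links.

#' Build a participant's node registry
#'
#' The registry is the list of all roots and all inflected patterns a
#' participant (one speaker stratum of one dyad) ever used across the whole
#' corpus — the fixed universe against which per-session networks are
#' snapshots. Two dyads x two speakers give the four lists of the design.
#'
#' @param tokens A verb-token table.
#' @param dyad_id Dyad identifier.
#' @param speaker `"CS"` or `"CDS"`.
#' @return An object of class `node_registry`: a list with `dyad_id`,
#'   `speaker`, `roots` and `patterns` (sorted character vectors).
#' @export
build_registry <- function(tokens, dyad_id, speaker) {
  tokens <- validate_verb_tokens(tokens)
  stratum <- dplyr::filter(tokens, .data$dyad_id == !!dyad_id,
                           .data$speaker == !!speaker)
  if (nrow(stratum) == 0) {
    stop("no tokens for dyad '", dyad_id, "', speaker '", speaker, "'")
  }
  structure(
    list(dyad_id = dyad_id, speaker = speaker,
         roots = sort(unique(stratum$root)),
         patterns = sort(unique(pattern_label(
           stratum$binyan, stratum$temporal, stratum$person,
           stratum$number, stratum$gender)))),
    class = "node_registry")
}

#' @export
print.node_registry <- function(x, ...) {
  cat(sprintf("<node_registry> %s / %s: %d roots, %d inflected patterns\n",
              x$dyad_id, x$speaker, length(x$roots), length(x$patterns)))
  invisible(x)
}

#' Build one participant's network for one recording session
#'
#' Nodes are the roots and inflected patterns with at least one token in the
#' session; links are verb wordforms. In `"binary"` mode (the default) a
#' link is a distinct root-pattern combination regardless of how often it
#' was said; `"weighted"` mode carries token counts as edge weights. The
#' graph is bipartite by construction: links only join a root to a pattern.
#'
#' @param tokens A verb-token table.
#' @param dyad_id,speaker,session_index Stratum selectors.
#' @param mode `"binary"` (distinct wordforms) or `"weighted"` (token
#'   counts).
#' @return An object of class `session_network`: a list with the stratum
#'   fields, `edges` (tibble root/pattern/weight), `root_nodes`,
#'   `pattern_nodes`, node count `n`, link count `m`, and `empty` flag. An
#'   empty stratum yields an explicitly empty network (`n = 0`, `m = 0`,
#'   `empty = TRUE`), never a silent skip.
#' @export
build_session_network <- function(tokens, dyad_id, speaker, session_index,
                                  mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  tokens <- validate_verb_tokens(tokens)
  stratum <- dplyr::filter(tokens, .data$dyad_id == !!dyad_id,
                           .data$speaker == !!speaker,
                           .data$session_index == !!session_index)
  age <- if (nrow(stratum) > 0) stratum$age_days[1] else {
    ages <- dplyr::filter(tokens, .data$dyad_id == !!dyad_id,
                          .data$session_index == !!session_index)
    if (nrow(ages) > 0) ages$age_days[1] else NA_integer_
  }
  edges <- stratum |>
    dplyr::mutate(pattern = pattern_label(
      .data$binyan, .data$temporal, .data$person, .data$number,
      .data$gender)) |>
    dplyr::group_by(.data$root, .data$pattern) |>
    dplyr::summarise(weight = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$root, .data$pattern)
  if (mode == "binary") edges$weight <- 1L
  root_nodes <- sort(unique(edges$root))
  pattern_nodes <- sort(unique(edges$pattern))
  structure(
    list(dyad_id = dyad_id, speaker = speaker,
         session_index = session_index, age_days = age, mode = mode,
         edges = edges, root_nodes = root_nodes,
         pattern_nodes = pattern_nodes,
         n = length(root_nodes) + length(pattern_nodes), m = nrow(edges),
         empty = nrow(edges) == 0),
    class = "session_network")
}

#' @export
print.session_network <- function(x, ...) {
  cat(sprintf(
    "<session_network> %s / %s, session %d%s: n = %d nodes (%d roots + %d patterns), m = %d links [%s]%s\n",
    x$dyad_id, x$speaker, x$session_index,
    if (is.na(x$age_days)) "" else sprintf(" (age %d d)", x$age_days),
    x$n, length(x$root_nodes), length(x$pattern_nodes), x$m, x$mode,
    if (x$empty) " EMPTY" else ""))
  invisible(x)
}

#' Adjacency matrix of a session network
#'
#' @param network A `session_network`.
#' @param full If `TRUE` (default) the symmetric (n x n) adjacency over both
#'   node classes (roots first, then patterns); if `FALSE` the rectangular
#'   roots x patterns incidence block.
#' @return A numeric matrix with node labels as dimnames.
#' @export
adjacency_matrix <- function(network, full = TRUE) {
  r <- network$root_nodes
  p <- network$pattern_nodes
  B <- matrix(0, length(r), length(p), dimnames = list(r, p))
  if (network$m > 0) {
    B[cbind(match(network$edges$root, r),
            match(network$edges$pattern, p))] <- network$edges$weight
  }
  if (!full) return(B)
  nodes <- c(r, p)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (length(r) > 0 && length(p) > 0) {
    A[seq_along(r), length(r) + seq_along(p)] <- B
    A[length(r) + seq_along(p), seq_along(r)] <- t(B)
  }
  A
}

#' Build the full series of per-session networks for a dyad
#'
#' One network per (session, speaker) stratum: a 47-recording dyad with both
#' speakers present in every session yields 94 networks; a 49-recording dyad
#' yields 98. Strata in which a speaker produced no verb token yield
#' explicitly empty networks so the time series keeps its index.
#'
#' @param tokens A verb-token table.
#' @param dyad_id Dyad identifier.
#' @param mode Adjacency mode, see [build_session_network()].
#' @return An object of class `network_series`: a list with `dyad_id`,
#'   `sessions` (tibble session_index/age_days), and `networks`, a named
#'   list keyed `"<session>.<speaker>"`.
#' @export
build_network_series <- function(tokens, dyad_id,
                                 mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  tokens <- validate_verb_tokens(tokens)
  dtab <- dplyr::filter(tokens, .data$dyad_id == !!dyad_id)
  if (nrow(dtab) == 0) stop("dyad '", dyad_id, "' not present")
  sessions <- dtab |>
    dplyr::distinct(.data$session_index, .data$age_days) |>
    dplyr::arrange(.data$session_index)
  grid <- tidyr::expand_grid(session_index = sessions$session_index,
                             speaker = c("CS", "CDS"))
  networks <- purrr::pmap(grid, function(session_index, speaker) {
    build_session_network(dtab, dyad_id, speaker, session_index, mode = mode)
  })
  names(networks) <- paste(grid$session_index, grid$speaker, sep = ".")
  structure(list(dyad_id = dyad_id, sessions = sessions,
                 networks = networks, mode = mode),
            class = "network_series")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf(
    "<network_series> dyad %s: %d sessions x 2 speakers = %d networks (%d empty)\n",
    x$dyad_id, nrow(x$sessions), length(x$networks),
    sum(purrr::map_lgl(x$networks, "empty"))))
  invisible(x)
}

#' Export a network series as a long edge-list tibble
#'
#' @param series A `network_series`.
#' @return A tibble with columns `session_index`, `age_days`, `speaker`,
#'   `root`, `pattern`, `weight` (one row per link per network).
#' @export
edge_list <- function(series) {
  stopifnot(inherits(series, "network_series"))
  purrr::map_dfr(series$networks, function(net) {
    if (net$empty) return(NULL)
    dplyr::mutate(net$edges, session_index = net$session_index,
                  age_days = net$age_days, speaker = net$speaker,
                  .before = 1)
  })
}
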