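# Node- and network-level measures over session networks: degree (row/column
# sums of the adjacency), eigenvector centrality (leading eigenpair of the
# symmetrized bipartite adjacency), density (links over possible links), and
# activation timelines quantifying punctuated usage.

#' Node degrees of a session network
#'
#' The degree of a node is the sum of its adjacency row: in binary mode, the
#' number of distinct partners — for an inflected pattern, the number of
#' roots it combines with; for a root, the number of inflected patterns it
#' takes.
#'
#' @param network A `session_network`.
#' @return A tibble with columns `node`, `class` (`"root"`/`"pattern"`),
#'   `degree`. An empty network yields a zero-row tibble with attribute
#'   `undefined = TRUE` (the measure is undefined, not zero).
#' @export
node_degree <- function(network) {
  stopifnot(inherits(network, "session_network"))
  if (network$empty) {
    out <- tibble::tibble(node = character(0), class = character(0),
                          degree = numeric(0))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  rd <- network$edges |>
    dplyr::group_by(node = .data$root) |>
    dplyr::summarise(degree = sum(.data$weight)) |>
    dplyr::mutate(class = "root")
  pd <- network$edges |>
    dplyr::group_by(node = .data$pattern) |>
    dplyr::summarise(degree = sum(.data$weight)) |>
    dplyr::mutate(class = "pattern")
  dplyr::bind_rows(rd, pd) |>
    dplyr::select("node", "class", "degree") |>
    dplyr::arrange(.data$class, .data$node)
}

#' Eigenvector centrality of a session network
#'
#' Computes the nonnegative leading eigenvector of the full symmetrized
#' bipartite adjacency by power iteration, scaled to unit Euclidean norm.
#' The iteration runs on the shifted matrix A + I: bipartite adjacency
#' spectra are symmetric (+/-lambda), so the unshifted iteration need not
#' converge, while the shift leaves the eigenvectors unchanged and makes the
#' leading eigenpair strictly dominant. On disconnected networks the result
#' concentrates on the component with the largest eigenvalue; other
#' components go to ~0.
#'
#' @param network A `session_network` with at least one link.
#' @param tol Convergence tolerance on the residual `max|Ax - lambda x|`.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   residual, never a silently unconverged result.
#' @return An object of class `centrality_result`: a list with `centrality`
#'   (tibble node/class/centrality), leading eigenvalue `lambda`,
#'   `iterations`, `converged`.
#' @export
eigenvector_centrality <- function(network, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(network, "session_network"))
  if (network$m < 1) stop("eigenvector centrality undefined: network has no links")
  A <- adjacency_matrix(network, full = TRUE)
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n) # fixed uniform positive start: deterministic
  lambda <- 0
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Ax <- drop(A %*% x)
    y <- Ax + x              # (A + I) x
    x_new <- y / sqrt(sum(y^2))
    lambda <- sum(x_new * drop(A %*% x_new)) # Rayleigh quotient of A
    resid <- max(abs(drop(A %*% x_new) - lambda * x_new))
    x <- x_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop(sprintf(
      "eigenvector centrality did not converge in %d iterations (residual %.3e)",
      iter, resid))
  }
  x <- abs(x) # Perron vector is nonnegative; clean sign noise
  x <- x / sqrt(sum(x^2))
  structure(
    list(
      centrality = tibble::tibble(
        node = rownames(A),
        class = rep(c("root", "pattern"),
                    c(length(network$root_nodes),
                      length(network$pattern_nodes))),
        centrality = x),
      lambda = lambda, iterations = iter, converged = TRUE,
      tol = tol),
    class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf(
    "<centrality_result> %d nodes, lambda = %.6g, %d iterations (tol %.1e)\n",
    nrow(x$centrality), x$lambda, x$iterations, x$tol))
  invisible(x)
}

#' Network density
#'
#' The proportion of realized links among possible links. The default
#' (`"paper"`) denominator is the unipartite n(n-1)/2 of Eq. d = m /
#' (n(n-1)/2), applied to the bipartite graph exactly as printed; the
#' `"bipartite"` option uses the bipartite maximum |roots| x |patterns|.
#'
#' @param network A `session_network`.
#' @param denominator `"paper"` or `"bipartite"`.
#' @return The density, a number in (0, 1]; `NA_real_` (undefined) when the
#'   network has fewer than 2 nodes.
#' @export
network_density <- function(network, denominator = c("paper", "bipartite")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(network, "session_network"))
  if (network$n < 2) return(NA_real_)
  possible <- switch(denominator,
    paper = network$n * (network$n - 1) / 2,
    bipartite = length(network$root_nodes) * length(network$pattern_nodes))
  network$m / possible
}

#' Node activation timeline of a participant
#'
#' For one speaker stratum of a dyad, records in which sessions each node
#' (root or inflected pattern) is active (has at least one link), and
#' summarizes per node the activity runs and the gaps between them within
#' its onset-offset span. Frequent short runs separated by gaps are the
#' signature of punctuated development; continuous single runs indicate
#' coherent usage.
#'
#' @param series A `network_series`.
#' @param speaker `"CS"` or `"CDS"`.
#' @return An object of class `activation_table`: a list with `activity`
#'   (tibble node/class/session_index/active over the full node x session
#'   grid) and `spans` (tibble node/class/onset/offset/n_active/n_runs/
#'   n_gaps/mean_gap_length).
#' @export
activation_timeline <- function(series, speaker) {
  stopifnot(inherits(series, "network_series"), speaker %in% c("CS", "CDS"))
  sessions <- series$sessions$session_index
  nets <- purrr::keep(series$networks, ~ .x$speaker == speaker)
  active <- purrr::map_dfr(nets, function(net) {
    if (net$empty) return(NULL)
    tibble::tibble(
      node = c(net$root_nodes, net$pattern_nodes),
      class = rep(c("root", "pattern"),
                  c(length(net$root_nodes), length(net$pattern_nodes))),
      session_index = net$session_index)
  })
  if (nrow(active) == 0) stop("no active nodes for speaker ", speaker)
  nodes <- dplyr::distinct(active, .data$node, .data$class)
  activity <- tidyr::expand_grid(nodes, session_index = sessions) |>
    dplyr::left_join(dplyr::mutate(active, active = TRUE),
                     by = c("node", "class", "session_index")) |>
    dplyr::mutate(active = !is.na(.data$active)) |>
    dplyr::arrange(.data$class, .data$node, .data$session_index)
  spans <- activity |>
    dplyr::group_by(.data$node, .data$class) |>
    dplyr::summarise(.run_stats(.data$active[order(.data$session_index)],
                                sessions), .groups = "drop")
  structure(list(dyad_id = series$dyad_id, speaker = speaker,
                 activity = activity, spans = spans),
            class = "activation_table")
}

# run/gap statistics for one node's activity vector over ordered sessions
.run_stats <- function(active, sessions) {
  on <- which(active)
  span <- active[min(on):max(on)]
  r <- rle(span)
  gaps <- r$lengths[!r$values]
  tibble::tibble(
    onset = sessions[min(on)], offset = sessions[max(on)],
    n_active = sum(active), n_runs = sum(r$values),
    n_gaps = length(gaps),
    mean_gap_length = if (length(gaps) > 0) mean(gaps) else 0)
}

#' @export
print.activation_table <- function(x, ...) {
  cat(sprintf(
    "<activation_table> %s / %s: %d nodes, mean %.2f activity runs per node\n",
    x$dyad_id, x$speaker, nrow(x$spans), mean(x$spans$n_runs)))
  invisible(x)
}

#' Long measure table over a network series
#'
#' One node-level row per active (node, session, speaker) carrying degree
#' and centrality, plus one network-level row per (session, speaker)
#' carrying density, m and n. Empty or sub-minimal networks contribute
#' network-level rows with missing density (undefined, never zero-filled).
#'
#' @param series A `network_series`.
#' @param centrality If `FALSE`, skip the eigenvector computation (node rows
#'   then carry `NA` centrality); useful when only densities are needed.
#' @param node_level If `FALSE`, emit only the network-level density rows
#'   (the input to the density models); degree/centrality are skipped.
#' @param denominator Density denominator, see [network_density()].
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @return A tibble with columns `dyad_id`, `session_index`, `age_days`,
#'   `speaker`, `level` (`"node"`/`"network"`), `node`, `class`, `degree`,
#'   `centrality`, `density`, `m`, `n`.
#' @export
measure_table <- function(series, centrality = TRUE, node_level = TRUE,
                          denominator = c("paper", "bipartite"),
                          tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(series, "network_series"))
  denominator <- match.arg(denominator)
  purrr::map_dfr(series$networks, function(net) {
    base <- tibble::tibble(
      dyad_id = net$dyad_id, session_index = net$session_index,
      age_days = net$age_days, speaker = net$speaker)
    net_row <- dplyr::mutate(
      base, level = "network", node = NA_character_, class = NA_character_,
      degree = NA_real_, centrality = NA_real_,
      density = network_density(net, denominator), m = net$m, n = net$n)
    if (net$empty || !node_level) return(net_row)
    deg <- node_degree(net)
    if (centrality && net$m >= 1) {
      cen <- eigenvector_centrality(net, tol = tol, max_iter = max_iter)
      deg <- dplyr::left_join(deg, cen$centrality, by = c("node", "class"))
    } else {
      deg$centrality <- NA_real_
    }
    node_rows <- dplyr::bind_cols(
      base[rep(1, nrow(deg)), ],
      dplyr::mutate(deg, level = "node", density = NA_real_,
                    m = net$m, n = net$n)) |>
      dplyr::select(dplyr::all_of(names(net_row)))
    dplyr::bind_rows(node_rows, net_row)
  })
}
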