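# Fixtures built in code: the two in-text worked examples, random bipartite
# graphs for property tests, and small synthetic corpora.

# four wordform tokens linking Qal.Present.Fm.Sg to four roots (the
# degree-4 worked example)
worked_example_tokens <- function(session = 3L, speaker = "CS") {
  tibble::tibble(
    dyad_id = "child2", session_index = session, age_days = 640L + session,
    speaker = speaker,
    root = c("r-?-y", "k-?-b", "n-w-H", "b-w-?"),
    binyan = "Qal", temporal = "Present",
    person = NA_character_, number = "Sg", gender = "Fm", count = 1L)
}

# the root l-m-d linked to Piel past and future 3SgM (two wordforms, 3 nodes)
fig1_tokens <- function() {
  tibble::tibble(
    dyad_id = "d", session_index = 1L, age_days = 650L, speaker = "CS",
    root = "l-m-d", binyan = "Piel", temporal = c("Past", "Future"),
    person = "3", number = "Sg", gender = "Masc", count = 1L)
}

# a valid token row generator over random roots/patterns; returns a token
# table for one stratum
random_stratum_tokens <- function(n_rows, session = 1L, speaker = "CS",
                                  dyad = "d", n_roots = 8, seed_pool = NULL) {
  infl <- inflection_inventory("Qal")
  pick <- sample(nrow(infl), n_rows, replace = TRUE)
  roots <- paste("r", letters[sample(n_roots, n_rows, replace = TRUE)],
                 "d", sep = "-")
  tibble::tibble(
    dyad_id = dyad, session_index = session, age_days = 600L + session,
    speaker = speaker, root = roots,
    binyan = infl$binyan[pick], temporal = infl$temporal[pick],
    person = infl$person[pick], number = infl$number[pick],
    gender = infl$gender[pick], count = 1L)
}

# a random non-empty session_network; optionally connected (the leading
# eigenvector is only unique up to component mixing when components tie)
random_bipartite_network <- function(n_roots = 6, n_patterns = 5,
                                     p_edge = 0.4, connected = FALSE) {
  repeat {
    toks <- random_stratum_tokens(
      n_rows = max(2, stats::rbinom(1, n_roots * n_patterns, p_edge)),
      n_roots = n_roots)
    net <- build_session_network(toks, "d", "CS", 1L)
    if (net$m >= 1 && (!connected || network_is_connected(net))) return(net)
  }
}

# breadth-first connectivity over the symmetric adjacency
network_is_connected <- function(net) {
  A <- adjacency_matrix(net, full = TRUE) > 0
  seen <- c(TRUE, rep(FALSE, nrow(A) - 1))
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# small fast dyad simulation for structural tests
small_sim_params <- function(n_sessions = 8L, ...) {
  default_sim_params(
    n_sessions = n_sessions, age_start = 664L,
    age_end = 664L + 3L * n_sessions,
    cds_tokens_per_session = 120, cs_tokens_per_session = 40,
    n_roots = 40L, child_initial_roots = 10L, ...)
}

# an artificial node-level model frame with known structure, for direct
# model-machinery tests (bypasses the measure pipeline)
make_node_frame <- function(n_nodes = 30, n_sessions = 10, seed = 1,
                            beta = NULL, tau = 0.5, sigma = 0.3) {
  set.seed(seed)
  cols <- c("degree.cs", "prior.degree.cs", "degree.cds", "prior.degree.cds",
            "centrality.cs", "prior.centrality.cs", "centrality.cds",
            "prior.centrality.cds", "density.cs", "prior.density.cs",
            "density.cds", "prior.density.cds")
  frame <- tidyr::expand_grid(
    name = sprintf("node%03d", seq_len(n_nodes)),
    session_index = 2:(n_sessions + 1))
  frame$age <- 660 + 3 * frame$session_index
  for (col in cols) frame[[col]] <- stats::rnorm(nrow(frame))
  # response injected over the stated predictors + node intercepts + noise
  if (is.null(beta)) {
    beta <- stats::setNames(rep(0, 12), c("age", setdiff(cols, "degree.cs")))
  }
  u <- stats::setNames(stats::rnorm(n_nodes, 0, tau), unique(frame$name))
  lin <- as.matrix(frame[, names(beta)]) %*% beta
  frame$degree.cs <- drop(lin) + u[frame$name] +
    stats::rnorm(nrow(frame), 0, sigma)
  frame$class <- "root"
  structure(tibble::as_tibble(frame), level = "node", dyad_id = "synth",
            scaling = tibble::tibble(column = character(0), mean = numeric(0),
                                     sd = numeric(0)),
            impute_prior = "zero",
            class = c("model_frame", class(tibble::tibble())))
}

# measure table -> model-frame pipeline on a small simulated dyad, cached
# per test file via local environment
small_pipeline <- function(seed = 11, n_sessions = 8L) {
  sim <- simulate_dyad(small_sim_params(n_sessions), seed = seed)
  series <- build_network_series(sim$tokens, "dyad1")
  measures <- measure_table(series)
  list(sim = sim, series = series, measures = measures)
}
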