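# End-to-end orchestration: corpus (read or simulate) -> networks ->
# measures -> activation -> lagged frames -> adaptation models -> artifact
# bundle on disk.

#' Run the full dynamic-network analysis pipeline
#'
#' Either reads a coded verb-token corpus or simulates one, then for each
#' dyad builds the per-session bipartite networks, computes the measure
#' table and activation timelines, assembles the lagged node- and
#' network-level model frames, fits the six adaptation models (four node
#' LMMs, two density LMs), and writes the artifact bundle: corpus summary,
#' edge lists, measure tables, activation spans, model summaries, the effect
#' ledger (JSON) and the resolved configuration.
#'
#' @param corpus Either a verb-token table / path to one, or `NULL` to
#'   simulate with `sim_params`.
#' @param sim_params A `sim_params` object used when `corpus` is `NULL`.
#' @param seed Seed for simulation (required if simulating).
#' @param out_dir Output directory for the artifact bundle; created if
#'   missing. `NULL` skips writing and just returns the results.
#' @param mode Adjacency mode, see [build_session_network()].
#' @param denominator Density denominator, see [network_density()].
#' @param impute_prior Prior imputation mode, see [assemble_model_frame()].
#' @param exclude_predictors Optional named list: response -> predictors to
#'   drop from that fit.
#' @param tol,max_iter Eigenvector-centrality controls.
#' @return A list per dyad with `summary`, `series`, `measures`,
#'   `activation` (CS and CDS), `frames`, `fits` (6 models), `ledger`.
#' @export
run_pipeline <- function(corpus = NULL, sim_params = default_sim_params(),
                         seed = NULL, out_dir = NULL,
                         mode = c("binary", "weighted"),
                         denominator = c("paper", "bipartite"),
                         impute_prior = c("zero", "drop"),
                         exclude_predictors = list(),
                         tol = 1e-10, max_iter = 10000) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  impute_prior <- match.arg(impute_prior)
  if (is.null(corpus)) {
    if (is.null(seed)) stop("seed is required when simulating a corpus")
    corpus <- simulate_dyad(sim_params, seed = seed)$tokens
  } else if (is.character(corpus)) {
    corpus <- read_verb_tokens(corpus)
  } else {
    corpus <- validate_verb_tokens(corpus)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  config <- list(mode = mode, denominator = denominator,
                 impute_prior = impute_prior, seed = seed,
                 tol = tol, max_iter = max_iter,
                 package_version = as.character(utils::packageVersion("morphodyn")))

  corpus_summary <- summarize_corpus(corpus)
  node_responses <- c("degree.cs", "degree.cds", "centrality.cs",
                      "centrality.cds")
  out <- purrr::map(unique(corpus$dyad_id), function(dy) {
    series <- build_network_series(corpus, dy, mode = mode)
    measures <- measure_table(series, denominator = denominator,
                              tol = tol, max_iter = max_iter)
    activation <- list(CS = activation_timeline(series, "CS"),
                       CDS = activation_timeline(series, "CDS"))
    frames <- list(node = assemble_model_frame(measures, "node",
                                               impute_prior),
                   network = assemble_model_frame(measures, "network"))
    fits <- c(
      purrr::map(rlang::set_names(node_responses), function(resp) {
        fit_node_lmm(frames$node, resp,
                     exclude = exclude_predictors[[resp]])
      }),
      purrr::map(rlang::set_names(c("density.cs", "density.cds")),
                 function(resp) fit_density_lm(frames$network, resp)))
    ledger <- effect_summary(fits)
    list(dyad_id = dy, series = series, measures = measures,
         activation = activation, frames = frames, fits = fits,
         ledger = ledger)
  })
  names(out) <- unique(corpus$dyad_id)

  if (!is.null(out_dir)) {
    readr::write_csv(as.data.frame(corpus_summary),
                     file.path(out_dir, "corpus_summary.csv"))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (dy in names(out)) {
      res <- out[[dy]]
      readr::write_tsv(as.data.frame(edge_list(res$series)),
                       file.path(out_dir, paste0(dy, "_edges.tsv")))
      readr::write_csv(as.data.frame(res$measures),
                       file.path(out_dir, paste0(dy, "_measures.csv")))
      for (sp in c("CS", "CDS")) {
        readr::write_csv(
          as.data.frame(res$activation[[sp]]$spans),
          file.path(out_dir, paste0(dy, "_activation_", sp, ".csv")))
      }
      model_tables <- purrr::imap_dfr(res$fits, function(f, nm) {
        dplyr::mutate(tidy(f), response = nm, .before = 1)
      })
      readr::write_csv(as.data.frame(model_tables),
                       file.path(out_dir, paste0(dy, "_model_fixed_effects.csv")))
      readr::write_csv(
        as.data.frame(purrr::map_dfr(res$fits, glance)),
        file.path(out_dir, paste0(dy, "_model_summaries.csv")))
      write_effect_ledger(res$ledger,
                          file.path(out_dir, paste0(dy, "_effect_ledger.json")))
    }
  }
  invisible(structure(list(summary = corpus_summary, dyads = out,
                           config = config),
                      class = "morphodyn_pipeline"))
}

#' @export
print.morphodyn_pipeline <- function(x, ...) {
  cat(sprintf("<morphodyn_pipeline> %d dyad(s): %s\n", length(x$dyads),
              paste(names(x$dyads), collapse = ", ")))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
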