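# The synthetic dyad generator: schema contract, determinism, calibration
# invariants, and the null-world intermittency oracle.

test_that("defaults encode the girl-dyad calibration anchors", {
  p <- default_sim_params()
  expect_equal(p$n_sessions, 47L)
  expect_equal(p$age_start, 664L)
  expect_equal(p$age_end, 810L)
  expect_equal(unname(p$binyan_mix["Qal"]), 0.80)
  expect_error(default_sim_params(nonsense = 1), "unknown parameter")
  expect_error(default_sim_params(child_initial_roots = 50L, n_roots = 10L))
})

test_that("simulated corpora are schema-valid and bit-reproducible given a seed", {
  p <- small_sim_params()
  a <- simulate_dyad(p, seed = 42)
  expect_s3_class(a$tokens, "verb_tokens")
  # re-validation from scratch finds zero violations
  expect_silent(validate_verb_tokens(tibble::as_tibble(
    as.data.frame(a$tokens))))
  b <- simulate_dyad(p, seed = 42)
  expect_identical(as.data.frame(a$tokens), as.data.frame(b$tokens))
  c <- simulate_dyad(p, seed = 43)
  expect_false(identical(as.data.frame(a$tokens), as.data.frame(c$tokens)))
  # ground truth is serialized alongside
  expect_equal(a$ground_truth$seed, 42L)
  expect_equal(nrow(a$ground_truth$sessions), p$n_sessions)
})

test_that("CDS exceeds CS in lemmas at every session and overall", {
  sim <- simulate_dyad(small_sim_params(n_sessions = 8L), seed = 3)
  per_session <- sim$tokens |>
    dplyr::group_by(session_index, speaker) |>
    dplyr::summarise(lemmas = dplyr::n_distinct(paste(root, binyan)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = speaker, values_from = lemmas)
  expect_true(all(per_session$CDS > per_session$CS))
})

test_that("the realized Qal token share is within 5 points of the parameter", {
  for (seed in c(5, 6)) {
    sim <- simulate_dyad(default_sim_params(), seed = seed)
    share <- with(sim$tokens, sum(count[binyan == "Qal"]) / sum(count))
    expect_lt(abs(share - 0.80), 0.05)
  }
})

test_that("with couplings, growth and jitter off, child activations are i.i.d. Bernoulli", {
  # closed-form oracle: for activation probability p over S sessions,
  # E[runs | >=1 activation] = (p + (S-1)p(1-p)) / (1 - (1-p)^S).
  # Estimate each node's p across replicates, compare mean runs per node.
  p <- small_sim_params(
    n_sessions = 20L, child_growth_per_session = 0,
    child_self_persistence = 0, child_echo_share = 0,
    child_from_parent_current = 0, child_from_parent_prior = 0,
    child_session_jitter = 0, child_volume_response = 0,
    cs_token_dispersion = 1e6, cds_token_dispersion = 1e6)
  n_reps <- 20
  S <- 20
  reps <- lapply(seq_len(n_reps), function(r) {
    sim <- simulate_dyad(p, seed = 1000 + r)
    series <- build_network_series(sim$tokens, "dyad1")
    act <- activation_timeline(series, "CS")
    act$spans[, c("node", "n_runs", "n_active")]
  })
  # pool activation frequency per node over all replicates; replicates in
  # which a node never appears contribute zero active sessions (the span
  # table conditions on >= 1 activation, the pooled rate must not)
  pooled <- dplyr::bind_rows(reps) |>
    dplyr::group_by(node) |>
    dplyr::summarise(p = sum(n_active) / (S * n_reps),
                     n_seen = dplyr::n())
  # mid-probability nodes give stable, informative run counts
  pooled <- dplyr::filter(pooled, n_seen >= n_reps * 0.8,
                          p > 0.05, p < 0.95)
  expected <- function(p) (p + (S - 1) * p * (1 - p)) / (1 - (1 - p)^S)
  per_rep <- vapply(reps, function(df) {
    df <- dplyr::inner_join(df, pooled, by = "node")
    mean(df$n_runs) - mean(expected(df$p))
  }, numeric(1))
  # observed minus oracle mean runs: zero within 2 SE over the replicates
  expect_lt(abs(mean(per_rep)), 2 * stats::sd(per_rep) / sqrt(n_reps))
})

test_that("positive couplings raise the child's reuse of the parent's prior constructs", {
  # P(child uses wordform at N | parent used it at N-1) minus
  # P(child uses | parent did not), averaged over replicates, is positive
  contrast <- vapply(1:6, function(r) {
    sim <- simulate_dyad(small_sim_params(n_sessions = 10L), seed = 300 + r)
    wf <- sim$tokens |>
      dplyr::mutate(wordform = paste(root, binyan, temporal, person, number,
                                     gender))
    use <- wf |>
      dplyr::distinct(session_index, speaker, wordform) |>
      dplyr::mutate(used = TRUE) |>
      tidyr::pivot_wider(names_from = speaker, values_from = used,
                         values_fill = FALSE)
    grid <- tidyr::expand_grid(session_index = 2:10,
                               wordform = unique(wf$wordform)) |>
      dplyr::left_join(use, by = c("session_index", "wordform")) |>
      dplyr::mutate(CS = dplyr::coalesce(CS, FALSE),
                    CDS = dplyr::coalesce(CDS, FALSE))
    prior <- use |>
      dplyr::transmute(session_index = session_index + 1L, wordform,
                       cds_prior = CDS)
    grid <- dplyr::left_join(grid, prior, by = c("session_index", "wordform")) |>
      dplyr::mutate(cds_prior = dplyr::coalesce(cds_prior, FALSE))
    mean(grid$CS[grid$cds_prior]) - mean(grid$CS[!grid$cds_prior])
  }, numeric(1))
  expect_gt(mean(contrast), 0)
})

test_that("recovery experiments are deterministic and tabulate per-predictor rates", {
  p <- small_sim_params(n_sessions = 10L)
  a <- recovery_experiment(p, n_reps = 2, seed = 9)
  b <- recovery_experiment(p, n_reps = 2, seed = 9)
  expect_identical(a$results, b$results)
  expect_setequal(a$summary$term,
                  c("age", "density.cds", "prior.density.cs",
                    "prior.density.cds"))
  expect_true(all(a$summary$positive_rate >= 0 & a$summary$positive_rate <= 1))
})
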