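# Synthetic dyad simulator: generates coded dyadic verb-token corpora with
# the statistical structure the analysis assumes — a Zipfian, Qal-dominant
# parental lexicon that is near-stationary across sessions; a growing child
# inventory sampled with multiplicative CS<->CDS adaptation couplings; and
# known ground truth for parameter-recovery experiments.

#' Default simulation parameters
#'
#' Calibrated to the girl dyad of the reference corpus: 47 recording
#' sessions between ages 664 and 810 days, roughly 650 child-directed and
#' 100 child verb tokens per session (corpus totals divided by sessions),
#' and a binyan mixture in which Qal carries 80% of the tokens. Couplings
#' default to moderately positive values so the adaptation signal the models
#' look for is present by construction.
#'
#' @param ... Named overrides of any default field.
#' @return An object of class `sim_params` (a named list).
#' @export
#' @examples
#' default_sim_params()$n_sessions # 47
default_sim_params <- function(...) {
  p <- list(
    dyad_id = "dyad1",
    n_sessions = 47L,
    age_start = 664L,
    age_end = 810L,
    cds_tokens_per_session = 650,
    cs_tokens_per_session = 100,
    # negative-binomial sizes for session token volumes, per speaker:
    # parental volume swings a lot with session length and engagement; the
    # child's volume, conditional on the parent's, varies less
    cds_token_dispersion = 2,
    cs_token_dispersion = 50,
    n_roots = 250L,             # CDS root inventory
    zipf_exponent = 1.0,        # root frequency ~ rank^-a
    binyan_mix = c(Qal = 0.80, Piel = 0.08, Hifil = 0.06, Hitpael = 0.03,
                   Nifal = 0.02, Hufal = 0.005, Pual = 0.005),
    extra_binyan_prob = c(0.6, 0.3),  # P(root has a 2nd / 3rd binyan)
    inflection_zipf_exponent = 0.8,   # skew over a binyan's categories
    child_initial_roots = 25L,
    child_growth_per_session = 3,     # roots added per session, Zipf order
    # multiplicative log-weight couplings (0 = off)
    child_self_persistence = 1.0,
    # share of the child's tokens echoed from the parent's current-session
    # token distribution (restricted to the child's root inventory):
    # imitation of immediate input, the strongest same-session
    # parent-to-child transmission channel at this age
    child_echo_share = 0.45,
    # elasticity of the child's session token volume to the parent's
    # realized volume (children talk more in sessions where they are
    # spoken to more); a directed same-session volume channel
    child_volume_response = 1.2,
    # share of the parent's tokens re-drawn (flat) from their own
    # previous-session wordforms: routine talk makes parental usage
    # continuous rather than resampled afresh each session
    parent_routine_reuse = 0.8,
    # session-level discourse-context jitter: sd of a per-session normal
    # perturbation of the log-weights. Child talk is dominated by the
    # activity at hand, so its effective lexicon rotates session to session
    # (the punctuated-usage signature); parental speech is more stationary.
    child_session_jitter = 1.5,
    parent_session_jitter = 0.0,
    child_from_parent_current = 0.8,
    child_from_parent_prior = 0.5,
    parent_from_child_current = 0.5,
    parent_from_child_prior = 0.3,
    # fraction of the parent's session tokens reallocated in response to
    # the child (the rest keep the provisional draw): parental adaptation
    # adjusts speech at the margin rather than resampling it wholesale
    parent_adapt_share = 0.3,
    parent_expansion_on_low_child_density = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$n_sessions >= 2, p$age_end > p$age_start,
            p$cds_tokens_per_session >= 1, p$cs_tokens_per_session >= 1,
            abs(sum(p$binyan_mix) - 1) < 1e-8, all(p$binyan_mix >= 0),
            p$child_initial_roots >= 1,
            p$child_initial_roots <= p$n_roots)
  structure(p, class = "sim_params")
}

# the lemma x inflection wordform space shared by parent and child:
# one row per (root, binyan, inflection category), with Zipfian base weights
.build_wordform_space <- function(params) {
  n <- params$n_roots
  # synthetic romanized roots: 3 radicals drawn from a consonant pool
  cons <- c("b", "g", "d", "z", "x", "T", "y", "k", "l", "m", "n", "s",
            "p", "c", "q", "r", "S", "t", "?", "H", "v", "f")
  roots <- character(n)
  taken <- character(0)
  i <- 1L
  while (i <= n) {
    cand <- paste(sample(cons, 3, replace = TRUE), collapse = "-")
    if (!cand %in% taken) {
      roots[i] <- cand
      taken <- c(taken, cand)
      i <- i + 1L
    }
  }
  root_w <- (seq_len(n))^(-params$zipf_exponent)
  b_names <- names(params$binyan_mix)
  primary <- sample(b_names, n, replace = TRUE, prob = params$binyan_mix)
  lemmas <- purrr::map_dfr(seq_len(n), function(i) {
    bs <- primary[i]
    for (p_extra in params$extra_binyan_prob) {
      if (stats::runif(1) < p_extra) {
        pool <- setdiff(b_names, bs)
        bs <- c(bs, sample(pool, 1, prob = params$binyan_mix[pool]))
      }
    }
    tibble::tibble(root = roots[i], root_rank = i, binyan = bs)
  })
  infl <- purrr::map_dfr(unique(lemmas$binyan), function(b) {
    tab <- inflection_inventory(b)
    tab$infl_w <- (seq_len(nrow(tab)))^(-params$inflection_zipf_exponent)
    tab$infl_w <- tab$infl_w / sum(tab$infl_w)
    tab
  })
  space <- dplyr::inner_join(lemmas, infl, by = "binyan",
                             relationship = "many-to-many")
  # calibrate so the aggregate base-weight share of each binyan equals the
  # stated mixture (roots differ in how many binyanim they take, so a naive
  # per-wordform product inflates the share of the dominant binyan)
  w_raw <- root_w[space$root_rank] * space$infl_w
  share_raw <- tapply(w_raw, space$binyan, sum)
  adj <- params$binyan_mix[names(share_raw)] / share_raw
  space$base_weight <- w_raw * adj[space$binyan]
  space$base_weight <- space$base_weight / sum(space$base_weight)
  # decomposition used by the expansion term: binyan share (held fixed)
  # and the within-binyan distribution (what expansion flattens)
  share <- tapply(space$base_weight, space$binyan, sum)
  space$log_binyan <- log(share[space$binyan])
  space$log_within <- log(space$base_weight) - space$log_binyan
  space
}

# rescale per-binyan probability masses to the stated token mixture; the
# within-binyan structure (couplings, reuse, expansion) is preserved. Kept
# for the parent only: CDS is the input whose binyan composition the
# mixture parameter states; the child's composition emerges via couplings.
.enforce_mix <- function(prob, binyan, mix) {
  cur <- tapply(prob, binyan, sum)
  cur <- cur[names(mix)]
  present <- !is.na(cur) & cur > 0
  scale <- rep(0, length(mix))
  names(scale) <- names(mix)
  scale[present] <- mix[present] / cur[present]
  out <- prob * scale[binyan]
  out / sum(out)
}

# mixture of a fresh sampling distribution with flat reuse of the
# previously-used wordform set (no-op before any usage exists)
.reuse_mix <- function(prob, prev_used, reuse) {
  if (reuse <= 0 || !any(prev_used)) return(prob)
  reuse_prob <- prev_used / sum(prev_used)
  (1 - reuse) * prob + reuse * reuse_prob
}

# density of a sampled wordform-count vector over the space (binary links)
.sample_density <- function(space, counts) {
  used <- counts > 0
  m <- sum(used)
  n <- length(unique(space$root[used])) + length(unique(space$label[used]))
  if (n < 2) return(NA_real_)
  m / (n * (n - 1) / 2)
}

#' Simulate a coded dyadic corpus with known adaptation couplings
#'
#' Each session, the parent (CDS) draws verb tokens from a near-stationary
#' Zipfian root-by-pattern distribution; the child (CS) draws from a growing
#' inventory (roots added in Zipf-rank order) whose log-weights are boosted
#' multiplicatively by the coupling terms: the child's own previous-session
#' usage, the parent's current-session usage, and the parent's
#' previous-session usage. The parent in turn reweights toward the child's
#' current and previous usage, and flattens (expands) its distribution when
#' the child's previous network density is low. Within-session simultaneity
#' is resolved by a two-pass draw: a provisional CDS sample (base weights
#' plus lagged child couplings) informs the child's "parent current" term,
#' then the recorded CDS is drawn conditional on the realized CS.
#'
#' @param params A `sim_params` object from [default_sim_params()].
#' @param seed Integer random seed (mandatory; identical (params, seed)
#'   give identical corpora).
#' @return A list with `tokens` (a validated verb-token tibble) and
#'   `ground_truth` (the parameters, seed, and per-session realized token
#'   volumes, child inventory sizes and usage-probability summaries).
#' @export
simulate_dyad <- function(params = default_sim_params(), seed) {
  stopifnot(inherits(params, "sim_params"), !missing(seed))
  set.seed(as.integer(seed))
  space <- .build_wordform_space(params)
  nW <- nrow(space)
  log_base <- log(space$base_weight)
  ages <- round(seq(params$age_start, params$age_end,
                    length.out = params$n_sessions))
  if (any(diff(ages) < 1)) ages <- params$age_start +
      round(seq(0, params$age_end - params$age_start,
                length.out = params$n_sessions))
  child_roots_n <- pmin(
    params$n_roots,
    floor(params$child_initial_roots +
            params$child_growth_per_session * (seq_len(params$n_sessions) - 1)))

  draw <- function(n_tok, prob) {
    drop(stats::rmultinom(1, n_tok, prob))
  }
  softmax <- function(lw) {
    w <- exp(lw - max(lw))
    w / sum(w)
  }

  cs_prev <- rep(FALSE, nW)
  cds_prev <- rep(FALSE, nW)
  cs_prev_density <- NA_real_
  cs_density_history <- numeric(0)
  rows <- vector("list", params$n_sessions)
  session_log <- vector("list", params$n_sessions)
  for (s in seq_len(params$n_sessions)) {
    n_cds <- max(1, stats::rnbinom(1, size = params$cds_token_dispersion,
                                   mu = params$cds_tokens_per_session))
    mu_cs <- params$cs_tokens_per_session *
      (n_cds / params$cds_tokens_per_session)^params$child_volume_response
    n_cs <- max(1, stats::rnbinom(1, size = params$cs_token_dispersion,
                                  mu = mu_cs))
    # pass 1: provisional parent distribution (base + lagged couplings)
    lw_cds <- log_base +
      params$parent_from_child_prior * cs_prev
    cds_prob_prov <- .enforce_mix(
      .reuse_mix(softmax(lw_cds), cds_prev, params$parent_routine_reuse),
      space$binyan, params$binyan_mix)
    cds_prov_counts <- draw(n_cds, cds_prob_prov)
    cds_prov_used <- cds_prov_counts > 0
    # child draw: growing inventory + persistence + parent couplings
    in_inventory <- space$root_rank <= child_roots_n[s]
    lw_cs <- log_base +
      params$child_self_persistence * cs_prev +
      params$child_from_parent_current * cds_prov_used +
      params$child_from_parent_prior * cds_prev +
      stats::rnorm(nW, 0, params$child_session_jitter)
    lw_cs[!in_inventory] <- -Inf
    cs_prob <- softmax(lw_cs)
    if (params$child_echo_share > 0) {
      echo <- cds_prov_counts * in_inventory
      if (sum(echo) > 0) {
        cs_prob <- (1 - params$child_echo_share) * cs_prob +
          params$child_echo_share * echo / sum(echo)
      }
    }
    cs_counts <- draw(n_cs, cs_prob)
    cs_used <- cs_counts > 0
    # pass 2: recorded parent draw, conditioned on realized child speech,
    # with expansion (flattening) when the child's prior density was low
    base2 <- log_base
    if (!is.na(cs_prev_density) && length(cs_density_history) >= 2 &&
        params$parent_expansion_on_low_child_density > 0) {
      # expansion: when the child's previous network is limited (sparser
      # than the child's own recent level) the parent spreads its usage,
      # providing more varied input. The reference is a moving average so
      # the parent reacts to local dips, not to the secular density decline
      # that comes with inventory growth. Flattening acts on the
      # within-binyan distribution only, preserving the binyan mixture.
      ref <- mean(utils::tail(cs_density_history, 5))
      deficit <- max(0, (ref - cs_prev_density) / ref)
      temp <- 1 + params$parent_expansion_on_low_child_density * deficit
      base2 <- space$log_binyan + space$log_within / temp
    }
    lw_cds2 <- base2 +
      params$parent_from_child_current * cs_used +
      params$parent_from_child_prior * cs_prev +
      stats::rnorm(nW, 0, params$parent_session_jitter)
    cds_prob <- .enforce_mix(
      .reuse_mix(softmax(lw_cds2), cds_prev, params$parent_routine_reuse),
      space$binyan, params$binyan_mix)
    w <- params$parent_adapt_share
    kept <- stats::rbinom(nW, cds_prov_counts, 1 - w)
    cds_counts <- kept + draw(n_cds - sum(kept), cds_prob)
    cds_used <- cds_counts > 0

    mk_rows <- function(counts, speaker) {
      idx <- which(counts > 0)
      tibble::tibble(
        dyad_id = params$dyad_id, session_index = s, age_days = ages[s],
        speaker = speaker, root = space$root[idx],
        binyan = space$binyan[idx], temporal = space$temporal[idx],
        person = space$person[idx], number = space$number[idx],
        gender = space$gender[idx], count = counts[idx])
    }
    rows[[s]] <- dplyr::bind_rows(mk_rows(cs_counts, "CS"),
                                  mk_rows(cds_counts, "CDS"))
    session_log[[s]] <- tibble::tibble(
      session_index = s, age_days = ages[s], n_cs_tokens = n_cs,
      n_cds_tokens = n_cds, child_n_roots = child_roots_n[s],
      cs_density = .sample_density(space, cs_counts),
      cds_density = .sample_density(space, cds_counts),
      cs_max_prob = max(cs_prob), cds_max_prob = max(cds_prob))
    cs_prev_density <- session_log[[s]]$cs_density
    if (!is.na(cs_prev_density)) {
      cs_density_history <- c(cs_density_history, cs_prev_density)
    }
    cs_prev <- cs_used
    cds_prev <- cds_used
  }
  tokens <- validate_verb_tokens(dplyr::bind_rows(rows))
  list(tokens = tokens,
       ground_truth = list(params = params, seed = as.integer(seed),
                           sessions = dplyr::bind_rows(session_log)))
}

#' Simulation-based parameter-recovery experiment
#'
#' Repeatedly simulates a dyad, runs the full density pipeline (networks ->
#' measures -> lagged network-level frame -> density linear models), and
#' tabulates, per predictor, the rate at which the fitted coefficient
#' recovers the ground-truth coupling sign and is significant at 0.05. With
#' all couplings set to zero the same tabulation estimates the coupling
#' terms' false-positive rate.
#'
#' @param params A `sim_params` object.
#' @param n_reps Number of replicates (>= 10).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param response Density response to model (default `"density.cs"`, whose
#'   `density.cds` coefficient carries the parent-to-child coupling).
#' @return An object of class `recovery_report`: a list with `results` (one
#'   row per replicate per predictor) and `summary` (per-predictor rates of
#'   positive sign, significance, and jointly positive-and-significant).
#' @export
recovery_experiment <- function(params = default_sim_params(), n_reps = 50,
                                seed = 1, response = "density.cs") {
  stopifnot(n_reps >= 1)
  results <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_dyad(params, seed = seed + r)
    series <- build_network_series(sim$tokens, params$dyad_id)
    meas <- measure_table(series, centrality = FALSE, node_level = FALSE)
    frame <- assemble_model_frame(meas, level = "network")
    fit <- fit_density_lm(frame, response)
    dplyr::mutate(tidy(fit), rep = r, .before = 1)
  })
  summary <- results |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      positive_rate = mean(.data$estimate > 0),
      significant_rate = mean(.data$p.value < 0.05),
      positive_significant_rate = mean(.data$estimate > 0 &
                                         .data$p.value < 0.05),
      .groups = "drop")
  structure(list(results = results, summary = summary, n_reps = n_reps,
                 response = response, params = params, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s over %d replicates (seed %d)\n",
              x$response, x$n_reps, x$seed))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
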