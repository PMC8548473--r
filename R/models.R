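# The adaptation models: linear mixed models (REML, random intercept per
# node name) for node degree and centrality, ordinary linear models for
# network density, with Wald inference, ICC and variance-partition R2.

#' Predictor set for a node-level response
#'
#' Age plus every current/prior measure column except the response itself.
#'
#' @param response One of `degree.cs`, `degree.cds`, `centrality.cs`,
#'   `centrality.cds`.
#' @param exclude Optional predictors to drop (some fits in the original
#'   design omit a predictor).
#' @return Character vector of predictor names.
#' @export
node_predictors <- function(response, exclude = NULL) {
  stopifnot(response %in% c("degree.cs", "degree.cds", "centrality.cs",
                            "centrality.cds"))
  preds <- c("age", setdiff(.measure_cols("node"), response))
  setdiff(preds, exclude)
}

#' Predictor set for a network-density response
#'
#' Age, the other party's density in the same recording, and both parties'
#' densities at the preceding recording.
#'
#' @param response `"density.cs"` or `"density.cds"`.
#' @return Character vector of the four predictor names.
#' @export
density_predictors <- function(response) {
  stopifnot(response %in% c("density.cs", "density.cds"))
  other <- setdiff(c("density.cs", "density.cds"), response)
  c("age", other, paste0("prior.", response), paste0("prior.", other))
}

#' Fit a node-level linear mixed adaptation model
#'
#' REML linear mixed model for node degree or eigenvector centrality with a
#' random intercept per node name, fixed effects = age plus the 11 remaining
#' current/prior measure columns, 95% Wald confidence intervals and
#' p-values, and ICC and marginal/conditional R2 by variance partition
#' (fixed-effects variance over total; fixed plus random over total).
#'
#' @param frame A node-level `model_frame`.
#' @param response One of `degree.cs`, `degree.cds`, `centrality.cs`,
#'   `centrality.cds`.
#' @param exclude Optional predictor names to omit from the fixed effects.
#' @return A `morphodyn_fit` object. Non-convergence or singularity is
#'   flagged in the object, never silent.
#' @export
fit_node_lmm <- function(frame, response, exclude = NULL) {
  stopifnot(inherits(frame, "model_frame"),
            identical(attr(frame, "level"), "node"))
  preds <- node_predictors(response, exclude)
  if (dplyr::n_distinct(frame$name) < 2) stop("need >= 2 node groups")
  fml <- stats::reformulate(c(preds, "(1 | name)"), response = response)
  fit <- lme4::lmer(fml, data = frame, REML = TRUE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  fixed <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    statistic = unname(beta / se),
    p.value = 2 * stats::pnorm(-abs(unname(beta / se))),
    conf.low = unname(beta - z * se), conf.high = unname(beta + z * se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "name"]
  sigma2 <- stats::sigma(fit)^2
  # Nakagawa variance partition on the fitted frame
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(drop(X %*% beta))
  total <- var_fixed + tau00 + sigma2
  structure(
    list(response = response, kind = "lmm", predictors = preds,
         formula = fml, fit = fit, fixed = fixed,
         sigma2 = sigma2, tau00 = tau00, icc = tau00 / (tau00 + sigma2),
         n_groups = dplyr::n_distinct(frame$name), n_obs = nrow(frame),
         r2_marginal = var_fixed / total,
         r2_conditional = (var_fixed + tau00) / total,
         reml = TRUE, converged = length(msgs) == 0, singular = singular,
         messages = msgs, dyad_id = attr(frame, "dyad_id")),
    class = "morphodyn_fit")
}

#' Fit a network-density linear adaptation model
#'
#' Ordinary least squares predicting one party's network density from age,
#' the other party's density in the same recording, and both parties'
#' densities at the preceding recording. Node-level measures are not
#' included: density is a global network property.
#'
#' @param frame A network-level `model_frame`.
#' @param response `"density.cs"` or `"density.cds"`.
#' @return A `morphodyn_fit` object; rank deficiency is flagged.
#' @export
fit_density_lm <- function(frame, response) {
  stopifnot(inherits(frame, "model_frame"),
            identical(attr(frame, "level"), "network"))
  if (nrow(frame) < 5) stop("need >= 5 sessions for the density model")
  preds <- density_predictors(response)
  fml <- stats::reformulate(preds, response = response)
  fit <- stats::lm(fml, data = frame)
  rank_deficient <- fit$rank < length(stats::coef(fit))
  sm <- summary(fit)
  co <- sm$coefficients
  z <- stats::qt(0.975, df = fit$df.residual)
  fixed <- tibble::tibble(
    term = rownames(co), estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4],
    conf.low = co[, 1] - z * co[, 2], conf.high = co[, 1] + z * co[, 2])
  structure(
    list(response = response, kind = "lm", predictors = preds,
         formula = fml, fit = fit, fixed = fixed,
         sigma2 = sm$sigma^2, tau00 = NA_real_, icc = NA_real_,
         n_groups = NA_integer_, n_obs = nrow(frame),
         r2 = sm$r.squared, r2_adjusted = sm$adj.r.squared,
         reml = FALSE, converged = TRUE, singular = rank_deficient,
         messages = character(0), dyad_id = attr(frame, "dyad_id")),
    class = "morphodyn_fit")
}

#' @export
print.morphodyn_fit <- function(x, digits = 2, ...) {
  cat(sprintf("<morphodyn_fit> %s model for %s (dyad %s)\n",
              toupper(x$kind), x$response, x$dyad_id))
  tab <- x$fixed
  fmt_ci <- sprintf(paste0("%.", digits, "f - %.", digits, "f"),
                    tab$conf.low, tab$conf.high)
  fmt_p <- ifelse(tab$p.value < 0.001, "<0.001",
                  sprintf("%.3f", tab$p.value))
  out <- data.frame(Predictors = tab$term,
                    Estimates = round(tab$estimate, digits),
                    CI = fmt_ci, p = fmt_p)
  print(out, row.names = FALSE)
  if (x$kind == "lmm") {
    cat("Random Effects\n")
    cat(sprintf("  sigma2  %.2f\n  tau00   %.2f name\n  ICC     %.2f\n",
                x$sigma2, x$tau00, x$icc))
    cat(sprintf("  N       %d name\n  Observations %d\n",
                x$n_groups, x$n_obs))
    cat(sprintf("Marg.R2/Cond.R2  %.3f/%.3f\n",
                x$r2_marginal, x$r2_conditional))
    if (!x$converged) cat("NOTE: optimizer messages -",
                          paste(x$messages, collapse = "; "), "\n")
    if (x$singular) cat("NOTE: singular fit (a variance component is ~0)\n")
  } else {
    cat(sprintf("Observations %d\nR2/R2 adjusted  %.3f/%.3f\n",
                x$n_obs, x$r2, x$r2_adjusted))
    if (x$singular) cat("NOTE: rank-deficient fit\n")
  }
  invisible(x)
}

#' Tidy the fixed effects of an adaptation model
#'
#' @param x A `morphodyn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.morphodyn_fit <- function(x, ...) {
  x$fixed
}

#' One-row model summary of an adaptation model
#'
#' @param x A `morphodyn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: response, kind, n_obs, n_groups, sigma2,
#'   tau00, ICC and the R2 pair appropriate to the model kind.
#' @exportS3Method generics::glance
glance.morphodyn_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, kind = x$kind, n_obs = x$n_obs,
    n_groups = x$n_groups, sigma2 = x$sigma2, tau00 = x$tau00, icc = x$icc,
    r2_marginal = if (x$kind == "lmm") x$r2_marginal else x$r2,
    r2_conditional = if (x$kind == "lmm") x$r2_conditional else
      x$r2_adjusted,
    converged = x$converged, singular = x$singular)
}

#' Machine-readable ledger of model effects
#'
#' Summarizes one or more fitted adaptation models into one row per
#' (model, predictor) with the effect's sign and its significance at 0.05 —
#' the tabular analogue of an effect path diagram (arrows from affecting to
#' affected measures).
#'
#' @param fits A `morphodyn_fit` or a list of them.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `response`, `term`, `estimate`, `p.value`,
#'   `sign` (`"positive"`/`"negative"`), `significant`.
#' @export
effect_summary <- function(fits, alpha = 0.05) {
  if (inherits(fits, "morphodyn_fit")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    f$fixed |>
      dplyr::filter(.data$term != "(Intercept)") |>
      dplyr::transmute(
        response = f$response, .data$term, .data$estimate, .data$p.value,
        sign = ifelse(.data$estimate >= 0, "positive", "negative"),
        significant = .data$p.value < alpha)
  })
}

#' Export an effect ledger as JSON
#'
#' Writes the [effect_summary()] ledger plus the edge list of significant
#' effects (affecting measure -> affected measure) to a JSON file.
#'
#' @param ledger An [effect_summary()] tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_effect_ledger <- function(ledger, path) {
  edges <- ledger |>
    dplyr::filter(.data$significant, .data$term != "age") |>
    dplyr::transmute(from = .data$term, to = .data$response, .data$sign,
                     .data$estimate)
  jsonlite::write_json(list(effects = ledger, edges = edges), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
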