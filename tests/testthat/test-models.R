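# Adaptation-model machinery: predictor sets, REML mixed models, OLS
# density models, inference summaries and the effect ledger.

test_that("predictor sets match the published model designs exactly", {
  expect_setequal(
    node_predictors("degree.cs"),
    c("age", "degree.cds", "prior.degree.cds", "prior.degree.cs",
      "centrality.cs", "prior.centrality.cs", "centrality.cds",
      "prior.centrality.cds", "density.cs", "prior.density.cs",
      "density.cds", "prior.density.cds"))
  expect_length(node_predictors("degree.cs"), 12)
  expect_false("degree.cs" %in% node_predictors("degree.cs"))
  expect_false("centrality.cds" %in% node_predictors("centrality.cds"))
  # the optional exclusion reproduces designs with a blank predictor cell
  expect_false("prior.degree.cs" %in%
                 node_predictors("centrality.cs", exclude = "prior.degree.cs"))
  expect_setequal(density_predictors("density.cs"),
                  c("age", "density.cds", "prior.density.cs",
                    "prior.density.cds"))
  expect_setequal(density_predictors("density.cds"),
                  c("age", "density.cs", "prior.density.cds",
                    "prior.density.cs"))
})

test_that("the density OLS matches a hand-rolled normal-equations oracle to 1e-8", {
  pl <- small_pipeline(seed = 19)
  frame <- assemble_model_frame(pl$measures, "network")
  fit <- fit_density_lm(frame, "density.cs")
  X <- cbind(1, as.matrix(frame[, density_predictors("density.cs")]))
  beta <- solve(t(X) %*% X, t(X) %*% frame$density.cs)
  expect_lt(max(abs(tidy(fit)$estimate - drop(beta))), 1e-8)
  # R2 from the same oracle
  res <- frame$density.cs - X %*% beta
  r2 <- 1 - sum(res^2) / sum((frame$density.cs - mean(frame$density.cs))^2)
  expect_equal(fit$r2, r2, tolerance = 1e-10)
  expect_error(fit_density_lm(frame[1:3, ], "density.cs"), ">= 5 sessions")
})

test_that("a noiseless linear response is recovered exactly by the mixed model", {
  frame <- make_node_frame(n_nodes = 40, n_sessions = 12, seed = 3,
                           tau = 0.8, sigma = 0)
  # response = 0.05*age + node intercepts, zero residual noise
  frame$degree.cs <- 0.05 * frame$age +
    rep(stats::rnorm(40, 0, 0.8), each = 12)
  fit <- suppressMessages(suppressWarnings(fit_node_lmm(frame, "degree.cs")))
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "age"], 0.05, tolerance = 1e-6)
  others <- est$estimate[!est$term %in% c("(Intercept)", "age")]
  expect_lt(max(abs(others)), 1e-6)
  expect_gt(fit$r2_conditional, 0.999)
})

test_that("with no node effect the mixed model collapses to the OLS solution", {
  frame <- make_node_frame(n_nodes = 40, n_sessions = 10, seed = 5,
                           beta = stats::setNames(
                             c(0.02, 0.4, -0.3, rep(0, 9)),
                             c("age", "degree.cds", "density.cs",
                               "prior.degree.cs", "prior.degree.cds",
                               "centrality.cs", "prior.centrality.cs",
                               "centrality.cds", "prior.centrality.cds",
                               "prior.density.cs", "density.cds",
                               "prior.density.cds")),
                           tau = 0, sigma = 0.5)
  fit <- suppressMessages(fit_node_lmm(frame, "degree.cs"))
  ols <- stats::lm(stats::reformulate(node_predictors("degree.cs"),
                                      "degree.cs"), data = frame)
  expect_lt(max(abs(tidy(fit)$estimate - stats::coef(ols))), 1e-4)
  expect_true(fit$singular) # tau00 ~ 0 is flagged, not hidden
})

test_that("the mixed model reports the variance components the design requires", {
  frame <- make_node_frame(n_nodes = 50, n_sessions = 10, seed = 7,
                           tau = 0.6, sigma = 0.4)
  fit <- fit_node_lmm(frame, "degree.cs")
  expect_true(fit$reml)
  expect_equal(fit$icc, fit$tau00 / (fit$tau00 + fit$sigma2))
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_equal(fit$n_groups, 50)
  expect_equal(fit$n_obs, nrow(frame))
  td <- tidy(fit)
  # Wald intervals: estimate +/- 1.96 se
  expect_equal(td$conf.high - td$estimate,
               stats::qnorm(0.975) * td$std.error, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$kind, "lmm")
  expect_equal(gl$icc, fit$icc)
  # variance components roughly recover the generating values
  expect_equal(fit$tau00, 0.36, tolerance = 0.5)
  expect_equal(fit$sigma2, 0.16, tolerance = 0.3)
})

test_that("Wald intervals cover a true zero coefficient at close to nominal rate", {
  # scaled-down coverage study: a null predictor's 95% CI should cover 0
  covered <- vapply(1:30, function(r) {
    frame <- make_node_frame(n_nodes = 40, n_sessions = 8, seed = 100 + r,
                             tau = 0.5, sigma = 0.4)
    fit <- suppressMessages(suppressWarnings(fit_node_lmm(frame, "degree.cs")))
    td <- tidy(fit)
    i <- td$term == "density.cds" # a pure noise predictor here
    td$conf.low[i] <= 0 && td$conf.high[i] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("the effect ledger records sign and significance per predictor", {
  pl <- small_pipeline(seed = 19)
  frame <- assemble_model_frame(pl$measures, "network")
  fits <- list(fit_density_lm(frame, "density.cs"),
               fit_density_lm(frame, "density.cds"))
  ledger <- effect_summary(fits)
  expect_setequal(unique(ledger$response), c("density.cs", "density.cds"))
  expect_false("(Intercept)" %in% ledger$term)
  expect_equal(ledger$sign, ifelse(ledger$estimate >= 0, "positive", "negative"))
  expect_equal(ledger$significant, ledger$p.value < 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_effect_ledger(ledger, path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(out, c("effects", "edges"))
  if (length(out$edges) > 0 && nrow(out$edges) > 0) {
    expect_true(all(out$edges$to %in% c("density.cs", "density.cds")))
  }
})
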