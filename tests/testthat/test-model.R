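# small clustered logistic data set with a known generating process
sim_clustered <- function(P, E, beta0, beta1, sigma, seed) {
  set.seed(seed)
  pid <- rep(seq_len(P), each = E)
  x <- stats::rnorm(P * E)
  u <- stats::rnorm(P)
  y <- stats::rbinom(P * E, 1, stats::plogis(beta0 + beta1 * x + sigma * u[pid]))
  list(y = y, x = x, pid = pid)
}

test_that("quadrature log-likelihood matches brute-force integration on a small fixture", {
  d <- sim_clustered(P = 5, E = 4, beta0 = -0.3, beta1 = 0.9, sigma = 0.8, seed = 5)
  X <- cbind(1, d$x)
  rule <- exadiary:::gh_rule(21)
  for (sg in c(0.3, 0.8, 1.5)) {
    ll_q <- exadiary:::agh_loglik(c(-0.3, 0.9), sg, X, d$y, d$pid, 5, rule)
    ll_t <- trapezoid_loglik(c(-0.3, 0.9), X = X, y = d$y, sigma = sg,
                             patient_id = d$pid)
    expect_equal(ll_q, ll_t, tolerance = 1e-6)
  }
})

test_that("adaptive and plain quadrature agree, and 21 vs 51 nodes is stable", {
  d <- sim_clustered(P = 20, E = 6, beta0 = -0.5, beta1 = 0.8, sigma = 1, seed = 9)
  f21 <- fit_reporting_model(d$y, data.frame(x = d$x), d$pid, nodes = 21)
  f51 <- fit_reporting_model(d$y, data.frame(x = d$x), d$pid, nodes = 51)
  expect_lt(max(abs(f21$coefficients - f51$coefficients)), 1e-4)
  expect_lt(abs(f21$random_intercept_sd - f51$random_intercept_sd), 1e-4)
  fpl <- fit_reporting_model(d$y, data.frame(x = d$x), d$pid, nodes = 51,
                             adaptive = FALSE)
  expect_lt(max(abs(f21$coefficients - fpl$coefficients)), 1e-3)
})

test_that("with zero true variance the fit collapses to ordinary logistic regression", {
  set.seed(1)
  P <- 100; E <- 40
  pid <- rep(seq_len(P), each = E)
  x <- stats::rnorm(P * E)
  y <- stats::rbinom(P * E, 1, stats::plogis(0.2 + 0.7 * x))
  fit <- fit_reporting_model(y, data.frame(x = x), pid)
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_lt(fit$random_intercept_sd, 0.05)
  expect_lt(max(abs(fit$coefficients - stats::coef(g))), 1e-3)
})

test_that("estimates agree with an independent mixed-model implementation", {
  d <- sim_clustered(P = 60, E = 6, beta0 = -0.4, beta1 = 0.9, sigma = 1, seed = 31)
  fit <- fit_reporting_model(d$y, data.frame(x = d$x), d$pid, nodes = 21)
  gm <- lme4::glmer(y ~ x + (1 | pid),
                    data = data.frame(y = d$y, x = d$x, pid = d$pid),
                    family = stats::binomial(), nAGQ = 21)
  expect_lt(max(abs(fit$coefficients - lme4::fixef(gm))), 1e-3)
  expect_lt(abs(fit$random_intercept_sd - sqrt(unlist(lme4::VarCorr(gm)))), 1e-3)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(gm)), tolerance = 1e-5)
})

test_that("likelihood at the optimum dominates the generating parameters", {
  d <- sim_clustered(P = 40, E = 5, beta0 = -0.5, beta1 = 0.7, sigma = 0.8, seed = 17)
  fit <- fit_reporting_model(d$y, data.frame(x = d$x), d$pid)
  X <- cbind(1, d$x)
  rule <- exadiary:::gh_rule(21)
  ll_truth <- exadiary:::agh_loglik(c(-0.5, 0.7), 0.8, X, d$y, d$pid, 40, rule)
  expect_gte(fit$log_likelihood, ll_truth - 1e-8)
})

test_that("odds ratios, intervals and p-values transform consistently", {
  d <- sim_clustered(P = 40, E = 5, beta0 = -0.5, beta1 = 0.7, sigma = 0.8, seed = 23)
  fit <- fit_reporting_model(d$y, data.frame(x = d$x), d$pid)
  expect_equal(fit$odds_ratios, exp(fit$coefficients))
  expect_equal(fit$ci_95, exp(fit$coef_ci_95), ignore_attr = TRUE)
  expect_true(all(fit$ci_95[, "lower"] <= fit$odds_ratios + 1e-12))
  expect_true(all(fit$ci_95[, "upper"] >= fit$odds_ratios - 1e-12))
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
})

test_that("pathological designs raise explicit diagnostics", {
  d <- sim_clustered(P = 10, E = 4, beta0 = 0, beta1 = 1, sigma = 0.5, seed = 3)
  expect_error(
    fit_reporting_model(d$y, data.frame(x = d$x, x2 = 2 * d$x), d$pid),
    "collinear"
  )
  y_sep <- as.integer(d$x > 0)
  expect_error(
    fit_reporting_model(y_sep, data.frame(x = d$x), d$pid),
    "separation"
  )
  expect_error(fit_reporting_model(d$y, data.frame(x = d$x), rep(1, length(d$y))),
               "two patients")
})

test_that("a predictor equal to the linear signal is selected; screening survives failures", {
  d <- sim_clustered(P = 50, E = 5, beta0 = -0.5, beta1 = 1.2, sigma = 0.5, seed = 12)
  noise <- stats::rnorm(length(d$y))
  scr <- univariate_screen(d$y, data.frame(signal = d$x, pure_noise = noise,
                                           degenerate = rep(1, length(d$y))),
                           d$pid)
  expect_true(scr$selected[scr$predictor == "signal"])
  expect_identical(scr$error[scr$predictor == "signal"], "")
  expect_false(scr$selected[scr$predictor == "degenerate"])
  expect_true(nzchar(scr$error[scr$predictor == "degenerate"]))
  expect_identical(nrow(scr), 3L)
})

test_that("an empty candidate list screens to an empty table", {
  d <- sim_clustered(P = 10, E = 3, beta0 = 0, beta1 = 0, sigma = 0.3, seed = 2)
  scr <- univariate_screen(d$y, data.frame(row.names = seq_along(d$y)), d$pid)
  expect_identical(nrow(scr), 0L)
})

test_that("chi-square test matches the Pearson formula and rejects zero marginals", {
  flat <- chi_square_test(matrix(c(10, 20, 10, 20), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  skewed <- chi_square_test(matrix(c(10, 20, 20, 10), 2))
  expect_equal(skewed$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(skewed$df, 1)
  expect_error(chi_square_test(cbind(c(5, 5), c(0, 0))), "zero marginal")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})
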