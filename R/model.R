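#' @title Two-level logistic model for exacerbation reporting
#' @description Events are nested in patients, and whether a patient
#'   seeks medical attention for an event depends both on event
#'   characteristics and on a stable patient-level propensity.  The
#'   model is a random-intercept logistic regression:
#'   `logit P(reported) = x'beta + sigma * u`, with `u ~ N(0, 1)` per
#'   patient.  The patient intercept is integrated out of the likelihood
#'   by adaptive Gauss-Hermite quadrature (per-patient mode and
#'   curvature centring), maximised over `(beta, log sigma)`, with Wald
#'   confidence intervals from the inverse observed information.
#' @name reporting-model
NULL

# Gauss-Hermite nodes/weights for weight function exp(-z^2)
gh_rule <- function(nodes) pracma::gaussHermite(nodes)

# Marginal log-likelihood of the random-intercept logit model.
# X: design matrix (with intercept), y: 0/1, pid: integer patient index
# 1..P, sigma >= 0.  adaptive=FALSE gives plain (non-centred) quadrature.
agh_loglik <- function(beta, sigma, X, y, pid, n_patients, rule,
                       adaptive = TRUE) {
  eta <- drop(X %*% beta)
  if (sigma < 1e-10) {
    p <- stats::plogis(eta)
    return(sum(y * log(p) + (1 - y) * log1p(-p)))
  }
  if (adaptive) {
    # Newton iterations for the per-patient posterior mode of u
    u <- numeric(n_patients)
    for (iter in 1:50) {
      p <- stats::plogis(eta + sigma * u[pid])
      g <- -u + sigma * drop(rowsum(y - p, pid, reorder = TRUE))
      h <- -1 - sigma^2 * drop(rowsum(p * (1 - p), pid, reorder = TRUE))
      step <- g / h
      u <- u - step
      if (max(abs(step)) < 1e-10) break
    }
    p <- stats::plogis(eta + sigma * u[pid])
    h <- -1 - sigma^2 * drop(rowsum(p * (1 - p), pid, reorder = TRUE))
    tau <- 1 / sqrt(-h)
  } else {
    u <- numeric(n_patients)
    tau <- rep(1, n_patients)
  }
  # integral_i = sqrt(2) tau_i sum_k w_k exp(z_k^2) f(u_i + sqrt(2) tau_i z_k)
  # with f(t) = exp(sum_j bernoulli loglik) * dnorm(t); log-sum-exp over k
  K <- length(rule$x)
  logcontrib <- matrix(0, n_patients, K)
  for (k in seq_len(K)) {
    t_k <- u + sqrt(2) * tau * rule$x[k]
    lp <- eta + sigma * t_k[pid]
    ll_obs <- y * stats::plogis(lp, log.p = TRUE) +
      (1 - y) * stats::plogis(-lp, log.p = TRUE)
    logcontrib[, k] <- log(rule$w[k]) + rule$x[k]^2 +
      drop(rowsum(ll_obs, pid, reorder = TRUE)) +
      stats::dnorm(t_k, log = TRUE)
  }
  m <- apply(logcontrib, 1, max)
  sum(log(sqrt(2) * tau) + m + log(rowSums(exp(logcontrib - m))))
}

#' Brute-force marginal log-likelihood by trapezoid integration
#'
#' Independent check of the quadrature likelihood: integrates each
#' patient's contribution over a fine regular grid of the random
#' intercept.  Only sensible for small data sets.
#'
#' @param beta coefficient vector (including intercept).
#' @param sigma random-intercept standard deviation.
#' @param X design matrix.
#' @param y binary outcome vector.
#' @param patient_id per-event patient identifiers.
#' @param lim integration limits for the standardised intercept.
#' @param n_grid number of grid points.
#' @return marginal log-likelihood.
#' @export
trapezoid_loglik <- function(beta, sigma, X, y, patient_id,
                             lim = c(-10, 10), n_grid = 20001) {
  pid <- as.integer(factor(patient_id))
  grid <- seq(lim[1], lim[2], length.out = n_grid)
  h <- grid[2] - grid[1]
  eta <- drop(X %*% beta)
  total <- 0
  for (i in seq_len(max(pid))) {
    idx <- pid == i
    logf <- vapply(grid, function(u) {
      lp <- eta[idx] + sigma * u
      sum(y[idx] * stats::plogis(lp, log.p = TRUE) +
            (1 - y[idx]) * stats::plogis(-lp, log.p = TRUE)) +
        stats::dnorm(u, log = TRUE)
    }, numeric(1))
    m <- max(logf)
    w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
    total <- total + m + log(sum(w * exp(logf - m)) * h)
  }
  total
}

check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("singular design: column(s) %s are collinear",
                 paste(drop_cols, collapse = ", ")), call. = FALSE)
  }
}

check_separation <- function(X, y) {
  fit0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p0 <- fit0$fitted.values
  if (all(p0[y == 1] > 1 - 1e-8) && all(p0[y == 0] < 1e-8)) {
    stop("complete separation: the outcome is perfectly predicted; coefficients diverge",
         call. = FALSE)
  }
  fit0$coefficients
}

#' Fit the random-intercept logistic reporting model
#'
#' @param outcome binary (0/1 or logical) per-event outcome, e.g.
#'   whether the event was reported.
#' @param predictors data frame of per-event covariates (numeric or
#'   two-level factors); an intercept is added automatically.
#' @param patient_id per-event patient identifier (grouping factor of
#'   the random intercept).
#' @param nodes number of Gauss-Hermite quadrature nodes (default 21).
#' @param adaptive centre the quadrature at each patient's posterior
#'   mode with curvature scaling (default `TRUE`); `FALSE` gives plain
#'   Gauss-Hermite, mainly for cross-checks.
#' @return object of class `exa_reporting_fit`: coefficients, standard
#'   errors, odds ratios with 95% Wald intervals, p-values, the
#'   random-intercept standard deviation, log-likelihood, sample sizes
#'   and a convergence flag.
#' @examples
#' set.seed(1)
#' pid <- rep(1:40, each = 4)
#' x <- rnorm(160)
#' y <- rbinom(160, 1, plogis(-0.5 + x + rnorm(40)[pid]))
#' fit_reporting_model(y, data.frame(x = x), pid)
#' @export
fit_reporting_model <- function(outcome, predictors, patient_id, nodes = 21,
                                adaptive = TRUE) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  pid_f <- factor(patient_id)
  if (nlevels(pid_f) < 2) stop("need at least two patients", call. = FALSE)
  pid <- as.integer(pid_f)
  n_patients <- nlevels(pid_f)

  mf <- stats::model.frame(~ ., data = as.data.frame(predictors),
                           na.action = stats::na.fail)
  X <- stats::model.matrix(~ ., data = mf)
  if (!all(is.finite(X))) stop("non-finite predictor values", call. = FALSE)
  check_design(X)
  beta0 <- check_separation(X, y)

  rule <- gh_rule(nodes)
  npar <- ncol(X)
  negll <- function(par) {
    -agh_loglik(par[seq_len(npar)], exp(par[npar + 1L]), X, y, pid,
                n_patients, rule, adaptive)
  }
  start <- c(beta0, log(0.5))
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, npar), log(1e-6)),
                      upper = c(rep(Inf, npar), log(25)),
                      control = list(maxit = 500))
  est <- opt$par
  beta_hat <- est[seq_len(npar)]
  sigma_hat <- exp(est[npar + 1L])
  names(beta_hat) <- colnames(X)

  at_bound <- est[npar + 1L] <= log(1e-6) + 1e-6
  H <- tryCatch(stats::optimHess(est, negll), error = function(e) NULL)
  se <- rep(NA_real_, npar)
  sigma_se <- NA_real_
  vc <- NULL
  if (!is.null(H)) {
    if (!at_bound) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
    }
    if (is.null(vc)) {
      # variance at (or near) the sigma boundary: profile out sigma
      vc_b <- tryCatch(solve(H[seq_len(npar), seq_len(npar), drop = FALSE]),
                       error = function(e) NULL)
      if (!is.null(vc_b)) se <- sqrt(pmax(diag(vc_b), 0))
    } else {
      se <- sqrt(pmax(diag(vc)[seq_len(npar)], 0))
      sigma_se <- sigma_hat * sqrt(max(diag(vc)[npar + 1L], 0))
    }
  }
  z <- beta_hat / se
  ci_lo <- beta_hat - stats::qnorm(0.975) * se
  ci_hi <- beta_hat + stats::qnorm(0.975) * se

  structure(list(
    coefficients = beta_hat,
    se = stats::setNames(se, colnames(X)),
    odds_ratios = exp(beta_hat),
    ci_95 = cbind(lower = exp(ci_lo), upper = exp(ci_hi)),
    coef_ci_95 = cbind(lower = ci_lo, upper = ci_hi),
    p_values = 2 * stats::pnorm(-abs(z)),
    random_intercept_sd = sigma_hat,
    random_intercept_sd_se = sigma_se,
    sd_at_boundary = at_bound,
    log_likelihood = -opt$value,
    n_events = length(y),
    n_patients = n_patients,
    nodes = nodes,
    adaptive = adaptive,
    converged = opt$convergence == 0
  ), class = "exa_reporting_fit")
}

#' @export
print.exa_reporting_fit <- function(x, ...) {
  cat(sprintf("Two-level logistic fit: %d events in %d patients (AGHQ, %d nodes)\n",
              x$n_events, x$n_patients, x$nodes))
  tab <- data.frame(OR = x$odds_ratios,
                    ci_low = x$ci_95[, "lower"], ci_high = x$ci_95[, "upper"],
                    p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("random-intercept sd: %.4f   logLik: %.4f   converged: %s\n",
              x$random_intercept_sd, x$log_likelihood, x$converged))
  invisible(x)
}

#' Univariate screening of reporting predictors
#'
#' Fits one single-predictor two-level model per candidate and flags
#' those with a Wald p-value below `alpha` (default .10) for inclusion
#' in the multivariable model.  Per-predictor fit failures are recorded
#' in the table, not fatal.
#'
#' @param outcome binary per-event outcome.
#' @param candidates data frame of candidate predictors.
#' @param patient_id per-event patient identifier.
#' @param alpha selection threshold on the p-value (default 0.10).
#' @inheritParams fit_reporting_model
#' @return data frame with one row per candidate: crude odds ratio,
#'   95% CI, p-value, `selected` flag and an `error` column (empty on
#'   success).
#' @export
univariate_screen <- function(outcome, candidates, patient_id, alpha = 0.10,
                              nodes = 21) {
  stopifnot(alpha > 0, alpha < 1)
  rows <- lapply(names(candidates), function(v) {
    res <- tryCatch({
      fit <- fit_reporting_model(outcome, candidates[v], patient_id, nodes = nodes)
      j <- 2L  # slot after the intercept
      data.frame(predictor = v,
                 or = fit$odds_ratios[j],
                 ci_low = fit$ci_95[j, "lower"], ci_high = fit$ci_95[j, "upper"],
                 p.value = fit$p_values[j],
                 selected = is.finite(fit$p_values[j]) && fit$p_values[j] < alpha,
                 error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(predictor = v, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p.value = NA_real_, selected = FALSE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(predictor = character(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p.value = numeric(0), selected = logical(0),
                      error = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square without continuity correction, as used for
#' comparing qualitative variables across groups.
#'
#' @param table matrix of non-negative integer counts.
#' @return list with `statistic`, `df` and `p.value`.
#' @examples
#' chi_square_test(matrix(c(10, 20, 20, 10), 2))
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
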