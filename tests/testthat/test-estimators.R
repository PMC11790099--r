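test_that("Hajek IPW reproduces the six-patient hand calculation exactly", {
  arm <- c(1, 1, 1, 0, 0, 0)
  y <- c(1, 0, 1, 0, 1, 0)
  e <- c(0.2, 0.5, 0.8, 0.2, 0.5, 0.8)
  fit <- ate_from_predictions(list(e = e), arm, y, estimator = "ipw")
  ## hand arithmetic: treated weights 1/e = (5, 2, 1.25);
  ## E[Y(1)] = (5*1 + 2*0 + 1.25*1) / 8.25; control weights 1/(1-e) =
  ## (1.25, 2, 5); E[Y(0)] = (1.25*0 + 2*1 + 5*0) / 8.25
  expect_equal(fit$arm_means[["ey1"]], 6.25 / 8.25, tolerance = 1e-15)
  expect_equal(fit$arm_means[["ey0"]], 2 / 8.25, tolerance = 1e-15)
  expect_equal(coef(fit)[["risk_difference"]], (6.25 - 2) / 8.25, tolerance = 1e-15)
})

test_that("uniform propensities make IPW collapse to the naive contrast", {
  set.seed(61)
  arm <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, 0.3)
  ipw <- ate_from_predictions(list(e = rep(0.5, 300)), arm, y, "ipw")
  naive <- ate_from_predictions(list(), arm, y, "naive")
  expect_equal(coef(ipw)[["risk_difference"]], coef(naive)[["risk_difference"]],
               tolerance = 1e-12)
  ## unclipped boundary propensities are a positivity error
  expect_error(ate_from_predictions(list(e = rep(c(0, 0.5), 150)), arm, y, "ipw"),
               "positivity")
})

test_that("G-formula averages counterfactual predictions", {
  mu0 <- runif(100, 0.1, 0.5)
  fit0 <- ate_from_predictions(list(mu1 = mu0, mu0 = mu0),
                               rep(0:1, 50), rep(0L, 100), "gformula")
  expect_equal(coef(fit0)[["risk_difference"]], 0, tolerance = 1e-15)
  fit1 <- ate_from_predictions(list(mu1 = mu0 + 0.1, mu0 = mu0),
                               rep(0:1, 50), rep(0L, 100), "gformula")
  expect_equal(coef(fit1)[["risk_difference"]], 0.1, tolerance = 1e-12)
})

test_that("oracle-injected estimators converge to the true ATE", {
  ## true nuisances from ground truth: bias bounds shrink with n
  for (n in c(2000, 10000, 50000)) {
    sim <- simulate_ehr(sim_config(n_patients = n, seed = n %% 1000 + 3))
    tr <- sim$truth
    np <- list(e = pmin(pmax(tr$e, 0.01), 0.99), mu1 = tr$p1, mu0 = tr$p0)
    for (est in c("ipw", "gformula", "aipw")) {
      fit <- ate_from_predictions(np, tr$arm, tr$y, est)
      ## 5 standard errors of the worst-case influence function
      expect_lt(abs(coef(fit)[["risk_difference"]] - mean(tr$tau)),
                5 * 1.5 / sqrt(n))
    }
  }
})

test_that("AIPW is robust to single-nuisance misspecification in both legs", {
  sim <- simulate_ehr(sim_config(n_patients = 20000, seed = 67,
                                 treatment_delay_range_h = c(0, 0)))
  tr <- sim$truth
  ybar <- mean(tr$y)
  ## constant outcome model, true propensity: algebra reduces toward IPW
  leg1 <- ate_from_predictions(
    list(e = pmin(pmax(tr$e, 0.01), 0.99),
         mu1 = rep(ybar, nrow(tr)), mu0 = rep(ybar, nrow(tr))),
    tr$arm, tr$y, "aipw")
  expect_lt(abs(coef(leg1)[["risk_difference"]]), 0.03)
  ## constant propensity, true outcome model
  leg2 <- ate_from_predictions(
    list(e = rep(mean(tr$arm), nrow(tr)), mu1 = tr$p1, mu0 = tr$p0),
    tr$arm, tr$y, "aipw")
  expect_lt(abs(coef(leg2)[["risk_difference"]]), 0.03)
})

test_that("DML recovers a randomized effect and zeroes orthogonal residuals", {
  set.seed(71)
  n <- 8000
  x <- rnorm(n)
  e <- rep(0.4, n)
  a <- rbinom(n, 1, e)
  ate <- -0.05
  y_prob <- pmin(pmax(0.3 + 0.1 * x + ate * a, 0.01), 0.99)
  y <- rbinom(n, 1, y_prob)
  m <- 0.3 + 0.1 * x + ate * e      # true marginal regression E[Y | X]
  fit <- ate_from_predictions(list(e = e, m = m), a, y, "dml")
  se <- 1 / (sqrt(n) * sd(a - e))
  expect_lt(abs(coef(fit)[["risk_difference"]] - ate), 3 * se)

  ## orthogonal residuals by construction -> slope exactly zero
  fit0 <- ate_from_predictions(list(e = e, m = as.numeric(y)), a, y, "dml")
  expect_equal(coef(fit0)[["risk_difference"]], 0, tolerance = 1e-12)

  ## degenerate treatment residuals are ill-posed
  expect_error(ate_from_predictions(list(e = as.numeric(a), m = m), a, y, "dml"),
               "ill-posed")
})

test_that("DML's constant-effect estimate lies between subgroup true effects", {
  sim <- simulate_ehr(sim_config(
    n_patients = 20000, seed = 73,
    modifier_effects = c(septic_shock = -0.08)))
  parts <- sim_features(sim)
  fit <- causal_ate(parts$fm, parts$cohort$arm, parts$cohort$death,
                    estimator = "dml", nuisance = ridge_fast(), B = 0, seed = 74)
  te <- true_effects(sim)
  lo <- min(te$true_ate) - 0.03
  hi <- max(te$true_ate) + 0.03
  rd <- coef(fit)[["risk_difference"]]
  expect_gt(rd, lo)
  expect_lt(rd, hi)
})

test_that("estimand transforms are exact and sign-coherent", {
  expect_equal(unname(transform_estimand(0.2, 0.4)),
               c(-0.2, 0.5, 0.375), tolerance = 1e-15)
  expect_equal(unname(transform_estimand(0.3, 0.3)), c(0, 1, 1), tolerance = 1e-15)
  expect_equal(transform_estimand(0.5, 0.5)[["odds_ratio"]], 1, tolerance = 1e-15)
  expect_error(transform_estimand(0, 0.4), "undefined")
  expect_error(transform_estimand(0.2, 1), "undefined")
  set.seed(79)
  for (i in 1:50) {
    p <- runif(2, 0.01, 0.99)
    est <- transform_estimand(p[1], p[2])
    expect_equal(sign(est[["risk_difference"]]), sign(log(est[["risk_ratio"]])))
    expect_equal(sign(est[["risk_difference"]]), sign(log(est[["odds_ratio"]])))
  }
})

test_that("bootstrap percentile intervals come from the replicate quantiles", {
  set.seed(83)
  x <- rnorm(200, mean = 1)
  ci <- bootstrap_ci(function(idx) c(mean = mean(x[idx])), n = 200,
                     B = 50, level = 0.95, seed = 9)
  ## replay the resampling independently
  set.seed(9)
  reps <- replicate(50, mean(x[sample.int(200, 200, replace = TRUE)]))
  ## (B+1) order-statistic convention for percentile intervals
  expect_equal(unname(ci$lower), unname(quantile(reps, 0.025, type = 6)),
               tolerance = 1e-12)
  expect_equal(unname(ci$upper), unname(quantile(reps, 0.975, type = 6)),
               tolerance = 1e-12)

  ## constant statistic -> zero-width interval
  ci0 <- bootstrap_ci(function(idx) c(est = 0.42), n = 50, B = 20, seed = 1)
  expect_identical(unname(ci0$lower), 0.42)
  expect_identical(unname(ci0$upper), 0.42)

  ## failing replicates are dropped and counted; too many is an error
  flaky <- function(idx) if (1L %in% idx) stop("boom") else c(est = mean(idx))
  expect_error(bootstrap_ci(flaky, n = 3, B = 30, seed = 2), "dropped")
  expect_error(bootstrap_ci(function(idx) 1, n = 10, B = 1), "B")
})
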