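test_that("box summaries match an independent order-statistics oracle", {
  ## a continuous modifier makes the fitted effects vary inside each group,
  ## so the quartile machinery is exercised on non-degenerate values
  tau <- c(-0.31, -0.12, -0.05, -0.02, 0.0, 0.01, 0.04, 0.07, 0.11, 0.40)
  mods <- data.frame(grp = c(rep(1L, 6), rep(0L, 4)),
                     sev = c(3, -1, 0.5, 2, -2, 1, -0.5, 0.2, 1.5, -3))
  cate <- estimate_cate(tau, mods, final_model = "ridge", lambda = 1e-9)
  s <- cate$subgroups
  expect_identical(s$n[s$level == 1], 6L)
  expect_identical(s$n[s$level == 0], 4L)
  expect_identical(sum(s$n), length(tau))

  g1 <- cate$tau[mods$grp == 1]
  expect_gt(stats::sd(g1), 0)
  expect_equal(s$median[s$level == 1], quartile_oracle(g1, 0.5), tolerance = 1e-9)
  expect_equal(s$q25[s$level == 1], quartile_oracle(g1, 0.25), tolerance = 1e-9)
  expect_equal(s$q75[s$level == 1], quartile_oracle(g1, 0.75), tolerance = 1e-9)
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  expect_true(all(s$whisker_lo >= s$q25 - 1.5 * (s$q75 - s$q25) - 1e-12))
  expect_true(all(s$whisker_hi <= s$q75 + 1.5 * (s$q75 - s$q25) + 1e-12))
})

test_that("a constant effect signal degenerates every box to that constant", {
  mods <- data.frame(a = rep(c(0L, 1L), 25), b = rep(c(1L, 1L, 0L, 0L, 0L), 10))
  cate <- estimate_cate(rep(-0.07, 50), mods, final_model = "ridge")
  s <- cate$subgroups
  expect_true(all(abs(s$median + 0.07) < 1e-9))
  expect_true(all(abs(s$q25 - s$q75) < 1e-9))
  expect_true(all(abs(s$whisker_lo - s$whisker_hi) < 1e-9))
})

test_that("mean predicted effect equals the ATE estimate (population coherence)", {
  sim <- simulate_ehr(sim_config(n_patients = 3000, seed = 157,
    modifier_effects = c(septic_shock = -0.05)))
  fit <- ate_pipeline(sim$tables, estimator = "aipw", nuisance = ridge_fast(),
                      B = 0, seed = 11)
  cate <- estimate_cate(fit, make_modifiers(fit$cohort))
  expect_equal(cate$mean_tau, coef(fit)[["risk_difference"]], tolerance = 1e-6)
  ## subgroup sizes sum to the cohort size for every modifier
  for (m in unique(cate$subgroups$modifier))
    expect_identical(sum(cate$subgroups$n[cate$subgroups$modifier == m]), fit$n)
  ## four binary characteristics -> eight box rows
  expect_identical(nrow(subgroup_report(cate)), 8L)
})

test_that("post-treatment modifiers are refused (leakage guard)", {
  mods <- data.frame(fine = rep(0:1, 10), leaky = rep(1:0, 10))
  attr(mods, "roles") <- data.frame(
    feature = c("fine", "leaky"),
    role = c("effect_modifier", "post_treatment"),
    group = "biology")
  expect_error(estimate_cate(rnorm(20), mods), "leakage.*leaky")
  ## a causal_ate fit without pseudo-outcomes cannot feed the DR-learner
  sim <- simulate_ehr(sim_config(n_patients = 600, seed = 163))
  fit <- ate_pipeline(sim$tables, estimator = "naive", B = 0)
  expect_error(estimate_cate(fit, make_modifiers(fit$cohort)), "aipw")
})

test_that("configured modifier effects are recovered from the DR-learner", {
  sim <- simulate_ehr(sim_config(
    n_patients = 10000, seed = 167,
    modifier_effects = c(septic_shock = -0.05, age_ge_60 = -0.03, male = -0.02)))
  fit <- ate_pipeline(sim$tables, estimator = "aipw", nuisance = ridge_fast(),
                      B = 0, seed = 13, truth = sim$truth)
  cate <- estimate_cate(fit, make_modifiers(fit$cohort))
  gap <- mean(cate$tau[cate$modifiers$septic_shock == 1]) -
    mean(cate$tau[cate$modifiers$septic_shock == 0])
  expect_lt(abs(gap - (-0.05)), 0.06)     # ~3 sampling SEs at this n
  expect_lt(cate$coefficients[["septic_shock"]], 0)
  ## null heterogeneity: subgroup medians within a Monte-Carlo band
  sim0 <- simulate_ehr(sim_config(n_patients = 10000, seed = 169))
  fit0 <- ate_pipeline(sim0$tables, estimator = "aipw", nuisance = ridge_fast(),
                       B = 0, seed = 14)
  cate0 <- estimate_cate(fit0, make_modifiers(fit0$cohort))
  s0 <- cate0$subgroups
  expect_lt(max(s0$median) - min(s0$median), 0.1)
})

test_that("plots and forest final models produce usable output", {
  sim <- simulate_ehr(sim_config(n_patients = 1200, seed = 173))
  fit <- ate_pipeline(sim$tables, estimator = "aipw", nuisance = ridge_fast(),
                      B = 0, seed = 15)
  cate_f <- estimate_cate(fit, make_modifiers(fit$cohort), final_model = "forest")
  expect_true(all(is.finite(cate_f$tau)))
  expect_null(cate_f$coefficients)
  f <- file.path(withr::local_tempdir(), "subgroups.png")
  tab <- subgroup_report(cate_f, plot_file = f)
  expect_true(file.exists(f))
  expect_identical(nrow(tab), 8L)
  expect_output(print(cate_f), "Conditional average")
})
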